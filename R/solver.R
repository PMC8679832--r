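# Minimal-number-of-studies search. Power is strictly increasing in k for a
# fixed design (the noncentrality is linear in k), so a doubling bracket
# followed by integer bisection on the constrained lattice finds the minimum.

K_CAP <- 1e6

new_required_k <- function(k_min, achieved_power, target_power, constraint,
                           params) {
  structure(
    list(k_min = k_min, achieved_power = achieved_power,
         target_power = target_power, constraint = constraint,
         params = params),
    class = "required_k"
  )
}

# power_fn(k) -> power; lattice: k = first + step * 0:m
solve_k <- function(power_fn, target_power, first, step) {
  if (power_fn(K_CAP) < target_power) {
    sp_stop("not_achievable",
            sprintf("target power %.3f is not reachable within %g studies", target_power, K_CAP))
  }
  lo <- first
  if (power_fn(lo) >= target_power) return(lo)
  hi <- lo
  repeat {
    hi <- min(lo + 2 * (hi - lo + step), K_CAP)
    hi <- first + step * ceiling((hi - first) / step)
    if (power_fn(hi) >= target_power) break
  }
  # invariant: power(lo) < target <= power(hi)
  while (hi - lo > step) {
    mid <- first + step * floor(((lo + hi) / 2 - first) / step)
    if (mid <= lo) mid <- lo + step
    if (mid >= hi) mid <- hi - step
    if (power_fn(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

check_target <- function(target_power) {
  if (length(target_power) != 1L || !is.finite(target_power) ||
      target_power <= 0 || target_power >= 1) {
    sp_stop("domain", "`target_power` must lie in (0, 1)")
  }
}

#' Required number of studies for the pooled-effect test
#'
#' Smallest integer number of studies `k >= 2` for which the random-effects
#' pooled-effect z-test ([power_main_effect()]) attains `target_power`.
#'
#' @inheritParams power_main_effect
#' @param target_power Target power in `(0, 1)`; default 0.80.
#' @return An object of class `"required_k"` with `k_min`, `achieved_power`,
#'   `target_power`, `constraint = "any_integer"` and the echoed `params`.
#' @examples
#' required_k_main(d = 0.5, study_size = 50, i2 = 0.5)  # 6 studies
#' @export
required_k_main <- function(d, study_size, i2 = 0, alpha = 0.05,
                            target_power = 0.80) {
  check_target(target_power)
  if (d == 0) sp_stop("not_achievable", "`d` = 0: power never exceeds alpha")
  pf <- function(k) power_main_effect(d, study_size, k, i2, alpha)$power
  k <- solve_k(pf, target_power, first = 2, step = 1)
  new_required_k(k, pf(k), target_power, "any_integer",
                 params = list(d = d, study_size = study_size, i2 = i2,
                               alpha = alpha))
}

#' Required number of studies for the between-subgroup test
#'
#' Smallest number of studies for which the moderator Q-test
#' ([power_subgroup()]) attains `target_power`, under an integrality
#' constraint on the total count:
#' \describe{
#'   \item{`any_integer`}{all integers `k >= 2`; per-subgroup counts
#'     `proportions * k` may be fractional,}
#'   \item{`even`}{even totals only (with two balanced subgroups this makes
#'     every per-subgroup count a whole number),}
#'   \item{`multiple_of_groups`}{multiples of the number of subgroups.}
#' }
#'
#' @inheritParams power_subgroup
#' @inheritParams required_k_main
#' @param constraint Integrality constraint on the study count.
#' @return An object of class `"required_k"`.
#' @examples
#' required_k_subgroup(c(0.1, 0.6), study_size = 50, i2 = 0.5,
#'                     constraint = "even")         # 22 studies
#' required_k_subgroup(c(0.1, 0.6), study_size = 50, i2 = 0.5)  # 21 studies
#' @export
required_k_subgroup <- function(effects, proportions = NULL, study_size,
                                i2 = 0, alpha = 0.05, target_power = 0.80,
                                constraint = c("any_integer", "even",
                                               "multiple_of_groups")) {
  constraint <- match.arg(constraint)
  check_target(target_power)
  if (is.null(proportions)) {
    proportions <- rep(1 / length(effects), length(effects))
  }
  p <- check_subgroups(effects, proportions)
  step <- switch(constraint, any_integer = 1, even = 2, multiple_of_groups = p)
  first <- switch(constraint, any_integer = 2, even = 2, multiple_of_groups = p)
  pf <- function(k) power_subgroup(effects, proportions, study_size, k,
                                   i2, alpha)$power
  k <- solve_k(pf, target_power, first = first, step = step)
  new_required_k(k, pf(k), target_power, constraint,
                 params = list(effects = effects, proportions = proportions,
                               study_size = study_size, i2 = i2, alpha = alpha))
}

#' Studies needed for a subgroup analysis relative to the main analysis
#'
#' Solves the required number of studies for a two-subgroup moderator test and
#' for the corresponding main (pooled-effect) analysis, and returns their
#' ratio. The main-analysis effect is, by convention, the *difference*
#' between the two subgroup effects — a subgroup contrast of a given size is
#' compared against detecting a pooled effect of the same size. The
#' main-analysis target power defaults to the subgroup target but can be set
#' separately (a headline main analysis is typically powered at 0.80 even
#' when the subgroup question is examined at a stricter target).
#'
#' @inheritParams required_k_subgroup
#' @param main_target_power Target power for the main-analysis solve;
#'   defaults to `target_power`.
#' @return An object of class `"power_ratio"`: a list with `ratio`,
#'   `subgroup` and `main` (the two `"required_k"` results).
#' @examples
#' ratio_to_main(c(0.1, 0.6), study_size = 50, i2 = 0.5,
#'               constraint = "even")  # 22 / 6
#' @export
ratio_to_main <- function(effects, proportions = NULL, study_size, i2 = 0,
                          alpha = 0.05, target_power = 0.80,
                          constraint = c("any_integer", "even",
                                         "multiple_of_groups"),
                          main_target_power = target_power) {
  if (length(effects) != 2L) {
    sp_stop("subgroup_spec", "the main-analysis comparison is defined for exactly two subgroups")
  }
  sub <- required_k_subgroup(effects, proportions, study_size, i2, alpha,
                             target_power, constraint)
  main <- required_k_main(d = effects[2] - effects[1], study_size = study_size,
                          i2 = i2, alpha = alpha,
                          target_power = main_target_power)
  structure(list(ratio = sub$k_min / main$k_min, subgroup = sub, main = main),
            class = "power_ratio")
}

#' @export
print.required_k <- function(x, ...) {
  cat("Required number of studies\n\n")
  cat("  k_min:          ", x$k_min, "  (constraint: ", x$constraint, ")\n", sep = "")
  cat("  Achieved power: ", format(round(x$achieved_power, 4)), "\n", sep = "")
  cat("  Target power:   ", format(x$target_power), "\n", sep = "")
  invisible(x)
}

#' @export
print.power_ratio <- function(x, ...) {
  cat("Subgroup vs main-analysis study requirement\n\n")
  cat("  Subgroup analysis: k =", x$subgroup$k_min,
      sprintf("(power %.3f at target %.2f)\n", x$subgroup$achieved_power,
              x$subgroup$target_power))
  cat("  Main analysis:     k =", x$main$k_min,
      sprintf("(power %.3f at target %.2f)\n", x$main$achieved_power,
              x$main$target_power))
  cat(sprintf("  Ratio:             %.2f times the studies of the main analysis\n",
              x$ratio))
  invisible(x)
}
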