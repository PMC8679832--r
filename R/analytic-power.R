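#' Upper tail of the noncentral chi-square distribution
#'
#' Survival function \eqn{P(\chi^2_{df}(\lambda) > x)}, the tail-probability
#' engine behind the moderator-test power. At `ncp = 0` this is the central
#' chi-square upper tail; for `df = 1` it equals
#' \eqn{\Phi(\sqrt\lambda - \sqrt x) + \Phi(-\sqrt\lambda - \sqrt x)}.
#'
#' @param x Quantile (the critical value in power computations).
#' @param df Degrees of freedom, a positive integer.
#' @param ncp Noncentrality parameter, non-negative.
#' @return Probability in `[0, 1]`.
#' @export
noncentral_chisq_sf <- function(x, df, ncp = 0) {
  if (length(df) != 1L || !is.finite(df) || df < 1) {
    sp_stop("domain", "`df` must be a positive integer")
  }
  if (any(!is.finite(ncp)) || any(ncp < 0)) {
    sp_stop("domain", "`ncp` must be non-negative")
  }
  stats::pchisq(x, df = df, ncp = ncp, lower.tail = FALSE)
}

new_meta_power <- function(test, power, noncentrality, critical_value, df,
                           params) {
  structure(
    list(test = test, power = power, noncentrality = noncentrality,
         critical_value = critical_value, df = df, params = params),
    class = "meta_power"
  )
}

#' Power of the pooled-effect test in a random-effects meta-analysis
#'
#' Analytic power of the two-sided z-test that the pooled standardized mean
#' difference is zero, for a meta-analysis of `k` studies of `study_size`
#' participants each, with heterogeneity `i2`. The noncentrality is
#' \deqn{\lambda = \frac{|d|}{\sqrt{v^* / k}}, \qquad
#'  v^* = \frac{v(d)}{1 - I^2}}
#' and power is \eqn{1 - \Phi(z_{1-\alpha/2} - \lambda) +
#' \Phi(-z_{1-\alpha/2} - \lambda)}. tau-squared is treated as known
#' (Wald / noncentral framework); estimation error is explored only by the
#' simulator ([empirical_power()]).
#'
#' @param d True standardized mean difference between treatment and control.
#' @param study_size Total participants per study (even, >= 4).
#' @param k Number of studies; any positive real (fractional values arise
#'   from subgroup allocations).
#' @param i2 Heterogeneity I-squared, proportion scale, in `[0, 1)`.
#' @param alpha Two-sided significance level.
#' @return An object of class `"meta_power"` with elements `power`,
#'   `noncentrality`, `critical_value` (\eqn{z_{1-\alpha/2}}), `df`
#'   (`NA` for the z-test) and the echoed `params`.
#' @examples
#' power_main_effect(d = 0.5, study_size = 50, k = 6, i2 = 0.5)
#' @seealso [power_subgroup()], [required_k_main()]
#' @export
power_main_effect <- function(d, study_size, k, i2 = 0, alpha = 0.05) {
  check_k(k); check_alpha(alpha)
  vstar <- inflated_variance(d, study_size, i2)
  lambda <- abs(d) / sqrt(vstar / k)
  zcrit <- stats::qnorm(1 - alpha / 2)
  pow <- 1 - stats::pnorm(zcrit - lambda) + stats::pnorm(-zcrit - lambda)
  new_meta_power(
    test = "pooled-effect z-test (random effects)",
    power = pow, noncentrality = lambda, critical_value = zcrit, df = NA_integer_,
    params = list(d = d, study_size = study_size, k = k, i2 = i2, alpha = alpha)
  )
}

# Noncentrality of the between-group homogeneity statistic for fixed weights.
# Exposed internally so that invariance properties (e.g. location shifts with
# variances held fixed) can be checked directly.
qb_noncentrality <- function(effects, weights) {
  dbar <- sum(weights * effects) / sum(weights)
  sum(weights * (effects - dbar)^2)
}

#' Power of the between-subgroup (moderator) test
#'
#' Analytic power of the Q-between test that the pooled effects of `p`
#' subgroups are equal, in a random-effects meta-analysis with `k` studies of
#' `study_size` participants split over the subgroups in `proportions`.
#' Each subgroup contributes fixed weights
#' \eqn{w_j = k_j / v_j^*} with \eqn{k_j = p_j k} and
#' \eqn{v_j^* = v(d_j)/(1 - I^2)} (the subgroup's own true effect enters its
#' variance). The test statistic follows a noncentral chi-square with
#' `p - 1` degrees of freedom and noncentrality
#' \eqn{\lambda = \sum_j w_j (d_j - \bar d)^2}, \eqn{\bar d} the weighted
#' mean; power is its upper tail beyond the central critical value.
#'
#' Fractional per-subgroup study counts are allowed; integrality is a solver
#' concern ([required_k_subgroup()]).
#'
#' @param effects True standardized mean difference of each subgroup
#'   (length >= 2).
#' @param proportions Share of the `k` studies in each subgroup; strictly
#'   positive, summing to 1. Defaults to an even split.
#' @param study_size Total participants per study (even, >= 4).
#' @param k Total number of studies across subgroups (positive real).
#' @param i2 Heterogeneity I-squared, proportion scale.
#' @param alpha Significance level of the chi-square test.
#' @return An object of class `"meta_power"` with `power`, `noncentrality`,
#'   `critical_value` (central chi-square quantile), `df = p - 1` and the
#'   echoed `params`.
#' @examples
#' power_subgroup(c(0.1, 0.6), study_size = 50, k = 22, i2 = 0.5)
#' @export
power_subgroup <- function(effects, proportions = NULL, study_size, k,
                           i2 = 0, alpha = 0.05) {
  if (is.null(proportions)) {
    proportions <- rep(1 / length(effects), length(effects))
  }
  p <- check_subgroups(effects, proportions)
  check_k(k); check_alpha(alpha)
  kj <- proportions * k
  if (any(kj <= 0)) sp_stop("allocation", "every subgroup must receive a positive study count")
  vstar <- vapply(effects, inflated_variance, numeric(1),
                  study_size = study_size, i2 = i2)
  w <- kj / vstar
  lambda <- qb_noncentrality(effects, w)
  crit <- stats::qchisq(1 - alpha, df = p - 1)
  pow <- noncentral_chisq_sf(crit, df = p - 1, ncp = lambda)
  new_meta_power(
    test = sprintf("between-subgroup Q-test (df = %d, random effects)", p - 1L),
    power = pow, noncentrality = lambda, critical_value = crit, df = p - 1L,
    params = list(effects = effects, proportions = proportions,
                  study_size = study_size, k = k, i2 = i2, alpha = alpha)
  )
}

#' @export
print.meta_power <- function(x, digits = 4, ...) {
  cat("Meta-analysis power calculation\n\n")
  cat("  Test:         ", x$test, "\n", sep = "")
  pars <- x$params
  if (!is.null(pars$effects)) {
    cat("  Effects (SMD): ", paste(format(pars$effects), collapse = ", "), "\n", sep = "")
    cat("  Proportions:   ", paste(format(pars$proportions), collapse = ", "), "\n", sep = "")
  } else {
    cat("  Effect (SMD):  ", format(pars$d), "\n", sep = "")
  }
  cat("  Studies (k):   ", format(pars$k), "\n", sep = "")
  cat("  Study size:    ", pars$study_size, " (", pars$study_size / 2, " per arm)\n", sep = "")
  cat("  I-squared:     ", format(100 * pars$i2), "%\n", sep = "")
  cat("  alpha:         ", format(pars$alpha), "\n\n", sep = "")
  cat("  Noncentrality: ", format(x$noncentrality, digits = digits + 2), "\n", sep = "")
  if (!is.na(x$df)) cat("  df:            ", x$df, "\n", sep = "")
  cat("  Power:         ", format(round(x$power, digits)), "\n", sep = "")
  invisible(x)
}
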