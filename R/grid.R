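#' Required-studies grid over subgroup difference and allocation balance
#'
#' For every combination of a between-subgroup effect difference and an
#' allocation share of the larger subgroup, solves the smallest number of
#' studies giving `target_power` for the moderator test. Effects are
#' anchored at `base_effect`: a difference of `D` means subgroup effects
#' `(base_effect, base_effect + D)`; the allocation `p` means proportions
#' `(1 - p, p)`. Cells whose target cannot be reached (e.g. a zero
#' difference) are flagged, not fatal.
#'
#' @param differences Between-subgroup SMD differences, in `(0, 2]` (zero
#'   differences are accepted but flagged `not_achievable`).
#' @param proportions_largest Allocation share of the larger subgroup, each
#'   in `[0.5, 1)`.
#' @param base_effect Anchor: the smaller subgroup's true SMD. Default 0.1.
#' @inheritParams required_k_subgroup
#' @return A data frame of class `"power_grid"` with columns
#'   `smd_difference`, `proportion_largest`, `k_min`, `achieved_power`,
#'   `flag` (`"ok"` or `"not_achievable"`; `k_min` is `NA` when flagged).
#' @examples
#' required_k_grid(differences = c(0.5, 0.2), proportions_largest = c(0.5, 0.9),
#'                 study_size = 50, i2 = 0.5)
#' @export
required_k_grid <- function(differences, proportions_largest,
                            base_effect = 0.1, study_size, i2 = 0,
                            alpha = 0.05, target_power = 0.80,
                            constraint = c("any_integer", "even",
                                           "multiple_of_groups")) {
  constraint <- match.arg(constraint)
  if (any(proportions_largest < 0.5) || any(proportions_largest >= 1)) {
    sp_stop("domain", "`proportions_largest` must lie in [0.5, 1)")
  }
  cells <- expand.grid(smd_difference = differences,
                       proportion_largest = proportions_largest,
                       KEEP.OUT.ATTRS = FALSE)
  k_min <- integer(nrow(cells)); pow <- numeric(nrow(cells))
  flag <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    delta <- cells$smd_difference[i]
    p_lg <- cells$proportion_largest[i]
    res <- tryCatch(
      required_k_subgroup(effects = c(base_effect, base_effect + delta),
                          proportions = c(1 - p_lg, p_lg),
                          study_size = study_size, i2 = i2, alpha = alpha,
                          target_power = target_power, constraint = constraint),
      subpower_not_achievable = function(e) NULL,
      subpower_subgroup_spec = function(e) NULL)
    if (is.null(res)) {
      k_min[i] <- NA_integer_; pow[i] <- NA_real_; flag[i] <- "not_achievable"
    } else {
      k_min[i] <- res$k_min; pow[i] <- res$achieved_power; flag[i] <- "ok"
    }
  }
  out <- data.frame(cells, k_min = k_min, achieved_power = pow, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(base_effect = base_effect,
                              study_size = study_size, i2 = i2, alpha = alpha,
                              target_power = target_power,
                              constraint = constraint)
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Write a required-studies grid to CSV or JSON
#'
#' The design parameters of the grid (anchor, study size, I-squared, alpha,
#' target power, constraint) are embedded so that the file is
#' self-describing and can be read back into an identical object with
#' [read_power_grid()].
#'
#' @param grid A `"power_grid"` object from [required_k_grid()].
#' @param path Output file path.
#' @param format `"csv"` (RFC-4180, parameters in `# key: value` header
#'   comments) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_power_grid <- function(grid, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "power_grid"))
  params <- attr(grid, "params")
  if (format == "csv") {
    hdr <- sprintf("# %s: %s", names(params),
                   vapply(params, function(p) paste(format(p), collapse = " "),
                          character(1)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(as.data.frame(grid), con, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(params = params, rows = as.data.frame(grid)),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read back a required-studies grid written by [write_power_grid()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension when missing.
#' @return A `"power_grid"` object equal to the one written.
#' @export
read_power_grid <- function(path, format = c("csv", "json")) {
  if (length(format) > 1L) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format)
  num <- function(x) as.numeric(x)
  if (format == "csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
    params <- stats::setNames(
      lapply(kv, function(m) {
        v <- strsplit(m[3], " ")[[1]]
        if (all(grepl("^-?[0-9.eE+]+$", v))) num(v) else v
      }),
      vapply(kv, `[`, character(1), 2))
    df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                          stringsAsFactors = FALSE)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    params <- obj$params
    df <- obj$rows
  }
  df$k_min <- as.integer(df$k_min)
  attr(df, "params") <- params
  class(df) <- c("power_grid", "data.frame")
  df
}

#' @export
print.power_grid <- function(x, ...) {
  params <- attr(x, "params")
  cat(sprintf(
    "Required-studies grid (anchor %.2f, N = %d, I^2 = %.0f%%, alpha = %g, target %.2f, %s)\n",
    params$base_effect, as.integer(params$study_size), 100 * params$i2,
    params$alpha, params$target_power, params$constraint))
  print.data.frame(x, ...)
  invisible(x)
}

#' Heat-map of a required-studies grid
#'
#' Simple base-graphics image of `k_min` (log colour scale) over the
#' difference-by-allocation grid.
#'
#' @param x A `"power_grid"` object.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.power_grid <- function(x, ...) {
  d <- sort(unique(x$smd_difference))
  p <- sort(unique(x$proportion_largest))
  z <- matrix(NA_real_, length(d), length(p))
  for (i in seq_len(nrow(x))) {
    z[match(x$smd_difference[i], d), match(x$proportion_largest[i], p)] <-
      log10(x$k_min[i])
  }
  graphics::image(d, p, z, xlab = "SMD difference between subgroups",
                  ylab = "proportion of studies in larger subgroup",
                  main = "log10 studies needed", ...)
  invisible(x)
}
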