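#' Sampling variance of a standardized mean difference
#'
#' Large-sample variance of Cohen's d for a two-arm study with
#' `study_size` participants in total, split equally over the arms:
#' \deqn{v = \frac{n_1 + n_2}{n_1 n_2} + \frac{d^2}{2 (n_1 + n_2)},
#' \quad n_1 = n_2 = \mathrm{study\_size}/2.}
#' No small-sample (Hedges' g) correction is applied here; the analytic power
#' computations in this package are defined on this asymptotic variance. The
#' simulator applies the correction where effects are *estimated*.
#'
#' @param d True standardized mean difference (sign is irrelevant).
#' @param study_size Total participants per study (both arms combined);
#'   must be an even integer, at least 4.
#' @return The sampling variance, a positive scalar.
#' @examples
#' smd_variance(0.5, 50)  # 0.0825
#' @export
smd_variance <- function(d, study_size) {
  check_study_size(study_size)
  if (any(!is.finite(d))) sp_stop("domain", "`d` must be finite")
  n1 <- study_size / 2
  study_size / (n1 * n1) + d^2 / (2 * study_size)
}

#' Between-study variance implied by I-squared
#'
#' Inverts the definition of I-squared (the proportion of total variability in
#' effect estimates due to between-study heterogeneity rather than sampling
#' error) at a typical within-study variance `v`:
#' \deqn{\tau^2 = v \frac{I^2}{1 - I^2}}
#' so that \eqn{I^2 = \tau^2 / (\tau^2 + v)} holds exactly.
#'
#' @param i2 Heterogeneity on the proportion scale, in `[0, 1)`.
#' @param v Typical within-study sampling variance, positive.
#' @return The between-study variance tau-squared (non-negative scalar).
#' @examples
#' tau2_from_i2(0.5, 0.0825)  # equals v at I^2 = 50%
#' @export
tau2_from_i2 <- function(i2, v) {
  check_i2(i2)
  if (any(!is.finite(v)) || any(v <= 0)) sp_stop("domain", "`v` must be positive")
  v * i2 / (1 - i2)
}

#' Heterogeneity-inflated variance of a study's effect estimate
#'
#' Total variance of one study's estimate under a random-effects model,
#' `smd_variance(d, study_size) + tau2`, written as the inflation
#' \eqn{v / (1 - I^2)}. This is the variance entering every random-effects
#' power formula in the package.
#'
#' @inheritParams smd_variance
#' @inheritParams tau2_from_i2
#' @return Positive scalar, equal to `smd_variance(d, study_size)` when
#'   `i2 = 0`.
#' @examples
#' inflated_variance(0.5, 50, 0.5)  # 0.165
#' @export
inflated_variance <- function(d, study_size, i2) {
  check_i2(i2)
  smd_variance(d, study_size) / (1 - i2)
}
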