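# Independent closed-form oracles, written before the tests that use them.
# They deliberately re-derive every quantity from first principles (normal
# CDF arithmetic only) and never call into the package's power path.

oracle_v <- function(d, n) 4 / n + d^2 / (2 * n)

oracle_vstar <- function(d, n, i2) oracle_v(d, n) / (1 - i2)

# two-sided z-test power at known variance
oracle_power_z <- function(d, n, k, i2, alpha = 0.05) {
  lam <- abs(d) / sqrt(oracle_vstar(d, n, i2) / k)
  z <- qnorm(1 - alpha / 2)
  1 - pnorm(z - lam) + pnorm(-z - lam)
}

# between-group noncentrality from fixed weights
oracle_lambda <- function(effects, proportions, k, i2, n) {
  w <- proportions * k / oracle_vstar(effects, n, i2)
  dbar <- sum(w * effects) / sum(w)
  sum(w * (effects - dbar)^2)
}

# df = 1 noncentral chi-square upper tail via the normal CDF
oracle_tail_df1 <- function(x, lam) {
  pnorm(sqrt(lam) - sqrt(x)) + pnorm(-sqrt(lam) - sqrt(x))
}

oracle_power_df1 <- function(effects, proportions, k, i2, n, alpha = 0.05) {
  oracle_tail_df1(qchisq(1 - alpha, 1), oracle_lambda(effects, proportions, k, i2, n))
}

# solver minimality: achieved at k_min, not at one constraint step below
expect_minimal <- function(res, power_fn) {
  step <- switch(res$constraint, any_integer = 1, even = 2,
                 multiple_of_groups = length(res$params$effects))
  expect_gte(res$achieved_power, res$target_power)
  expect_identical(res$achieved_power, power_fn(res$k_min))
  if (res$k_min - step >= 2) {
    expect_lt(power_fn(res$k_min - step), res$target_power)
  }
}
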