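test_that("pooled-effect power matches the normal closed form", {
  # frozen from the independent oracle: lambda = 0.5 / sqrt(0.165/6) = 3.01511
  res <- power_main_effect(d = 0.5, study_size = 50, k = 6, i2 = 0.5)
  expect_equal(res$power, 0.8543218, tolerance = 1e-6)
  expect_equal(res$noncentrality, 3.015113, tolerance = 1e-6)
  expect_equal(res$critical_value, qnorm(0.975))
  # one study short of the 80% target
  expect_equal(power_main_effect(0.5, 50, 5, 0.5)$power, 0.7859507,
               tolerance = 1e-6)
  # zero effect: two-sided size alpha exactly
  expect_equal(power_main_effect(0, 50, 10, 0.5)$power, 0.05, tolerance = 1e-12)
  # oracle agreement across a grid
  for (d in c(0.2, 0.5, 1)) {
    for (k in c(3, 8, 40)) {
      for (i2 in c(0, 0.5, 0.9)) {
        expect_equal(power_main_effect(d, 50, k, i2)$power,
                     oracle_power_z(d, 50, k, i2), tolerance = 1e-12)
      }
    }
  }
})

test_that("subgroup Q-test power matches the df=1 closed form", {
  res <- power_subgroup(c(0.1, 0.6), c(0.5, 0.5), study_size = 50, k = 22,
                        i2 = 0.5)
  expect_equal(res$noncentrality, 8.399511, tolerance = 1e-6)
  expect_equal(res$power, 0.8259367, tolerance = 1e-6)
  expect_identical(res$df, 1L)
  expect_equal(res$critical_value, qchisq(0.95, 1))
  expect_equal(power_subgroup(c(0.1, 0.6), study_size = 50, k = 20,
                              i2 = 0.5)$power, 0.7891157, tolerance = 1e-6)
  # no between-group difference: lambda 0, power = alpha
  null <- power_subgroup(c(0.3, 0.3), c(0.4, 0.6), study_size = 50, k = 10,
                         i2 = 0.25)
  expect_equal(null$noncentrality, 0)
  expect_equal(null$power, 0.05, tolerance = 1e-9)
  # df = 1 equivalence with the two-sided z-test on the effect difference
  for (k in c(6, 22, 101)) {
    for (i2 in c(0, 0.5)) {
      for (pr in list(c(0.5, 0.5), c(0.2, 0.8))) {
        expect_equal(power_subgroup(c(0.1, 0.6), pr, 50, k, i2)$power,
                     oracle_power_df1(c(0.1, 0.6), pr, k, i2, 50),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("noncentral chi-square tail: central cases and df=1 closed form", {
  expect_equal(noncentral_chisq_sf(qchisq(0.95, 1), 1, 0), 0.05,
               tolerance = 1e-9)
  expect_equal(noncentral_chisq_sf(qchisq(0.95, 2), 2, 0), 0.05,
               tolerance = 1e-9)
  expect_equal(noncentral_chisq_sf(3.8415, 1, 8.3995), 0.8259,
               tolerance = 1e-4)
  for (x in c(0.5, 3.8415, 10)) {
    for (lam in c(0, 0.5, 2, 8.4, 25)) {
      expect_equal(noncentral_chisq_sf(x, 1, lam), oracle_tail_df1(x, lam),
                   tolerance = 1e-9)
    }
  }
  expect_error(noncentral_chisq_sf(1, 0, 1), class = "subpower_domain")
  expect_error(noncentral_chisq_sf(1, 1, -1), class = "subpower_domain")
})

test_that("power is monotone in k, difference, study size, I^2 and balance", {
  base <- function(k = 22, delta = 0.5, n = 50, i2 = 0.5, p = 0.5) {
    power_subgroup(c(0.1, 0.1 + delta), c(1 - p, p), n, k, i2)$power
  }
  expect_true(all(diff(vapply(c(5, 10, 20, 40, 80), function(k) base(k = k),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.1, 0.2, 0.4, 0.8), function(d) base(delta = d),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(c(20, 50, 100, 400), function(n) base(n = n),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0, 0.25, 0.5, 0.75, 0.9), function(h) base(i2 = h),
                              numeric(1))) < 0))
  # balanced allocation maximizes power when within-group variances are equal
  sym <- function(p) power_subgroup(c(-0.25, 0.25), c(1 - p, p), 50, 22, 0.5)$power
  p50 <- sym(0.5)
  for (p in c(0.55, 0.65, 0.75, 0.85, 0.95)) expect_lt(sym(p), p50)
})

test_that("noncentrality is shift-invariant when weights are held fixed", {
  w <- c(3.2, 5.1, 1.7)
  eff <- c(0.1, 0.4, 0.9)
  lam0 <- subpower:::qb_noncentrality(eff, w)
  for (shift in c(-1, 0.3, 2)) {
    expect_equal(subpower:::qb_noncentrality(eff + shift, w), lam0,
                 tolerance = 1e-9)
  }
})

test_that("per-group and common-tau2 heterogeneity conventions nearly agree", {
  # analytic side: each group's variance inflated by its own v_j / (1 - I^2);
  # simulation truth: one common tau2 at the mean within-study variance
  eff <- c(0.1, 0.6); kj <- c(11, 11); n <- 50; i2 <- 0.5
  lam_pergroup <- power_subgroup(eff, kj / sum(kj), n, sum(kj), i2)$noncentrality
  tau2_common <- tau2_from_i2(i2, mean(vapply(eff, smd_variance, numeric(1), n)))
  w <- kj / (vapply(eff, smd_variance, numeric(1), n) + tau2_common)
  lam_common <- subpower:::qb_noncentrality(eff, w)
  expect_lt(abs(lam_pergroup - lam_common), 0.005)
})

test_that("invalid subgroup specifications raise typed errors", {
  expect_error(power_subgroup(c(0.5), c(1), 50, 10), class = "subpower_subgroup_spec")
  expect_error(power_subgroup(c(0.1, 0.6), c(0.3, 0.8), 50, 10),
               class = "subpower_subgroup_spec")
  expect_error(power_subgroup(c(0.1, 0.6), c(0.5, 0.5), 50, -2),
               class = "subpower_invalid_design")
  expect_error(power_main_effect(0.5, 50, 6, 0.5, alpha = 1.2),
               class = "subpower_domain")
})
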