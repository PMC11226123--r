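test_that("the Weinberg rule converts pair counts into mixture coefficients", {
  w <- weinberg(22331, 11619)
  expect_equal(round(w$gamma, 2), 0.74)
  expect_equal(w$p_mz, (22331 - 11619) / 22331)
  expect_equal(w$delta_same_sex, w$p_mz + 0.25 * (1 - w$p_mz))
  # all-DZ and all-MZ limits
  expect_equal(weinberg(5000, 5000)$gamma, 0.5)
  expect_equal(weinberg(5000, 0)$gamma, 1)
  expect_warning(clipped <- weinberg(100, 150), "clipped")
  expect_equal(clipped$p_mz, 0)
  expect_equal(clipped$gamma, 0.5)
})

test_that("expected pair correlations follow the model algebra", {
  w <- weinberg(22331, 11619)
  expect_equal(expected_pair_correlation("ACE", 0.57, 0, kappa = w$gamma),
               w$gamma * 0.57)
  expect_equal(expected_pair_correlation("ACE", 0.57, 0, kappa = 0.5),
               0.285)
  expect_equal(expected_pair_correlation("ADE", 0, 1, kappa = 0.5,
                                         delta = 0.25), 0.25)
})

test_that("the method-of-moments solver inverts forward-generated correlations", {
  expect_equal(mom_decompose(0.4218, 0.285, 0.74),
               c(a2 = 0.57, c2 = 0, e2 = 0.43), tolerance = 1e-10)
  # equal group correlations leave no genetic signal
  expect_equal(unname(mom_decompose(0.3, 0.3, 0.74)["a2"]), 0)
  expect_equal(unname(mom_decompose(0.3, 0.3, 0.74)["c2"]), 0.3)
  # maximal heritability
  expect_equal(unname(mom_decompose(0.74, 0.5, 0.74)["a2"]), 1)
  # ADE system round-trips
  w <- weinberg(22331, 11619)
  r_ss <- w$gamma * 0.4 + w$delta_same_sex * 0.2
  r_os <- 0.5 * 0.4 + 0.25 * 0.2
  expect_equal(mom_decompose(r_ss, r_os, w, model = "ADE"),
               c(a2 = 0.4, d2 = 0.2, e2 = 0.4), tolerance = 1e-10)
  expect_error(mom_decompose(0.3, 0.2, 0.5), "unidentified")
})

test_that("method-of-moments heritability is monotone in the same-sex correlation", {
  r_ss <- seq(0.3, 0.7, by = 0.05)
  a2 <- vapply(r_ss, function(r)
    unname(mom_decompose(r, 0.285, 0.74)["a2"]), numeric(1))
  expect_true(all(diff(a2) > 0))
})

test_that("ML fit on exact model tables matches the closed-form solution", {
  w <- weinberg(22331, 11619)
  tau <- liability_threshold(0.17)
  tb <- exact_ace_tables(0.57, 0, w, tau, 1e5)
  fit <- fit_biometric(tb, gamma = w)
  expect_equal(fit$a2, 0.57, tolerance = 5e-3)
  expect_equal(fit$c2_or_d2, 0, tolerance = 5e-3)
  expect_equal(fit$tau[1], tau, tolerance = 5e-3)
  # agreement with method of moments applied to per-group tetrachorics
  r_hat <- vapply(1:2, function(i)
    fit_tetrachoric(tb[i, , drop = FALSE])$rho, numeric(1))
  mom <- mom_decompose(r_hat[1], r_hat[2], w)
  expect_equal(fit$a2, unname(mom["a2"]), tolerance = 5e-3)

  # an interior truth with shared environment
  tb2 <- exact_ace_tables(0.4, 0.2, w, tau, 1e5)
  fit2 <- fit_biometric(tb2, gamma = w)
  expect_equal(fit2$a2, 0.4, tolerance = 5e-3)
  expect_equal(fit2$c2_or_d2, 0.2, tolerance = 5e-3)
})

test_that("equal group correlations attribute everything to shared environment", {
  tau <- liability_threshold(0.17)
  tb <- rbind(exact_table(0.3, tau, 5e4, "same_sex"),
              exact_table(0.3, tau, 5e4, "opposite_sex"))
  fit <- fit_biometric(tb, gamma = 0.74)
  expect_equal(fit$a2, 0, tolerance = 5e-3)
  expect_equal(fit$c2_or_d2, 0.3, tolerance = 5e-3)
})

test_that("ADE fits recover dominance structure from exact tables", {
  w <- weinberg(22331, 11619)
  tau <- liability_threshold(0.17)
  r_ss <- w$gamma * 0.4 + w$delta_same_sex * 0.2
  r_os <- 0.5 * 0.4 + 0.25 * 0.2
  tb <- rbind(exact_table(r_ss, tau, 1e5, "same_sex"),
              exact_table(r_os, tau, 1e5, "opposite_sex"))
  fit <- fit_biometric(tb, model = "ADE", gamma = w)
  expect_equal(fit$a2, 0.4, tolerance = 5e-3)
  expect_equal(fit$c2_or_d2, 0.2, tolerance = 5e-3)
})

test_that("every fit satisfies the standardization identity exactly", {
  set.seed(19)
  for (i in 1:5) {
    d <- simulate_pairs(1500, 3000, a2 = runif(1, 0.2, 0.7),
                        c2 = runif(1, 0, 0.2), prevalence = 0.17)
    fit <- fit_biometric(d)
    expect_lt(abs(fit$a2 + fit$c2_or_d2 + fit$e2 - 1),
              4 * .Machine$double.eps)
    expect_true(all(c(fit$a2, fit$c2_or_d2, fit$e2) >= 0))
    expect_true(all(c(fit$a2, fit$c2_or_d2, fit$e2) <= 1))
  }
})

test_that("the free shared-environment model nests the AE model", {
  d <- simulate_pairs(3000, 6000, a2 = 0.5, c2 = 0.15, prevalence = 0.17,
                      seed = 23)
  ace <- fit_biometric(d, model = "ACE")
  ae <- fit_biometric(d, model = "AE")
  expect_gte(ace$loglik, ae$loglik - 1e-6)
  expect_identical(ae$c2_or_d2, 0)
})

test_that("identifiability failures are reported, not silently fitted", {
  d <- simulate_pairs(1000, 2000, a2 = 0.5, prevalence = 0.17, seed = 4)
  only_ss <- d[d$group == "same_sex", ]
  expect_error(fit_biometric(only_ss), "twin_sibling")
  expect_error(fit_biometric(d, gamma = 0.5), "not identifiable")
})

test_that("the twin-sibling design fits single-sex style data", {
  set.seed(55)
  d <- simulate_pairs(10000, 20000, n_sib = 20000, a2 = 0.4, c2 = 0.25,
                      prevalence = 0.17)
  fit <- fit_biometric(d, design = "twin_sibling", gamma = 0.75)
  expect_equal(fit$a2, 0.4, tolerance = 0.1)
  expect_equal(fit$c2_or_d2, 0.25, tolerance = 0.08)
  expect_setequal(fit$groups, c("same_sex", "sibling"))
  # lowering the sibling shared-environment coefficient changes the fit
  fit_lo <- fit_biometric(d, design = "twin_sibling", gamma = 0.75,
                          sibling_c = 0.8)
  expect_false(isTRUE(all.equal(fit$loglik, fit_lo$loglik)))
})

test_that("group-specific thresholds are available behind a flag", {
  d <- simulate_pairs(2000, 4000, a2 = 0.5, prevalence = 0.17, seed = 61)
  shared <- fit_biometric(d)
  free <- fit_biometric(d, tau_by_group = TRUE)
  expect_length(shared$tau, 1)
  expect_length(free$tau, 2)
  expect_gte(free$loglik, shared$loglik - 1e-6)
})

test_that("model object methods expose the fit consistently", {
  d <- simulate_pairs(2000, 4000, a2 = 0.6, c2 = 0.1, prevalence = 0.17,
                      seed = 71)
  fit <- fit_biometric(d)
  expect_named(coef(fit), c("a2", "c2", "e2"))
  expect_equal(unname(sum(coef(fit))), 1)
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$loglik)
  expect_true(is.matrix(vcov(fit)))
  ci_w <- confint(fit, parm = "a2")
  expect_true(ci_w[1, "lower"] < fit$a2 && fit$a2 < ci_w[1, "upper"])
  ci_p <- confint(fit, parm = "a2", type = "profile")
  expect_true(ci_p[1, "lower"] < fit$a2 && fit$a2 < ci_p[1, "upper"])
  expect_output(print(summary(fit)), "Components")
})
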