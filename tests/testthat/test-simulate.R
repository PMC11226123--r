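test_that("pair liability correlation follows the biometric expectation", {
  expect_equal(pair_liability_correlation(0.6, 0.1, kappa = 1), 0.7)
  expect_equal(pair_liability_correlation(0.6, 0.1, kappa = 0.5), 0.4)
  expect_equal(pair_liability_correlation(0.5, 0, 0.2, kappa = 0.5,
                                          delta = 0.25), 0.30)
  expect_error(pair_liability_correlation(0.8, 0.3), "a2 \\+ c2")
})

test_that("marginal phenotype frequency converges to the prevalence", {
  d <- simulate_pairs(n_mz = 5000, n_dz = 10000, a2 = 0.5, c2 = 0.1,
                      prevalence = 0.17, seed = 101)
  phat <- mean(c(d$pheno_1, d$pheno_2))
  # binomial tolerance: 4 sd at n = 30,000 individuals (correlated pairs
  # roughly double the variance)
  expect_lt(abs(phat - 0.17), 4 * sqrt(2 * 0.17 * 0.83 / 30000))
})

test_that("uncorrelated liabilities give independent Bernoulli phenotypes", {
  d <- simulate_pairs(n_mz = 0, n_dz = 10000, a2 = 0, c2 = 0,
                      prevalence = 0.5, seed = 7)
  tb <- aggregate_pairs(d)
  counts <- as.numeric(colSums(tb[, c("n00", "n01", "n10", "n11")]))
  expect_true(all(abs(counts - 2500) < 4 * sqrt(10000 * 0.25 * 0.75)))
  expect_lt(abs(cor(d$pheno_1, d$pheno_2)), 0.035)
})

test_that("group sizes reproduce the registry design in expectation", {
  d <- simulate_pairs(n_mz = 10712, n_dz = 23238, a2 = 0.57, c2 = 0,
                      prevalence = 0.17, dz_opposite_sex_prob = 0.5,
                      seed = 3)
  n_ss <- sum(d$group == "same_sex")
  n_os <- sum(d$group == "opposite_sex")
  sd_binom <- sqrt(23238 * 0.25)
  expect_lt(abs(n_ss - 22331), 4 * sd_binom)
  expect_lt(abs(n_os - 11619), 4 * sd_binom)
  expect_true(all(d$sex_pair[d$group == "opposite_sex"] == "MF"))
  expect_true(all(d$sex_pair[d$group != "opposite_sex"] %in% c("MM", "FF")))
})

test_that("seeds make the generator reproducible and distinct", {
  a <- simulate_pairs(100, 200, a2 = 0.4, prevalence = 0.2, seed = 11)
  b <- simulate_pairs(100, 200, a2 = 0.4, prevalence = 0.2, seed = 11)
  c <- simulate_pairs(100, 200, a2 = 0.4, prevalence = 0.2, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("hidden truth columns appear only under the debug flag", {
  d <- simulate_pairs(500, 500, a2 = 0.6, prevalence = 0.17, seed = 5)
  expect_false(any(c("zygosity", "liab_1", "liab_2") %in% names(d)))
  dd <- simulate_pairs(500, 500, a2 = 0.6, prevalence = 0.17, seed = 5,
                       debug = TRUE)
  expect_true(all(c("zygosity", "liab_1", "liab_2") %in% names(dd)))
  # latent liability correlation by true zygosity matches the model
  r_mz <- cor(dd$liab_1[dd$zygosity == "mz"], dd$liab_2[dd$zygosity == "mz"])
  r_dz <- cor(dd$liab_1[dd$zygosity == "dz"], dd$liab_2[dd$zygosity == "dz"])
  expect_equal(r_mz, 0.6, tolerance = 0.12)
  expect_equal(r_dz, 0.3, tolerance = 0.2)
})

test_that("tetrachoric within true zygosity class recovers the liability correlation", {
  dd <- simulate_pairs(20000, 20000, a2 = 0.6, c2 = 0.1,
                       prevalence = 0.17, seed = 31, debug = TRUE)
  for (z in c("mz", "dz")) {
    sub <- dd[dd$zygosity == z, ]
    tb <- aggregate_pairs(sub)  # dz pairs span both observed groups
    fit <- fit_tetrachoric(colSums(tb[, c("n00", "n01", "n10", "n11")]))
    truth <- if (z == "mz") 0.7 else 0.4
    expect_equal(fit$rho, truth, tolerance = 0.05)
  }
})

test_that("member order is exchangeable for downstream statistics", {
  d <- simulate_pairs(2000, 2000, a2 = 0.5, c2 = 0.1, prevalence = 0.17,
                      seed = 13)
  swapped <- d
  swapped$pheno_1 <- d$pheno_2
  swapped$pheno_2 <- d$pheno_1
  expect_equal(aggregate_pairs(d), aggregate_pairs(swapped))
})

test_that("strata overrides change only the targeted parameters", {
  d <- simulate_pairs(4000, 8000, a2 = 0.6, c2 = 0, prevalence = 0.17,
                      strata = list(low = list(a2 = 0.7),
                                    high = list(a2 = 0.3,
                                                prevalence = 0.3)),
                      seed = 9)
  expect_setequal(unique(d$stratum), c("low", "high"))
  expect_equal(sum(d$stratum == "low"), sum(d$stratum == "high"))
  p_high <- mean(c(d$pheno_1[d$stratum == "high"],
                   d$pheno_2[d$stratum == "high"]))
  p_low <- mean(c(d$pheno_1[d$stratum == "low"],
                  d$pheno_2[d$stratum == "low"]))
  expect_gt(p_high, p_low + 0.05)
  expect_error(
    simulate_pairs(10, 10, a2 = 0.5, strata = list(x = list(h2 = 1))),
    "unknown stratum override")
})

test_that("an empty design yields an empty data set with a warning", {
  expect_warning(d <- simulate_pairs(0, 0, 0, a2 = 0.5, prevalence = 0.17),
                 "zero pairs")
  expect_equal(nrow(d), 0)
  expect_true(all(c("pair_id", "group", "pheno_1", "pheno_2") %in% names(d)))
})
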