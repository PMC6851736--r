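test_that("zero-noise generation reproduces the translog polynomial exactly", {
  s <- strata_config(2, 5, 1, years = 2012:2014)  # 10 groups x 3 years
  tr <- synthetic_truth(s, fe_sd = 0, noise_sd = 0)
  gen <- generate_panel(s, tr, seed = 11)
  p <- gen$panel
  logC <- log(p$true_corrected_eur)
  logN <- log(p$patients)
  # independent evaluation of the log-polynomial
  poly <- tr$constant + tr$trend * p$time_index +
    tr$c1 * logC + tr$c2 * logC^2 + tr$d1 * logN + tr$d2 * logN^2 +
    tr$c3 * logC * logN
  expect_equal(log(p$true_qaly_loss), poly, tolerance = 1e-12)
})

test_that("spending equals corrected spending when no one dies", {
  s <- small_strata()
  tr <- synthetic_truth(s, death_rates = rep(0, s$n_age_bands))
  gen <- generate_panel(s, tr, seed = 5)
  expect_identical(gen$panel$deaths, rep(0L, nrow(gen$panel)))
  expect_equal(gen$panel$spending_eur, gen$panel$true_corrected_eur)
})

test_that("last-year-of-life reconstruction identity holds on every cell", {
  for (seed in c(1, 42)) {
    fx <- small_generation(seed = seed)
    lyol <- lyol_total(fx$gen$panel, fx$truth$life_table)
    expect_equal(fx$gen$panel$spending_eur - lyol,
                 fx$gen$panel$true_corrected_eur, tolerance = 1e-9)
  }
})

test_that("generation is bit-identical under the same seed", {
  s <- small_strata()
  tr <- synthetic_truth(s)
  expect_identical(generate_panel(s, tr, seed = 9),
                   generate_panel(s, tr, seed = 9))
  expect_false(identical(generate_panel(s, tr, seed = 9)$panel,
                         generate_panel(s, tr, seed = 10)$panel))
  expect_identical(generate_questionnaires(s, tr, 20, seed = 3),
                   generate_questionnaires(s, tr, 20, seed = 3))
})

test_that("questionnaire sample reproduces the planted utility structure", {
  s <- small_strata(n_age_bands = 3)
  tf <- fixture_tariff()
  # no gap, no trend: patients and non-patients coincide in expectation
  tr0 <- synthetic_truth(s, utility_gap = 0, utility_trend = 0)
  q0 <- generate_questionnaires(s, tr0, 800, seed = 2, tariff = tf)
  u0 <- score_eq5d(q0[, c("mo", "sc", "ua", "pd", "ad")], tf)
  gap0 <- mean(u0[q0$visited_hospital == 0]) -
    mean(u0[q0$visited_hospital == 1])
  se0 <- sqrt(stats::var(u0) * (1 / sum(q0$visited_hospital == 0) +
                                  1 / sum(q0$visited_hospital == 1)))
  expect_lt(abs(gap0), 3 * se0)

  # planted gap of 0.1 recovered within Monte Carlo error
  tr1 <- synthetic_truth(s, utility_gap = 0.1, utility_trend = 0)
  q1 <- generate_questionnaires(s, tr1, 800, seed = 2, tariff = tf)
  u1 <- score_eq5d(q1[, c("mo", "sc", "ua", "pd", "ad")], tf)
  gap1 <- mean(u1[q1$visited_hospital == 0]) -
    mean(u1[q1$visited_hospital == 1])
  se1 <- sqrt(stats::var(u1) * (1 / sum(q1$visited_hospital == 0) +
                                  1 / sum(q1$visited_hospital == 1)))
  expect_lt(abs(gap1 - 0.1), 2 * se1 + 0.01)
})

test_that("invalid truth parameters are rejected", {
  s <- small_strata()
  expect_error(synthetic_truth(s, noise_sd = -1), "dispersion")
  expect_error(synthetic_truth(s, death_rates = rep(1.5, s$n_age_bands)),
               "death_rates")
  expect_error(synthetic_truth(s, bod = rep(2, s$n_diseases)), "\\[0, 1\\]")
  # positive elasticity at the means violates diminishing returns
  expect_error(synthetic_truth(s, c1 = 0.5, c2 = 0, c3 = 0), "negative")
})

test_that("simulate_inputs writes a consistent, re-readable input set", {
  dirp <- withr::local_tempdir()
  s <- small_strata(n_diseases = 5)
  res <- simulate_inputs(dirp, s, seed = 3, n_per_stratum = 10)
  expect_true(all(file.exists(unlist(res[c("claims", "questionnaires",
                                           "life_table", "burden",
                                           "tariff", "truth")]))))
  claims <- read.csv(res$claims)
  expect_identical(nrow(claims), nrow(res$panel))
  expect_true(all(claims$deaths <= claims$patients))
  q <- read.csv(res$questionnaires)
  expect_true(all(unlist(q[, c("mo", "sc", "ua", "pd", "ad")]) %in% 1:3))
})
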