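test_that("design matrix holds the log-polynomial regressors", {
  pan <- manual_outcome_panel(data.frame(
    group_id = rep(c("a", "b"), each = 3),
    year = rep(2012:2014, 2),
    qaly_loss = exp(1),
    corrected_eur = exp(10), patients = round(exp(5))))
  d <- build_design(pan)
  expect_equal(unique(d$logC), 10)
  expect_equal(unique(d$logC_sq), 100)
  expect_equal(d$logN, rep(log(round(exp(5))), 6))
  expect_equal(unique(d$logC_logN), 10 * log(round(exp(5))))
  expect_identical(sort(unique(d$time_index)), c(0L, 1L, 2L))
})

test_that("excluded cells never reach the design matrix", {
  pan <- manual_outcome_panel(data.frame(
    group_id = rep(c("a", "b"), each = 3),
    year = rep(2012:2014, 2),
    qaly_loss = c(2, 2, 2, 2, 2, -1),
    corrected_eur = 100, patients = 10,
    excluded = c(rep(FALSE, 5), TRUE),
    exclude_reason = c(rep(NA, 5), "nonpositive outcome")))
  d <- build_design(pan)
  expect_identical(nrow(d), 5L)
  # a nonpositive value slipping through the flag is an internal error
  pan2 <- pan
  pan2$excluded[6] <- FALSE
  pan2$qaly_loss[6] <- 1  # make constructor pass, then corrupt
  pan2$qaly_loss[6] <- -1
  expect_error(build_design(pan2), "internal error")
})

test_that("groups reduced to one observation drop from the within fit", {
  pan <- manual_outcome_panel(data.frame(
    group_id = c("a", "a", "a", "b", "c", "c"),
    year = c(2012:2014, 2012, 2012:2013),
    qaly_loss = c(2, 3, 4, 5, 6, 7),
    corrected_eur = c(10, 20, 30, 40, 50, 60) * 1e3,
    patients = c(5, 6, 7, 8, 9, 10)))
  d <- build_design(pan)
  expect_false("b" %in% d$group_id)
  expect_identical(attr(d, "n_singleton_groups"), 1L)
})

test_that("within estimator is numerically identical to LSDV", {
  fx <- small_generation(seed = 13, n_diseases = 1)  # 10 groups x 3 years
  d <- build_design(fx$panel)
  fit <- fit_fixed_effects(d)
  lsdv <- stats::lm(logQ ~ 0 + time_index + logC + logC_sq + logN +
                      logN_sq + logC_logN + factor(group_id), data = d)
  expect_lt(max(abs(stats::coef(lsdv)[1:6] - fit$coefficients)), 1e-8)
  # and the conventional SEs agree too (same absorbed-dummy df)
  se_lsdv <- sqrt(diag(stats::vcov(lsdv)))[1:6]
  expect_lt(max(abs(se_lsdv - sqrt(diag(fit$vcov)))), 1e-8)
})

test_that("zero-noise panels identify the generator coefficients exactly", {
  fx <- small_generation(seed = 4, fe_sd = 0.3, noise_sd = 0)
  fit <- fit_fixed_effects(build_design(fx$panel))
  tr <- fx$truth
  truthv <- c(time_index = tr$trend, logC = tr$c1, logC_sq = tr$c2,
              logN = tr$d1, logN_sq = tr$d2, logC_logN = tr$c3)
  expect_lt(max(abs(fit$coefficients - truthv[names(fit$coefficients)])),
            1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("perfect collinearity is reported with the offending column", {
  pan <- manual_outcome_panel(data.frame(
    group_id = rep(c("a", "b", "c"), each = 3),
    year = rep(2012:2014, 3),
    qaly_loss = exp(rnorm(9)),
    corrected_eur = rep(c(1e4, 2e4, 3e4), 3),  # same within-path per group
    patients = 10))                            # constant => collinear
  d <- build_design(pan)
  expect_error(fit_fixed_effects(d), "singular|collinear")
})

test_that("elasticity evaluation follows the quadratic-coefficient convention", {
  expect_identical(elasticity_at(c(c1 = 0, c2 = 0, c3 = 0), 11, 5), 0)
  expect_identical(elasticity_at(c(c1 = -0.1, c2 = 0, c3 = 0), 3, 99),
                   -0.1)
  e <- elasticity_at(c(c1 = -0.0461, c2 = 0.0033, c3 = -0.0372),
                     11.97, 5.10)
  expect_equal(e, -0.0461 + 2 * 0.0033 * 11.97 - 0.0372 * 5.10)
})

test_that("elasticity is invariant to rescaling the spending units", {
  fx <- small_generation(seed = 17)
  m <- qalythreshold:::panel_means(fx$panel)
  fit <- fit_fixed_effects(build_design(fx$panel))
  e_eur <- elasticity_at(fit, m$mean_logC, m$mean_logN)
  pan_k <- fx$panel
  pan_k$corrected_eur <- pan_k$corrected_eur / 1000  # EUR -> kEUR
  mk <- qalythreshold:::panel_means(pan_k)
  fit_k <- fit_fixed_effects(build_design(pan_k))
  e_keur <- elasticity_at(fit_k, mk$mean_logC, mk$mean_logN)
  expect_equal(e_eur, e_keur, tolerance = 1e-8)
})

test_that("threshold formula is homogeneous and guards its domain", {
  t1 <- qaly_threshold(-1, 100, 100)
  expect_equal(t1$threshold, 1)
  t2 <- qaly_threshold(-0.2, 50, 1e6)
  expect_equal(qaly_threshold(-0.2, 50, 2e6)$threshold, 2 * t2$threshold)
  expect_gt(t2$threshold, 0)
  expect_equal(t2$gain_per_1pct, 0.2 / 100 * 50)
  expect_error(qaly_threshold(0.1, 100, 100), "non-negative elasticity")
  expect_error(qaly_threshold(-0.1, 0, 100), "positive")
})

test_that("cluster bootstrap is seeded and collapses under zero noise", {
  fx0 <- small_generation(seed = 6, fe_sd = 0.3, noise_sd = 0)
  b0 <- bootstrap_threshold(fx0$panel, reps = 10, seed = 2)
  expect_equal(b0$se, 0, tolerance = 1e-8)
  expect_equal(b0$ci_normal[1], b0$ci_normal[2], tolerance = 1e-4)

  fx <- small_generation(seed = 6)
  b1 <- bootstrap_threshold(fx$panel, reps = 15, seed = 3)
  b2 <- bootstrap_threshold(fx$panel, reps = 15, seed = 3)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$se, b2$se)
  expect_gt(b1$se, 0)
  expect_true(b1$ci_normal[1] <= b1$threshold &
                b1$threshold <= b1$ci_normal[2])
})

test_that("a single-stratum stratifier reproduces the pooled estimate", {
  fx <- small_generation(seed = 19)
  pan <- fx$panel
  pan$gender <- 1L  # collapse to one stratum
  class(pan) <- class(fx$panel)
  sub <- subgroup_thresholds(pan, "gender")
  pooled <- estimate_threshold(pan)
  expect_identical(nrow(sub), 1L)
  expect_equal(sub$elasticity, pooled$elasticity, tolerance = 1e-12)
  expect_equal(sub$threshold, pooled$threshold, tolerance = 1e-12)
})

test_that("homogeneous truth gives comparable subgroup thresholds", {
  fx <- small_generation(seed = 23, n_diseases = 40)
  sub <- subgroup_thresholds(fx$panel, "gender")
  expect_identical(sub$status, rep("ok", 2))
  expect_lt(abs(log(sub$threshold[1] / sub$threshold[2])), log(2.5))
  # refit variant runs and flags nothing on this healthy panel
  sub_r <- subgroup_thresholds(fx$panel, "gender", refit = TRUE)
  expect_identical(sub_r$status, rep("ok", 2))
})

test_that("Cobb-Douglas agrees with the translog when curvature is absent", {
  s <- small_strata(n_diseases = 60)
  tr <- synthetic_truth(s, c1 = -0.15, c2 = 0, c3 = 0, noise_sd = 0.02)
  pan <- latent_outcome_panel(generate_panel(s, tr, seed = 31))
  cd <- alternative_spec(pan, spec = "cobb_douglas")
  tl <- estimate_threshold(pan)
  expect_lt(abs(cd$elasticity - (-0.15)), 0.02)
  expect_lt(abs(cd$elasticity - tl$elasticity), 0.02)
})

test_that("linear specification recovers a linear marginal effect", {
  # levels-generated data: Q = a_i - b C + c N + tiny noise
  set.seed(99)
  G <- 60
  b <- 2e-4
  df <- expand.grid(g = seq_len(G), year = 2012:2014)
  a_i <- runif(G, 500, 700)[df$g]
  C <- runif(nrow(df), 5e5, 2e6)
  N <- round(runif(nrow(df), 50, 500))
  Q <- a_i - b * C + 0.05 * N + rnorm(nrow(df), 0, 0.5)
  pan <- manual_outcome_panel(data.frame(
    group_id = paste0("g", df$g), year = df$year,
    qaly_loss = Q, corrected_eur = C, patients = N))
  lin <- alternative_spec(pan, spec = "linear")
  expect_lt(abs(lin$marginal_effect - (-b)) / b, 0.05)
  expect_lt(abs(lin$threshold - 1 / b) / (1 / b), 0.05)
})

test_that("time dummies reproduce a linear trend as multiples", {
  s <- small_strata(n_diseases = 30)
  tr <- synthetic_truth(s, noise_sd = 0.01)
  pan <- latent_outcome_panel(generate_panel(s, tr, seed = 37))
  td <- alternative_spec(pan, time_dummies = TRUE)
  cf <- td$fit$coefficients
  expect_lt(abs(cf[["year_2013"]] - tr$trend), 0.005)
  expect_lt(abs(cf[["year_2014"]] - 2 * tr$trend), 0.005)
})

test_that("outcome swaps and the spending lag behave as specified", {
  fx <- small_generation(seed = 41, n_diseases = 30)
  lag <- alternative_spec(fx$panel, lagged_spending = TRUE)
  # one panel year is consumed by the lag
  expect_lt(lag$fit$n, estimate_threshold(fx$panel)$fit$n)
  pan2 <- fx$panel[fx$panel$year < 2014, ]
  class(pan2) <- class(fx$panel)
  expect_error(alternative_spec(pan2, lagged_spending = TRUE), ">= 3")
  mort <- alternative_spec(fx$panel, outcome = "mortality_counts")
  expect_s3_class(mort, "threshold_estimate")
})

test_that("proportional death reattribution conserves totals", {
  # all spending on the primary diagnosis: attribution unchanged
  expect_equal(reattribute_deaths_proportional(c(10, 20), diag(2)),
               c(10, 20))
  sh <- matrix(c(0.7, 0.3), 1, dimnames = list(NULL, c("u1", "u2")))
  expect_equal(reattribute_deaths_proportional(100, sh),
               c(u1 = 70, u2 = 30))
  # conservation for arbitrary share matrices
  set.seed(5)
  S <- matrix(runif(12), 3, 4)
  S <- S / rowSums(S)
  d <- c(13, 7, 111)
  expect_equal(sum(reattribute_deaths_proportional(d, S)), sum(d))
  Sbad <- S; Sbad[1, 1] <- Sbad[1, 1] + 0.01
  expect_error(reattribute_deaths_proportional(d, Sbad), "sum to 1")
})
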