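# shared small constructed-pipeline world for Monte Carlo tests
mc_world <- function(seed = 51, n_diseases = 6, n_age_bands = 4,
                     degenerate = FALSE) {
  s <- strata_config(2, n_age_bands, n_diseases)
  lt <- synthetic_life_table(s)
  if (degenerate) {
    lt$hle_sd <- 0
    lt$lyol_sd <- 0
  }
  tr <- synthetic_truth(s, life_table = lt)
  gen <- generate_panel(s, tr, seed = seed)
  q <- generate_questionnaires(s, tr, 150, seed = seed)
  est <- estimate_morbidity_gap(q, fixture_tariff())
  if (degenerate) {
    est$gap_se[] <- 0
    est$trend_se[] <- 0
  }
  claims <- gen$panel[, c("group_id", "gender", "age_band", "disease",
                          "year", "patients", "deaths", "spending_eur")]
  burden <- data.frame(disease = seq_len(s$n_diseases),
                       bod = ifelse(is.na(tr$bod), NA, tr$bod),
                       bod_available = as.integer(!is.na(tr$bod)))
  list(strata = s, truth = tr, claims = claims, est = est,
       life_table = lt, burden = burden)
}

test_that("degenerate distributions reproduce the point estimate on every draw", {
  w <- mc_world(degenerate = TRUE)
  cfg <- mc_config(n_draws = 5, seed = 3, freeze = "bod")
  res <- run_monte_carlo(w$claims, w$est, w$life_table, w$burden, cfg,
                         one_at_a_time = FALSE)
  expect_equal(unname(res$draws[, "combined"]),
               rep(res$point$threshold, 5), tolerance = 1e-12)
  expect_equal(res$summary$se, 0)
})

test_that("Monte Carlo results are reproducible under a fixed seed", {
  w <- mc_world()
  cfg <- mc_config(n_draws = 8, seed = 7)
  r1 <- run_monte_carlo(w$claims, w$est, w$life_table, w$burden, cfg)
  r2 <- run_monte_carlo(w$claims, w$est, w$life_table, w$burden, cfg)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_monte_carlo(w$claims, w$est, w$life_table, w$burden,
                        mc_config(n_draws = 8, seed = 8))
  expect_false(identical(r1$draws, r3$draws))
})

test_that("parameter draws respect their admissible supports", {
  w <- mc_world()
  cfg <- mc_config(n_draws = 1, seed = 1)
  b0 <- resolve_bod(w$burden, w$burden$disease)
  for (i in 1:40) {
    par <- draw_parameters(list(morbidity_est = w$est,
                                life_table = w$life_table,
                                burden = w$burden), cfg, i)
    expect_true(all(par$life_table$hle_years >= 0))
    expect_true(all(par$life_table$lyol_cost_eur >= 0))
    expect_true(all(par$burden$bod >= b0 - 1e-12 &
                      par$burden$bod <= 1 + 1e-12))
  }
  # frozen parameters stay at their point estimates
  parf <- draw_parameters(list(morbidity_est = w$est,
                               life_table = w$life_table,
                               burden = w$burden), cfg, 1,
                          active = character(0))
  expect_identical(parf$life_table$hle_years, w$life_table$hle_years)
  expect_identical(parf$morbidity_est$gap, w$est$gap)
})

test_that("LYoL draws average to the mean at the assumed 10% SD", {
  lt <- life_table(gender = 1, age_band = 0, hle_years = 10,
                   lyol_cost_eur = 20000)
  cfg <- mc_config(n_draws = 1, seed = 5)
  inputs <- list(morbidity_est = NULL, life_table = lt, burden = NULL)
  n <- 2000
  draws <- vapply(seq_len(n), function(i)
    draw_parameters(inputs, cfg, i, active = "lyol")$life_table$lyol_cost_eur,
    numeric(1))
  # CLT: sample mean within 3 * (0.1 * mean) / sqrt(n)
  expect_lt(abs(mean(draws) - 20000), 3 * 2000 / sqrt(n))
  expect_lt(abs(stats::sd(draws) - 2000), 4 * 2000 / sqrt(2 * n))
})

test_that("combined uncertainty dominates each single parameter", {
  w <- mc_world()
  cfg <- mc_config(n_draws = 60, seed = 11)
  res <- run_monte_carlo(w$claims, w$est, w$life_table, w$burden, cfg)
  s <- res$summary
  comb <- s$se[s$scenario == "combined"]
  singles <- s$se[s$scenario != "combined"]
  # allow 2 Monte Carlo SEs of slack on the SE estimates themselves
  mc_se <- (comb + max(singles)) / sqrt(2 * (cfg$n_draws - 1))
  expect_gt(comb, max(singles) - 2 * mc_se)
  # percentile interval contains the median
  expect_true(all(s$p2.5 <= s$median & s$median <= s$p97.5))
})
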