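# deterministic questionnaire table with known per-stratum structure
make_records <- function(strata_gaps, base = 0.9, n = 40,
                         years = 2012:2014, trend = 0) {
  tf <- fixture_tariff()
  rows <- list()
  for (i in seq_along(strata_gaps)) {
    for (y in years) {
      u_pat <- base - strata_gaps[[i]] + trend * (y - years[1])
      for (visited in c(0, 1)) {
        target <- if (visited) u_pat else base
        # deterministic two-point mixture hitting the target mean exactly
        u_mid <- score_eq5d(c(2, 2, 2, 2, 2), tf)
        k <- round(n * (target - u_mid) / (tf$full_health - u_mid))
        lev <- c(rep(1L, k), rep(2L, n - k))
        rows[[length(rows) + 1L]] <- data.frame(
          respondent_id = "x", year = y, gender = 1L,
          age_band = i - 1L, visited_hospital = visited,
          mo = lev, sc = lev, ua = lev, pd = lev, ad = lev)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("identical patient and non-patient utilities give a zero gap", {
  rec <- make_records(strata_gaps = c(0, 0))
  est <- estimate_morbidity_gap(rec, fixture_tariff())
  expect_equal(est$gap, rep(0, 2), tolerance = 0.02)
})

test_that("per-stratum gaps are recovered and ordered", {
  # exact brute-force oracle: with no trend the fitted gap must equal the
  # patient/non-patient difference of stratum means
  rec <- make_records(strata_gaps = c(0.05, 0.15))
  tf <- fixture_tariff()
  u <- score_eq5d(rec[, c("mo", "sc", "ua", "pd", "ad")], tf)
  oracle <- sapply(0:1, function(b) {
    sel <- rec$age_band == b
    mean(u[sel & rec$visited_hospital == 0]) -
      mean(u[sel & rec$visited_hospital == 1])
  })
  est <- estimate_morbidity_gap(rec, tf)
  expect_equal(est$gap, oracle, tolerance = 1e-10)
  expect_lt(est$gap[1], est$gap[2])
})

test_that("a planted trend in patient utility is recovered on the loss scale", {
  # patient utility falls by 0.01/yr => per-patient QALY loss rises by 0.01/yr
  rec <- make_records(strata_gaps = c(0.1), n = 200, trend = -0.01)
  est <- estimate_morbidity_gap(rec, fixture_tariff())
  expect_lt(abs(est$trend - 0.01), 3 * est$trend_se + 0.003)
})

test_that("gap and trend estimates recover generator truth within 2 SE", {
  s <- small_strata(n_age_bands = 3)
  tr <- synthetic_truth(s, utility_gap = 0.1, utility_trend = -0.005)
  q <- generate_questionnaires(s, tr, 1500, seed = 8)
  est <- estimate_morbidity_gap(q, fixture_tariff())
  # pooled over strata: average estimate vs truth, 2 SEs of the average
  expect_lt(abs(mean(est$gap) - 0.1),
            2 * mean(est$gap_se) / sqrt(nrow(est)) + 0.005)
  expect_lt(abs(mean(est$trend) - 0.005),
            2 * mean(est$trend_se) / sqrt(nrow(est)) + 0.005)
})

test_that("strata with a single class are excluded, not estimated", {
  rec <- make_records(strata_gaps = c(0.05, 0.15))
  rec <- rec[!(rec$age_band == 1 & rec$visited_hospital == 1), ]
  est <- estimate_morbidity_gap(rec, fixture_tariff())
  expect_identical(attr(est, "excluded_strata"), "1 1")
  expect_identical(nrow(est), 1L)
})

test_that("morbidity loss scales gap and trend by base-year patients", {
  est <- structure(
    data.frame(gender = 1L, age_band = 0L, gap = 0.1, gap_se = 0,
               trend = -0.01, trend_se = 0),
    class = c("morbidity_estimates", "data.frame"))
  base <- data.frame(group_id = c("a", "b"), gender = 1L,
                     age_band = c(0L, 0L), patients = c(1000, 0))
  # base year: gap only
  l0 <- morbidity_qaly_loss(est, base, 2012, 2012)
  expect_equal(l0$morbidity_qaly, c(100, 0))
  # two years on, trend -0.01/yr: (0.1 - 0.02) * 1000 = 80
  l2 <- morbidity_qaly_loss(est, base, 2014, 2012)
  expect_equal(l2$morbidity_qaly, c(80, 0))
  # missing stratum estimate flags the group
  base2 <- data.frame(group_id = "c", gender = 2L, age_band = 5L,
                      patients = 10)
  l3 <- morbidity_qaly_loss(est, base2, 2012, 2012)
  expect_true(l3$excluded)
  expect_true(is.na(l3$morbidity_qaly))
})

test_that("linear-in-age extrapolation fills uncovered bands", {
  est <- structure(
    data.frame(gender = 1L, age_band = c(2L, 4L, 6L),
               gap = c(0.06, 0.10, 0.14), gap_se = c(0.01, 0.02, 0.01),
               trend = c(0.002, 0.004, 0.006), trend_se = 0.001),
    class = c("morbidity_estimates", "data.frame"))
  full <- extrapolate_morbidity(est, age_bands = 0:7)
  expect_identical(nrow(full), 8L)
  # exact linear profile: extrapolated values lie on the same line
  expect_equal(full$gap[full$age_band == 0], 0.02)
  expect_equal(full$gap[full$age_band == 7], 0.16)
  expect_equal(full$trend[full$age_band == 1], 0.001)
  expect_identical(full$extrapolated[full$age_band == 3], TRUE)
  expect_identical(full$extrapolated[full$age_band == 4], FALSE)
  # conservative SE: the gender's largest observed SE
  expect_equal(full$gap_se[full$age_band == 0], 0.02)
})
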