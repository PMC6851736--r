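# Seeded synthetic panel generator. Emulates the structure of Dutch
# hospital claims aggregated to patient group (gender x age band x
# disease) by year: skewed log-normal spending and patient counts, a
# group fixed effect, a common time trend, binomial deaths whose
# last-year-of-life costs are embedded in raw spending, and an EQ-5D
# questionnaire sample with a patient/non-patient utility gap. The
# production-function truth is stored alongside so that every
# downstream stage can be tested against known parameters.

#' Synthetic production-function truth
#'
#' Fixes the parameters of the data-generating process: the translog
#' coefficients of log QALY loss in log corrected spending (`logC`) and
#' log patients (`logN`), the dispersion of group fixed effects and of
#' the idiosyncratic noise, the location/spread of spending and patient
#' counts, age-graded death rates, a life table, per-stratum utility
#' baselines with a patient/non-patient gap and an annual patient
#' utility trend, and burden-of-disease weights per disease.
#'
#' The quadratic coefficients `c2` and `d2` are the *regression*
#' coefficients on `logC^2` and `logN^2`; in the second-order Taylor
#' parameterisation with 1/2 factors they equal half the Taylor
#' curvature terms, so the spending elasticity at a point is
#' `c1 + 2*c2*logC + c3*logN`.
#'
#' Defaults reproduce the magnitudes typical of national hospital
#' claims panels: mean log corrected spending about 11.97 with a wide
#' between-group spread (so the arithmetic mean spending, about €1.7M,
#' is far above `exp(mean log)`), mean log patients about 5.1, a
#' negative spending elasticity at the means (about -0.157), a small
#' negative common time trend, and death rates rising steeply with age.
#'
#' @param strata A [strata_config()].
#' @param constant,trend,c1,c2,c3,d1,d2 Translog coefficients (response
#'   `log Q`): constant, linear time trend, `logC`, `logC^2`,
#'   `logC*logN`, `logN`, `logN^2`.
#' @param fe_sd SD of the group fixed effect (log scale, >= 0).
#' @param noise_sd SD of the idiosyncratic error on `log Q` (>= 0).
#' @param logC_mean,logC_between_sd,logC_within_sd Location of log
#'   corrected spending, its between-group spread, and the SD of
#'   year-to-year innovations within a group.
#' @param logN_mean,logN_between_sd,logN_within_sd Same for log patient
#'   counts.
#' @param ar_rho First-order autocorrelation of the within-group
#'   spending/patient innovations (stationary AR(1), `|rho| < 1`).
#' @param death_rates Per-age-band annual death rate among patients
#'   (vector of length `n_age_bands`, values in `[0, 1]`); default rises
#'   from about 0.2% in the youngest band to about 11% in the oldest.
#' @param mortality_response Semi-elasticity of the death rate with
#'   respect to within-group log-spending innovations (>= 0): a year in
#'   which a group's corrected spending runs one log-unit above its own
#'   level multiplies its death rate by `exp(-mortality_response)`.
#'   This plants the causal spending-averts-deaths gradient that the
#'   estimation pipeline is built to detect; 0 switches it off.
#' @param life_table A [life_table()]; default [synthetic_life_table()].
#' @param utility_gap Patient vs non-patient mean utility gap (QALY/yr),
#'   recycled over (gender, age band) strata.
#' @param utility_trend Annual change in patient utility (QALY/yr per
#'   year; negative means patients' health declines over the panel).
#' @param baseline_utility Non-patient mean utility per age band;
#'   default declines mildly with age.
#' @param bod Burden-of-disease weight per disease in `[0, 1]`, `NA` for
#'   diseases without a published weight; default a deterministic
#'   sequence over `[0.05, 0.35]` with every seventh weight missing.
#' @param patient_share Share of questionnaire respondents who visited
#'   a hospital during the year.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(strata,
                            constant = -2.86, trend = -0.0185,
                            c1 = -0.0461, c2 = 0.0033, c3 = -0.0372,
                            d1 = 1.3012, d2 = 0.0222,
                            fe_sd = 0.5, noise_sd = 0.06,
                            logC_mean = 11.97, logC_between_sd = 2.0,
                            logC_within_sd = 0.35,
                            logN_mean = 5.10, logN_between_sd = 1.2,
                            logN_within_sd = 0.25,
                            ar_rho = 0.3,
                            death_rates = NULL,
                            mortality_response = 0.5,
                            life_table = synthetic_life_table(strata),
                            utility_gap = 0.10,
                            utility_trend = -0.005,
                            baseline_utility = NULL,
                            bod = NULL,
                            patient_share = 0.35) {
  stopifnot(inherits(strata, "strata_config"))
  if (is.null(death_rates)) {
    frac <- if (strata$n_age_bands == 1L) 1
            else (seq_len(strata$n_age_bands) - 1L) / (strata$n_age_bands - 1L)
    death_rates <- 0.002 * exp(4 * frac)
  }
  if (is.null(baseline_utility))
    baseline_utility <- 0.95 - 0.004 * (seq_len(strata$n_age_bands) - 1L)
  if (is.null(bod)) {
    d <- seq_len(strata$n_diseases)
    bod <- 0.05 + 0.30 * ((d - 1L) %% 10L) / 9
    bod[d %% 7L == 0L] <- NA_real_
  }
  if (any(c(fe_sd, noise_sd, logC_between_sd, logC_within_sd,
            logN_between_sd, logN_within_sd) < 0))
    stop("dispersion parameters must be >= 0", call. = FALSE)
  if (length(death_rates) != strata$n_age_bands ||
      any(death_rates < 0 | death_rates > 1))
    stop("`death_rates` must give one rate in [0, 1] per age band",
         call. = FALSE)
  if (any(!is.na(bod) & (bod < 0 | bod > 1)))
    stop("burden-of-disease weights must lie in [0, 1]", call. = FALSE)
  if (abs(ar_rho) >= 1) stop("`ar_rho` must satisfy |rho| < 1", call. = FALSE)
  if (mortality_response < 0)
    stop("`mortality_response` must be >= 0", call. = FALSE)
  truth <- structure(
    list(strata = strata, constant = constant, trend = trend,
         c1 = c1, c2 = c2, c3 = c3, d1 = d1, d2 = d2,
         fe_sd = fe_sd, noise_sd = noise_sd,
         logC_mean = logC_mean, logC_between_sd = logC_between_sd,
         logC_within_sd = logC_within_sd,
         logN_mean = logN_mean, logN_between_sd = logN_between_sd,
         logN_within_sd = logN_within_sd, ar_rho = ar_rho,
         death_rates = death_rates,
         mortality_response = mortality_response,
         life_table = life_table,
         utility_gap = rep_len(utility_gap, strata$n_age_bands),
         utility_trend = utility_trend,
         baseline_utility = rep_len(baseline_utility, strata$n_age_bands),
         bod = bod, patient_share = patient_share),
    class = "synthetic_truth")
  e <- with(truth, c1 + 2 * c2 * logC_mean + c3 * logN_mean)
  if (e >= 0)
    stop(sprintf(paste0("implied spending elasticity at the generated means ",
                        "is %.4f; it must be negative (diminishing QALY ",
                        "loss in spending)"), e), call. = FALSE)
  truth
}

# evaluate the translog polynomial of the truth (without fixed effect/noise)
translog_poly <- function(truth, logC, logN, time_index) {
  truth$constant + truth$trend * time_index +
    truth$c1 * logC + truth$c2 * logC^2 +
    truth$d1 * logN + truth$d2 * logN^2 +
    truth$c3 * logC * logN
}

# run `expr` under a dedicated RNG stream so each logical sub-draw
# (fixed effects, counts, noise, deaths, ...) has its own sequence
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 97L + offset) %% 2147483629L)
  force(expr)
}

# stationary AR(1) innovations, one row per unit, one column per period
ar1_matrix <- function(n, periods, sd, rho) {
  e <- matrix(stats::rnorm(n * periods, 0, sd), n, periods)
  if (periods > 1L && rho != 0) {
    for (t in 2:periods)
      e[, t] <- rho * e[, t - 1L] + sqrt(1 - rho^2) * e[, t]
  }
  e
}

#' Generate a synthetic claims/mortality panel
#'
#' Produces one record per patient group and year. For each group a
#' fixed effect is drawn once; log patient counts and log corrected
#' spending follow stationary AR(1) paths around group-specific levels;
#' log QALY loss is computed exactly from the translog truth plus noise;
#' deaths are binomial in the patient count with the age-band rate; and
#' raw spending is assembled as corrected spending plus deaths times the
#' last-year-of-life cost of the group's (gender, age) stratum. The
#' same seed always yields bit-identical output.
#'
#' @param strata A [strata_config()].
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed.
#' @return A list with `panel` (data frame: `group_id`, `gender`,
#'   `age_band`, `disease`, `year`, `time_index`, `patients`, `deaths`,
#'   `spending_eur`, plus the latent columns `true_corrected_eur` and
#'   `true_qaly_loss` used as test oracles) and `truth`.
#' @export
generate_panel <- function(strata, truth, seed) {
  stopifnot(inherits(strata, "strata_config"),
            inherits(truth, "synthetic_truth"))
  keys <- enumerate_groups(strata)
  G <- nrow(keys)
  years <- strata$years
  P <- length(years)

  fe   <- with_stream(seed, 1L, stats::rnorm(G, 0, truth$fe_sd))
  muN  <- with_stream(seed, 2L,
                      stats::rnorm(G, truth$logN_mean, truth$logN_between_sd))
  eN   <- with_stream(seed, 3L,
                      ar1_matrix(G, P, truth$logN_within_sd, truth$ar_rho))
  muC  <- with_stream(seed, 4L,
                      stats::rnorm(G, truth$logC_mean, truth$logC_between_sd))
  eC   <- with_stream(seed, 5L,
                      ar1_matrix(G, P, truth$logC_within_sd, truth$ar_rho))
  eQ   <- with_stream(seed, 6L,
                      matrix(stats::rnorm(G * P, 0, truth$noise_sd), G, P))

  patients <- pmax(1L, round(exp(muN + eN)))      # G x P
  logN <- log(patients)
  corrected <- exp(muC + eC)
  logC <- muC + eC
  tmat <- matrix(seq_len(P) - 1L, G, P, byrow = TRUE)
  logQ <- translog_poly(truth, logC, logN, tmat) + fe + eQ

  # death rate: age-band base, damped by the group's spending innovation
  rate <- matrix(truth$death_rates[keys$age_band + 1L], G, P) *
    exp(-truth$mortality_response * eC)
  rate <- pmin(rate, 1)
  deaths <- with_stream(seed, 7L, {
    d <- stats::rbinom(G * P, as.vector(patients), as.vector(rate))
    matrix(d, G, P)
  })
  lyol <- lookup_life_table(truth$life_table, keys, "lyol_cost_eur")
  spending <- corrected + deaths * lyol

  panel <- data.frame(
    group_id = rep(keys$group_id, P),
    gender = rep(keys$gender, P),
    age_band = rep(keys$age_band, P),
    disease = rep(keys$disease, P),
    year = rep(years, each = G),
    time_index = rep(seq_len(P) - 1L, each = G),
    patients = as.vector(patients),
    deaths = as.vector(deaths),
    spending_eur = as.vector(spending),
    true_corrected_eur = as.vector(corrected),
    true_qaly_loss = as.vector(exp(logQ))
  )
  panel <- panel[order(panel$group_id, panel$year), ]
  rownames(panel) <- NULL
  list(panel = panel, truth = truth)
}

#' Generate synthetic EQ-5D questionnaire records
#'
#' Draws `n_per_stratum` respondents per (gender, age band, year), a
#' fixed share of whom visited a hospital during the year. Expected
#' utility is the stratum baseline for non-patients and the baseline
#' minus the truth gap plus the annual trend times elapsed years for
#' patients. Profiles are drawn as two-point mixtures of anchor states
#' (11111 / 22222 / 33333) whose tariff scores bracket the target, so
#' that scored utilities reproduce the target expectation on average.
#'
#' @inheritParams generate_panel
#' @param n_per_stratum Respondents per (gender, age band, year), >= 1.
#' @param tariff The [tariff_spec()] under which expectations should be
#'   reproduced (default [synthetic_tariff()]).
#' @return A data frame with columns `respondent_id`, `year`, `gender`,
#'   `age_band`, `visited_hospital` (0/1) and the five EQ-5D levels
#'   `mo`, `sc`, `ua`, `pd`, `ad`.
#' @export
generate_questionnaires <- function(strata, truth, n_per_stratum, seed,
                                    tariff = synthetic_tariff()) {
  stopifnot(inherits(strata, "strata_config"),
            inherits(truth, "synthetic_truth"))
  n_per_stratum <- as.integer(n_per_stratum)
  if (n_per_stratum < 1L) stop("`n_per_stratum` must be >= 1", call. = FALSE)

  grid <- expand.grid(age_band = seq_len(strata$n_age_bands) - 1L,
                      gender = seq_len(strata$n_genders),
                      year = strata$years, KEEP.OUT.ATTRS = FALSE)
  rows <- grid[rep(seq_len(nrow(grid)), each = n_per_stratum), ]
  n <- nrow(rows)
  rownames(rows) <- NULL

  visited <- with_stream(seed, 11L,
                         stats::rbinom(n, 1L, truth$patient_share))
  elapsed <- rows$year - strata$years[1L]
  target <- truth$baseline_utility[rows$age_band + 1L] -
    visited * (truth$utility_gap[rows$age_band + 1L] -
                 truth$utility_trend * elapsed)

  u_full <- tariff$full_health
  u_mid <- score_eq5d(c(2L, 2L, 2L, 2L, 2L), tariff)
  u_low <- score_eq5d(c(3L, 3L, 3L, 3L, 3L), tariff)
  if (any(target > u_full) || any(target < u_low))
    stop("target utilities fall outside the tariff's anchor range",
         call. = FALSE)
  hi <- target >= u_mid
  p_upper <- ifelse(hi, (target - u_mid) / (u_full - u_mid),
                        (target - u_low) / (u_mid - u_low))
  pick_upper <- with_stream(seed, 12L, stats::runif(n)) < p_upper
  level <- ifelse(hi, ifelse(pick_upper, 1L, 2L),
                      ifelse(pick_upper, 2L, 3L))

  q <- data.frame(
    respondent_id = sprintf("r%06d", seq_len(n)),
    year = rows$year, gender = rows$gender, age_band = rows$age_band,
    visited_hospital = visited,
    mo = level, sc = level, ua = level, pd = level, ad = level
  )
  q
}

#' Write the full set of synthetic pipeline inputs
#'
#' Generates a panel and questionnaire sample and writes every input the
#' analysis pipeline reads: `claims.csv` (group-year spending, patients
#' and deaths), `questionnaires.csv`, `life_table.csv`, `burden.csv`,
#' `tariff.yaml`, and `truth.json` (the generator parameters, for use as
#' a test oracle — not read by the pipeline).
#'
#' @inheritParams generate_questionnaires
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of file paths plus the in-memory
#'   `panel` and `truth`.
#' @export
simulate_inputs <- function(dir, strata, truth = synthetic_truth(strata),
                            n_per_stratum = 50L, seed = 1L,
                            tariff = synthetic_tariff()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_panel(strata, truth, seed)
  quest <- generate_questionnaires(strata, truth, n_per_stratum, seed, tariff)

  claims <- gen$panel[, c("group_id", "gender", "age_band", "disease",
                          "year", "patients", "deaths", "spending_eur")]
  paths <- list(
    claims = file.path(dir, "claims.csv"),
    questionnaires = file.path(dir, "questionnaires.csv"),
    life_table = file.path(dir, "life_table.csv"),
    burden = file.path(dir, "burden.csv"),
    tariff = file.path(dir, "tariff.yaml"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(claims, paths$claims, row.names = FALSE)
  utils::write.csv(quest, paths$questionnaires, row.names = FALSE)
  utils::write.csv(as.data.frame(truth$life_table), paths$life_table,
                   row.names = FALSE)
  burden <- data.frame(disease = seq_len(strata$n_diseases),
                       bod = truth$bod,
                       bod_available = as.integer(!is.na(truth$bod)))
  utils::write.csv(burden, paths$burden, row.names = FALSE)
  write_tariff(tariff, paths$tariff)
  truth_plain <- truth[setdiff(names(truth), c("strata", "life_table"))]
  truth_plain$years <- strata$years
  jsonlite::write_json(truth_plain, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(panel = gen$panel, truth = truth)))
}

#' Latent outcome panel of a synthetic generation
#'
#' Assembles the generator's latent corrected spending and QALY loss
#' into an analysis-ready outcome panel, bypassing the questionnaire and
#' mortality construction. This is the oracle path for testing the
#' estimation stage against known production-function parameters.
#'
#' @param gen The list returned by [generate_panel()].
#' @return An `outcome_panel` (see [total_qaly_loss()]).
#' @export
latent_outcome_panel <- function(gen) {
  p <- gen$panel
  new_outcome_panel(data.frame(
    group_id = p$group_id, gender = p$gender, age_band = p$age_band,
    disease = p$disease, year = p$year, time_index = p$time_index,
    morbidity_qaly = NA_real_, death_qaly = NA_real_,
    qaly_loss = p$true_qaly_loss,
    corrected_eur = p$true_corrected_eur,
    patients = p$patients,
    deaths = p$deaths,
    excluded = FALSE, exclude_reason = NA_character_
  ))
}
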