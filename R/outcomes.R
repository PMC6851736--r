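# Assembly of the analysis panel: total QALY loss Q, corrected
# spending C and patient count N per group-year, with exclusion flags
# for cells that cannot enter the log model.

new_outcome_panel <- function(df) {
  req <- c("group_id", "gender", "age_band", "disease", "year",
           "time_index", "morbidity_qaly", "death_qaly", "qaly_loss",
           "corrected_eur", "patients", "excluded", "exclude_reason")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("outcome panel is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ok <- !df$excluded
  if (any(ok & (df$qaly_loss <= 0 | df$corrected_eur <= 0 |
                  df$patients <= 0), na.rm = TRUE))
    stop("non-excluded cells must have positive Q, C and N", call. = FALSE)
  structure(df, class = c("outcome_panel", "data.frame"))
}

#' Total QALY loss per group-year
#'
#' Adds death-related to morbidity-related QALY loss, cell by cell.
#' Cells whose total is not positive cannot be log-transformed and are
#' flagged excluded with reason `"nonpositive outcome"`.
#'
#' @param morbidity Data frame with `group_id`, `year`,
#'   `morbidity_qaly` (and optional upstream `excluded` /
#'   `exclude_reason` flags).
#' @param death Data frame with `group_id`, `year`, `death_qaly`.
#' @return The merged data frame with `qaly_loss`, `excluded`,
#'   `exclude_reason`. The two inputs must cover exactly the same
#'   (group, year) keys; a mismatch is an error listing offending keys.
#' @export
total_qaly_loss <- function(morbidity, death) {
  km <- paste(morbidity$group_id, morbidity$year)
  kd <- paste(death$group_id, death$year)
  only_m <- setdiff(km, kd)
  only_d <- setdiff(kd, km)
  if (length(only_m) || length(only_d))
    stop("group-year keys do not align; only in morbidity: ",
         paste(utils::head(only_m, 5L), collapse = ", "),
         "; only in death: ",
         paste(utils::head(only_d, 5L), collapse = ", "), call. = FALSE)
  out <- morbidity
  out$death_qaly <- death$death_qaly[match(km, kd)]
  out$qaly_loss <- out$morbidity_qaly + out$death_qaly
  if (is.null(out$excluded)) {
    out$excluded <- FALSE
    out$exclude_reason <- NA_character_
  }
  nonpos <- !out$excluded & (is.na(out$qaly_loss) | out$qaly_loss <= 0)
  out$excluded <- out$excluded | nonpos
  out$exclude_reason[nonpos] <- "nonpositive outcome"
  out
}

#' Build the full outcome panel from raw inputs
#'
#' Runs the complete data-transformation chain on a claims panel:
#' morbidity QALY loss per group (stratum gap and trend times base-year
#' patients), death-related QALY loss (deaths times discounted healthy
#' life expectancy, shrunk by burden of disease), their sum as total
#' QALY loss, and last-year-of-life-corrected spending. Parameter
#' overrides allow the Monte Carlo engine to rebuild the panel under
#' drawn transformation parameters.
#'
#' @param claims Data frame per group-year: `group_id`, `gender`,
#'   `age_band`, `disease`, `year`, `patients`, `deaths`,
#'   `spending_eur`.
#' @param morbidity_est A [estimate_morbidity_gap()] result (or a data
#'   frame with the same columns).
#' @param life_table A [life_table()].
#' @param burden Burden-of-disease table (see [resolve_bod()]).
#' @param base_year Base year for patient counts; default the first
#'   panel year.
#' @param discount_rate Annual discount rate for healthy life
#'   expectancy (default 0.015).
#' @param extrapolate_morbidity Fill age bands without questionnaire
#'   coverage by linear-in-age extrapolation of the gap and trend
#'   (see [extrapolate_morbidity()]); off by default.
#' @return An `outcome_panel`.
#' @export
compute_outcomes <- function(claims, morbidity_est, life_table, burden,
                             base_year = min(claims$year),
                             discount_rate = 0.015,
                             extrapolate_morbidity = FALSE) {
  life_table <- validate_life_table(life_table)
  if (extrapolate_morbidity)
    morbidity_est <- extrapolate_morbidity(morbidity_est,
                                           sort(unique(claims$age_band)))
  claims <- claims[order(claims$group_id, claims$year), ]

  base <- claims[claims$year == base_year,
                 c("group_id", "gender", "age_band", "disease", "patients")]
  if (!nrow(base))
    stop("no claims rows in base year ", base_year, call. = FALSE)

  years <- sort(unique(claims$year))
  morb <- do.call(rbind, lapply(years, function(y)
    morbidity_qaly_loss(morbidity_est, base, y, base_year)))

  dhle <- discounted_hle(lookup_life_table(life_table, claims, "hle_years"),
                         discount_rate)
  bod <- resolve_bod(burden, claims$disease, claims$gender)
  death <- data.frame(group_id = claims$group_id, year = claims$year,
                      death_qaly = death_qaly_loss(claims$deaths, dhle, bod))

  key_c <- paste(claims$group_id, claims$year)
  morb <- morb[match(key_c, paste(morb$group_id, morb$year)), ]
  no_base <- is.na(morb$excluded)          # group absent from base year
  morb$excluded[no_base] <- TRUE
  morb$exclude_reason[no_base] <- "no base-year patient count"
  morb$group_id <- claims$group_id
  morb$year <- claims$year
  total <- total_qaly_loss(morb, death)

  corr <- corrected_spending(claims, life_table)
  excluded <- total$excluded | corr$excluded
  reason <- ifelse(total$excluded, total$exclude_reason,
                   corr$exclude_reason)
  new_outcome_panel(data.frame(
    group_id = claims$group_id, gender = claims$gender,
    age_band = claims$age_band, disease = claims$disease,
    year = claims$year,
    time_index = claims$year - min(claims$year),
    morbidity_qaly = total$morbidity_qaly,
    death_qaly = total$death_qaly,
    qaly_loss = total$qaly_loss,
    corrected_eur = corr$corrected_eur,
    patients = claims$patients,
    excluded = excluded | claims$patients <= 0,
    exclude_reason = ifelse(claims$patients <= 0 & !excluded,
                            "no patients", reason)
  ))
}
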