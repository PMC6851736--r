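# Morbidity-related QALY loss: pooled regression of scored EQ-5D
# utilities on a hospital-visit indicator, per-stratum, with a linear
# time trend among patients; then scaling by base-year patient counts.

#' Estimate the patient/non-patient utility gap and patient trend
#'
#' Scores every questionnaire record under the tariff and fits one
#' pooled least-squares regression of utility on stratum intercepts
#' (gender x age band), a per-stratum hospital-visit effect, and a
#' per-stratum visit-by-year interaction. The visit effect gives the
#' mean utility gap between patients and non-patients — interpretable as
#' the health gain the hospital sector could still achieve per patient —
#' and the interaction gives the annual trend in patient utility.
#'
#' Sign convention: `gap` and `trend` are reported on the *QALY-loss*
#' scale — `gap` is positive when patients are worse off, and `trend` is
#' the annual change in per-patient QALY loss (negative when patients'
#' health improves over time, i.e. loss shrinks).
#'
#' @param records Questionnaire data frame with columns `year`,
#'   `gender`, `age_band`, `visited_hospital` (0/1) and EQ-5D levels
#'   `mo`, `sc`, `ua`, `pd`, `ad`.
#' @param tariff A [tariff_spec()].
#' @return An object of class `morbidity_estimates`: a data frame with
#'   one row per (gender, age_band) and columns `gap`, `gap_se`,
#'   `trend`, `trend_se`; strata observed with only one of the two
#'   classes (patients / non-patients) are excluded from the fit and
#'   listed in `attr(, "excluded_strata")`.
#' @export
estimate_morbidity_gap <- function(records, tariff) {
  req <- c("year", "gender", "age_band", "visited_hospital",
           "mo", "sc", "ua", "pd", "ad")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("questionnaire table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(records$year)) < 2L)
    stop("at least 2 years of questionnaire data are required",
         call. = FALSE)

  u <- score_eq5d(records[, c("mo", "sc", "ua", "pd", "ad")], tariff)
  d <- data.frame(u = u, year = records$year,
                  gender = records$gender, age_band = records$age_band,
                  visited = as.numeric(records$visited_hospital))

  key <- paste(d$gender, d$age_band)
  both <- tapply(d$visited, key, function(v) any(v == 1) && any(v == 0))
  bad <- names(both)[!both]
  if (length(bad)) d <- d[!(key %in% bad), , drop = FALSE]
  if (!nrow(d))
    stop("no stratum contains both patients and non-patients",
         call. = FALSE)

  d$stratum <- factor(paste(d$gender, d$age_band))
  d$yearc <- d$year - min(records$year)
  # explicit full-dummy design: stratum intercepts, per-stratum visit
  # effects, per-stratum visit-by-year interactions (robust to a single
  # stratum, where formula contrasts would fail)
  levs <- levels(d$stratum)
  S <- vapply(levs, function(l) as.numeric(d$stratum == l),
              numeric(nrow(d)))
  X <- cbind(S, S * d$visited, S * (d$visited * d$yearc))
  colnames(X) <- c(levs, paste0(levs, ":visited"),
                   paste0(levs, ":visited:yearc"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("morbidity design is singular; a used stratum lacks ",
         "patient/non-patient or multi-year contrast", call. = FALSE)
  beta <- qr.coef(qrX, d$u)
  resid <- d$u - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                 drop = FALSE]
  se <- stats::setNames(sqrt(sigma2 * diag(XtX_inv)), colnames(X))

  vis_nm <- paste0(levs, ":visited")
  trd_nm <- paste0(levs, ":visited:yearc")
  gk <- strsplit(levs, " ", fixed = TRUE)
  out <- data.frame(
    gender = as.integer(vapply(gk, `[`, "", 1L)),
    age_band = as.integer(vapply(gk, `[`, "", 2L)),
    gap = -unname(beta[vis_nm]),
    gap_se = unname(se[vis_nm]),
    trend = -unname(beta[trd_nm]),
    trend_se = unname(se[trd_nm])
  )
  rownames(out) <- NULL
  out <- out[order(out$gender, out$age_band), ]
  if (any(out$gap_se < 0, na.rm = TRUE)) stop("negative SE", call. = FALSE)
  structure(out, excluded_strata = bad,
            class = c("morbidity_estimates", "data.frame"))
}

#' Extrapolate morbidity estimates to uncovered age bands
#'
#' Health questionnaires often cover only part of the age range (e.g.
#' respondents above 50). This fits, per gender, a straight line in age
#' band through the available gap and trend estimates and fills the
#' missing bands from it, assuming smooth age profiles. Extrapolated
#' rows carry the largest observed SE of their gender as a conservative
#' uncertainty. Off by default in [compute_outcomes()].
#'
#' @param est A [estimate_morbidity_gap()] result.
#' @param age_bands Integer vector of age bands that must be covered.
#' @return A `morbidity_estimates` covering every requested (gender,
#'   age band); rows gain a logical `extrapolated` column.
#' @export
extrapolate_morbidity <- function(est, age_bands) {
  stopifnot(inherits(est, "morbidity_estimates"))
  out <- lapply(unique(est$gender), function(g) {
    e <- est[est$gender == g, , drop = FALSE]
    missing_bands <- setdiff(age_bands, e$age_band)
    e$extrapolated <- FALSE
    if (!length(missing_bands)) return(e)
    if (nrow(e) < 2L)
      stop("need >= 2 covered age bands per gender to extrapolate",
           call. = FALSE)
    fg <- stats::lm(gap ~ age_band, data = e)
    ft <- stats::lm(trend ~ age_band, data = e)
    nd <- data.frame(age_band = missing_bands)
    add <- data.frame(gender = g, age_band = missing_bands,
                      gap = stats::predict(fg, nd),
                      gap_se = max(e$gap_se),
                      trend = stats::predict(ft, nd),
                      trend_se = max(e$trend_se),
                      extrapolated = TRUE)
    rbind(e, add)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$gender, out$age_band), ]
  rownames(out) <- NULL
  structure(out, excluded_strata = attr(est, "excluded_strata"),
            class = c("morbidity_estimates", "data.frame"))
}

#' Morbidity-related QALY loss per patient group
#'
#' Multiplies the per-patient loss `gap + trend * (year - base_year)`
#' of each group's (gender, age band) stratum by the group's patient
#' count in the base year. The base-year count is used for every panel
#' year, so changes over time reflect only the estimated trend.
#'
#' @param est A [estimate_morbidity_gap()] result.
#' @param base_patients Data frame with `group_id`, `gender`,
#'   `age_band`, and `patients` — the counts in the base year.
#' @param year Calendar year to evaluate.
#' @param base_year Base calendar year of the counts.
#' @return Data frame `group_id`, `year`, `morbidity_qaly`, `excluded`
#'   (TRUE when the stratum has no estimate), `exclude_reason`.
#' @export
morbidity_qaly_loss <- function(est, base_patients, year, base_year) {
  stopifnot(inherits(est, "morbidity_estimates"))
  idx <- match(paste(base_patients$gender, base_patients$age_band),
               paste(est$gender, est$age_band))
  per_patient <- est$gap[idx] + est$trend[idx] * (year - base_year)
  loss <- per_patient * base_patients$patients
  missing <- is.na(idx)
  loss[missing] <- NA_real_
  data.frame(
    group_id = base_patients$group_id,
    year = year,
    morbidity_qaly = loss,
    excluded = missing,
    exclude_reason = ifelse(missing, "no morbidity estimate for stratum",
                            NA_character_)
  )
}
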