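# Monte Carlo propagation of transformation-parameter uncertainty.
# The data transformations that build the outcome variable rest on
# estimated parameters — healthy life expectancy, the morbidity gap and
# trend, burden-of-disease weights, last-year-of-life costs. Each draw
# perturbs these, rebuilds the outcome panel and corrected spending,
# refits the translog model and recomputes the threshold; parameters
# are also varied one at a time for a variance decomposition.

.mc_params <- c("hle", "morbidity", "bod", "lyol")

#' Monte Carlo configuration
#'
#' Distributions, per parameter: healthy life expectancy is normal with
#' the life table's SD; the morbidity gap and trend are normal with
#' their regression SEs; burden-of-disease weights are uniform on
#' `[BoD, 1]`; last-year-of-life costs are normal with the life table's
#' SD (by convention 10% of the mean when no source SD exists). Normal
#' draws are truncated at their admissible bounds (HLE >= 0, LYoL >= 0)
#' rather than resampled, so each draw index maps to one deterministic
#' parameter set.
#'
#' @param n_draws Draws per scenario (>= 1). 500 gives a stable SE at
#'   desk scale; 10,000 matches full-scale practice.
#' @param seed Integer seed.
#' @param freeze Character subset of `c("hle", "morbidity", "bod",
#'   "lyol")` to hold at their point estimates in every scenario.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_draws = 500L, seed = 1L, freeze = character(0)) {
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop("`n_draws` must be >= 1", call. = FALSE)
  bad <- setdiff(freeze, .mc_params)
  if (length(bad))
    stop("unknown parameters in `freeze`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n_draws = n_draws, seed = seed, freeze = freeze),
            class = "mc_config")
}

#' Draw one joint parameter set
#'
#' Deterministic in `(seed, draw_index)`: parameters are drawn
#' independently of each other, each on its own stream.
#'
#' @param inputs List with `morbidity_est`, `life_table`, `burden`
#'   (point estimates).
#' @param config An [mc_config()].
#' @param draw_index Draw number (>= 1).
#' @param active Character vector of parameters to vary; the rest stay
#'   at their point estimates. Defaults to all not frozen.
#' @return A list `morbidity_est` / `life_table` / `burden` with drawn
#'   values substituted.
#' @export
draw_parameters <- function(inputs, config, draw_index,
                            active = setdiff(.mc_params, config$freeze)) {
  stopifnot(inherits(config, "mc_config"))
  lt <- inputs$life_table
  est <- inputs$morbidity_est
  burden <- inputs$burden
  base_seed <- (config$seed * 131L + draw_index) %% 2147483629L

  if ("hle" %in% active)
    lt$hle_years <- with_stream(base_seed, 31L,
      pmax(0, stats::rnorm(nrow(lt), lt$hle_years, lt$hle_sd)))
  if ("lyol" %in% active)
    lt$lyol_cost_eur <- with_stream(base_seed, 32L,
      pmax(0, stats::rnorm(nrow(lt), lt$lyol_cost_eur, lt$lyol_sd)))
  if ("morbidity" %in% active) {
    est$gap <- with_stream(base_seed, 33L,
      stats::rnorm(nrow(est), est$gap, est$gap_se))
    est$trend <- with_stream(base_seed, 34L,
      stats::rnorm(nrow(est), est$trend, est$trend_se))
  }
  if ("bod" %in% active) {
    b0 <- resolve_bod(burden, burden$disease,
                      if (!is.null(burden$gender)) burden$gender)
    burden$bod <- with_stream(base_seed, 35L,
      b0 + stats::runif(length(b0)) * (1 - b0))
    burden$bod_available <- 1L
  }
  list(morbidity_est = est, life_table = lt, burden = burden)
}

#' Run the Monte Carlo uncertainty analysis
#'
#' For the combined scenario and for each parameter alone, performs
#' `n_draws` full pipeline rebuilds (outcomes, spending correction,
#' translog refit, threshold) under drawn transformation parameters.
#' Draws in which the elasticity turns non-negative leave the threshold
#' undefined; they are counted and excluded from the summaries.
#'
#' @param claims Claims panel (see [compute_outcomes()]).
#' @param morbidity_est A [estimate_morbidity_gap()] result.
#' @param life_table A [life_table()].
#' @param burden Burden-of-disease table.
#' @param config An [mc_config()].
#' @param base_year,discount_rate Passed to [compute_outcomes()].
#' @param one_at_a_time Also run each parameter alone (default TRUE).
#' @return An object of class `mc_result`: `$summary` (one row per
#'   scenario: SE, 2.5/97.5 percentiles, failed draws), `$draws` (a
#'   draws x scenario matrix of thresholds), `$point` (the unperturbed
#'   `threshold_estimate`).
#' @export
run_monte_carlo <- function(claims, morbidity_est, life_table, burden,
                            config = mc_config(),
                            base_year = min(claims$year),
                            discount_rate = 0.015,
                            one_at_a_time = TRUE) {
  stopifnot(inherits(config, "mc_config"))
  inputs <- list(morbidity_est = morbidity_est,
                 life_table = validate_life_table(life_table),
                 burden = burden)
  point <- estimate_threshold(
    compute_outcomes(claims, morbidity_est, life_table, burden,
                     base_year, discount_rate))

  vary <- setdiff(.mc_params, config$freeze)
  scenarios <- c(list(combined = vary),
                 if (one_at_a_time && length(vary) > 1L)
                   stats::setNames(as.list(vary), vary))

  draws <- matrix(NA_real_, config$n_draws, length(scenarios),
                  dimnames = list(NULL, names(scenarios)))
  for (s in seq_along(scenarios)) {
    for (i in seq_len(config$n_draws)) {
      par <- draw_parameters(inputs, config, i, active = scenarios[[s]])
      thr <- tryCatch({
        pan <- compute_outcomes(claims, par$morbidity_est,
                                par$life_table, par$burden,
                                base_year, discount_rate)
        estimate_threshold(pan)$threshold
      }, error = function(e) NA_real_)
      draws[i, s] <- thr
    }
  }
  if (all(is.na(draws)))
    stop("all Monte Carlo draws failed", call. = FALSE)
  summ <- do.call(rbind, lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    ok <- x[!is.na(x)]
    data.frame(scenario = nm, n_draws = config$n_draws,
               failed = sum(is.na(x)),
               se = if (length(ok) > 1L) stats::sd(ok) else 0,
               p2.5 = stats::quantile(ok, 0.025, names = FALSE),
               median = stats::median(ok),
               p97.5 = stats::quantile(ok, 0.975, names = FALSE))
  }))
  structure(list(summary = summ, draws = draws, point = point,
                 config = config),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo uncertainty (%d draws/scenario); point threshold EUR %s\n",
    x$config$n_draws, format(round(x$point$threshold), big.mark = ",")))
  s <- x$summary
  s$se <- round(s$se)
  s$p2.5 <- round(s$p2.5); s$median <- round(s$median)
  s$p97.5 <- round(s$p97.5)
  print(s, row.names = FALSE)
  invisible(x)
}
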