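# End-to-end orchestration: read and validate the input tables, build
# outcomes and corrected spending, estimate the translog model, and
# attach bootstrap, Monte Carlo, discount-sweep and subgroup results,
# writing every intermediate table plus a final run report.

#' Pipeline configuration
#'
#' @param claims,questionnaires,life_table,burden,tariff Input file
#'   paths (headered CSV; the tariff is YAML, see [read_tariff()]).
#' @param outdir Output directory for reports and intermediate tables.
#' @param base_year Base year for patient counts; default the first
#'   claims year.
#' @param discount_rate Discount rate for healthy life expectancy
#'   (default 0.015, within `[0, 0.10]`).
#' @param discount_sweep Rates for the sensitivity sweep (default
#'   `c(0, 0.015, 0.03, 0.05)`).
#' @param bootstrap_reps Cluster-bootstrap replicates (default 100).
#' @param mc An [mc_config()], or `NULL` to skip the Monte Carlo.
#' @param seed Integer seed for bootstrap and Monte Carlo.
#' @param outcome_panel Optional path to a precomputed outcome-panel
#'   CSV; when given, the questionnaire/mortality construction is
#'   skipped and estimation runs directly on it (Monte Carlo, which
#'   needs the transformation parameters, is skipped too).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(claims = NULL, questionnaires = NULL,
                            life_table = NULL, burden = NULL,
                            tariff = NULL, outdir = tempfile("qt_run_"),
                            base_year = NULL, discount_rate = 0.015,
                            discount_sweep = c(0, 0.015, 0.03, 0.05),
                            bootstrap_reps = 100L,
                            mc = mc_config(n_draws = 200L),
                            seed = 1L, outcome_panel = NULL) {
  if (discount_rate < 0 || discount_rate > 0.10)
    stop("`discount_rate` must lie in [0, 0.10]", call. = FALSE)
  if (any(discount_sweep < 0 | discount_sweep > 0.10))
    stop("sweep rates must lie in [0, 0.10]", call. = FALSE)
  structure(list(claims = claims, questionnaires = questionnaires,
                 life_table = life_table, burden = burden,
                 tariff = tariff, outdir = outdir, base_year = base_year,
                 discount_rate = discount_rate,
                 discount_sweep = discount_sweep,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 mc = mc, seed = as.integer(seed),
                 outcome_panel = outcome_panel),
            class = "pipeline_config")
}

stop_stage <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

read_csv_checked <- function(path, required, what, optional = character(0)) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop(sprintf("%s file %s is missing required columns: %s", what,
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(tab), c(required, optional))
  if (length(extra))
    warning(sprintf("%s file has unrecognised columns (kept): %s", what,
                    paste(extra, collapse = ", ")), call. = FALSE)
  tab
}

#' Read and validate all pipeline inputs
#'
#' Schema-validates the claims, questionnaire, life-table and burden
#' CSVs and the tariff YAML. Duplicate (group, year) claims rows,
#' EQ-5D levels outside 1-3, deaths exceeding patients, and negative
#' spending are fatal, with the offending row numbers reported.
#'
#' @param config A [pipeline_config()].
#' @return List `claims`, `questionnaires`, `life_table`, `burden`,
#'   `tariff`.
#' @export
read_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  claims <- read_csv_checked(config$claims,
    c("group_id", "gender", "age_band", "disease", "year", "patients",
      "deaths", "spending_eur"), "claims")
  dup <- duplicated(claims[, c("group_id", "year")])
  if (any(dup))
    stop("claims file has duplicate (group, year) rows at lines: ",
         paste(utils::head(which(dup) + 1L, 10L), collapse = ", "),
         call. = FALSE)
  bad <- which(claims$deaths > claims$patients | claims$deaths < 0 |
                 claims$patients < 0 | claims$spending_eur < 0)
  if (length(bad))
    stop("claims rows violate 0 <= deaths <= patients, spending >= 0 ",
         "at lines: ", paste(utils::head(bad + 1L, 10L), collapse = ", "),
         call. = FALSE)
  zero_mismatch <- which((claims$patients == 0) !=
                           (claims$spending_eur == 0))
  if (length(zero_mismatch))
    stop("claims rows must have spending = 0 exactly when patients = 0; ",
         "violated at lines: ",
         paste(utils::head(zero_mismatch + 1L, 10L), collapse = ", "),
         call. = FALSE)

  quest <- read_csv_checked(config$questionnaires,
    c("respondent_id", "year", "gender", "age_band", "visited_hospital",
      "mo", "sc", "ua", "pd", "ad"), "questionnaire")
  lev <- as.matrix(quest[, c("mo", "sc", "ua", "pd", "ad")])
  badq <- which(rowSums(lev < 1 | lev > 3 | lev != round(lev)) > 0)
  if (length(badq))
    stop("questionnaire EQ-5D levels outside {1,2,3} at lines: ",
         paste(utils::head(badq + 1L, 10L), collapse = ", "),
         call. = FALSE)
  if (!all(quest$visited_hospital %in% c(0, 1)))
    stop("`visited_hospital` must be 0/1", call. = FALSE)

  lt <- validate_life_table(read_csv_checked(config$life_table,
    c("gender", "age_band", "hle_years", "hle_sd", "lyol_cost_eur",
      "lyol_sd"), "life table"))
  burden <- read_csv_checked(config$burden, c("disease", "bod"),
                             "burden",
                             optional = c("bod_available", "gender"))
  tariff <- read_tariff(config$tariff)
  list(claims = claims, questionnaires = quest, life_table = lt,
       burden = burden, tariff = tariff)
}

read_outcome_panel_csv <- function(path) {
  tab <- read_csv_checked(path,
    c("group_id", "gender", "age_band", "disease", "year", "qaly_loss",
      "corrected_eur", "patients"), "outcome panel",
    optional = c("time_index", "morbidity_qaly", "death_qaly", "deaths",
                 "excluded", "exclude_reason"))
  if (is.null(tab$time_index)) tab$time_index <- tab$year - min(tab$year)
  if (is.null(tab$morbidity_qaly)) tab$morbidity_qaly <- NA_real_
  if (is.null(tab$death_qaly)) tab$death_qaly <- NA_real_
  if (is.null(tab$excluded))
    tab$excluded <- !(tab$qaly_loss > 0 & tab$corrected_eur > 0 &
                        tab$patients > 0)
  if (is.null(tab$exclude_reason)) tab$exclude_reason <- NA_character_
  new_outcome_panel(tab)
}

#' Run the full threshold-estimation pipeline
#'
#' Executes every stage in order — input validation, morbidity gap
#' estimation, outcome construction, spending correction, translog
#' estimation, cluster bootstrap, Monte Carlo, discount-rate sweep and
#' subgroup evaluation — writing intermediate tables and a JSON run
#' report under `config$outdir`. Identical configuration and seed
#' reproduce the report exactly.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report` (list): `threshold`
#'   (point `threshold_estimate`), `bootstrap`, `mc`, `fit_table`,
#'   `discount_sweep`, `subgroups`, `exclusions`, `config_json`,
#'   `version`, and the paths of files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$outcome_panel)) {
    panel <- tryCatch(read_outcome_panel_csv(config$outcome_panel),
                      error = function(e) stop_stage("read_inputs", e))
    inputs <- NULL
    mc_res <- NULL
    sweep <- NULL
    excl_report <- NULL
  } else {
    inputs <- tryCatch(read_inputs(config),
                       error = function(e) stop_stage("read_inputs", e))
    base_year <- if (is.null(config$base_year)) min(inputs$claims$year)
                 else config$base_year
    est <- tryCatch(
      estimate_morbidity_gap(inputs$questionnaires, inputs$tariff),
      error = function(e) stop_stage("morbidity_gap", e))
    panel <- tryCatch(
      compute_outcomes(inputs$claims, est, inputs$life_table,
                       inputs$burden, base_year, config$discount_rate),
      error = function(e) stop_stage("outcomes", e))
    panel$deaths <- inputs$claims$deaths[
      match(paste(panel$group_id, panel$year),
            paste(inputs$claims$group_id, inputs$claims$year))]
    corr <- corrected_spending(inputs$claims, inputs$life_table)
    excl_report <- correction_report(corr)

    sweep <- do.call(rbind, lapply(config$discount_sweep, function(r) {
      p <- compute_outcomes(inputs$claims, est, inputs$life_table,
                            inputs$burden, base_year, r)
      t <- tryCatch(estimate_threshold(p)$threshold,
                    error = function(e) NA_real_)
      data.frame(discount_rate = r, threshold = t)
    }))
    mc_res <- if (!is.null(config$mc))
      tryCatch(run_monte_carlo(inputs$claims, est, inputs$life_table,
                               inputs$burden, config$mc, base_year,
                               config$discount_rate),
               error = function(e) stop_stage("monte_carlo", e))
  }

  point <- tryCatch(estimate_threshold(panel),
                    error = function(e) stop_stage("estimation", e))
  boot <- tryCatch(
    bootstrap_threshold(panel, config$bootstrap_reps, config$seed),
    error = function(e) stop_stage("bootstrap", e))
  subgroups <- list(
    gender = subgroup_thresholds(panel, "gender"),
    age_band = subgroup_thresholds(panel, "age_band"))

  paths$outcome_panel <- file.path(config$outdir, "outcome_panel.csv")
  utils::write.csv(as.data.frame(panel), paths$outcome_panel,
                   row.names = FALSE)
  fit_tab <- coef_table(point$fit)
  paths$fit <- file.path(config$outdir, "fit_table.csv")
  utils::write.csv(fit_tab, paths$fit, row.names = FALSE)
  if (!is.null(sweep)) {
    paths$sweep <- file.path(config$outdir, "discount_sweep.csv")
    utils::write.csv(sweep, paths$sweep, row.names = FALSE)
  }
  if (!is.null(mc_res)) {
    paths$mc <- file.path(config$outdir, "monte_carlo.csv")
    utils::write.csv(mc_res$summary, paths$mc, row.names = FALSE)
  }
  if (!is.null(excl_report)) {
    paths$exclusions <- file.path(config$outdir, "correction_report.csv")
    utils::write.csv(excl_report, paths$exclusions, row.names = FALSE)
  }

  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config), "mc")], auto_unbox = TRUE, digits = NA,
    null = "null")
  report <- structure(list(
    threshold = point, bootstrap = boot, mc = mc_res,
    fit_table = fit_tab, discount_sweep = sweep, subgroups = subgroups,
    exclusions = excl_report, paths = paths,
    config_json = as.character(cfg_json),
    version = as.character(utils::packageVersion("qalythreshold"))
  ), class = "run_report")

  paths$report <- file.path(config$outdir, "run_report.json")
  jsonlite::write_json(list(
    threshold_eur_per_qaly = point$threshold,
    elasticity = point$elasticity,
    mean_Q = point$mean_Q, mean_C = point$mean_C,
    bootstrap_se = boot$se, ci_normal = boot$ci_normal,
    ci_percentile = boot$ci_percentile,
    mc_summary = mc_res$summary, discount_sweep = sweep,
    version = report$version,
    config = jsonlite::fromJSON(report$config_json)
  ), paths$report, auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE)
  report$paths <- paths
  report
}

#' @export
print.run_report <- function(x, ...) {
  print(x$threshold)
  if (!is.null(x$bootstrap$se))
    cat(sprintf("Bootstrap SE: EUR %s (%d replicates used, %d failed)\n",
                format(round(x$bootstrap$se), big.mark = ","),
                x$bootstrap$reps_used, x$bootstrap$reps_failed))
  if (!is.null(x$discount_sweep)) {
    cat("Discount-rate sweep (EUR/QALY):\n")
    print(x$discount_sweep, row.names = FALSE)
  }
  invisible(x)
}
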