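# Reverse-causality correction: raw group spending S contains the
# last-year-of-life costs of the group's decedents, so mortality and
# spending are mechanically linked. Subtracting deaths times the
# stratum LYoL cost isolates corrected spending C with S = LYoL + C.

#' Total last-year-of-life cost per group-year
#'
#' @param panel Data frame with `gender`, `age_band` and `deaths` per
#'   group-year.
#' @param life_table A [life_table()] covering every (gender, age band)
#'   present; a missing stratum is an error naming the stratum.
#' @return Euros: `deaths` times the stratum LYoL cost, per row.
#' @export
lyol_total <- function(panel, life_table) {
  life_table <- validate_life_table(life_table)
  panel$deaths * lookup_life_table(life_table, panel, "lyol_cost_eur")
}

#' Corrected spending
#'
#' Subtracts the mortality-driven last-year-of-life costs from raw
#' spending. Cells where the correction exhausts spending (`C <= 0`)
#' cannot enter a log model and are flagged excluded, never floored.
#'
#' @param panel Data frame with `group_id`, `gender`, `age_band`,
#'   `year`, `deaths` and `spending_eur` per group-year.
#' @inheritParams lyol_total
#' @return An object of class `correction_result`: the panel with
#'   `lyol_eur`, `corrected_eur`, `excluded` and `exclude_reason`
#'   columns; `attr(, "exclusion_fraction")` reports the share of
#'   flagged cells.
#' @export
corrected_spending <- function(panel, life_table) {
  lyol <- lyol_total(panel, life_table)
  corrected <- panel$spending_eur - lyol
  excluded <- corrected <= 0
  out <- panel
  out$lyol_eur <- lyol
  out$corrected_eur <- corrected
  out$excluded <- excluded
  out$exclude_reason <- ifelse(excluded, "nonpositive corrected spending",
                               NA_character_)
  structure(out, exclusion_fraction = mean(excluded),
            class = c("correction_result", "data.frame"))
}

#' Per-year exclusion report for a spending correction
#'
#' @param result A [corrected_spending()] result.
#' @return Data frame with one row per year: cells, excluded cells,
#'   exclusion fraction.
#' @export
correction_report <- function(result) {
  stopifnot(inherits(result, "correction_result"))
  agg <- stats::aggregate(cbind(cells = rep(1L, nrow(result)),
                                excluded = as.integer(result$excluded)) ~
                            year, data = result, FUN = sum)
  agg$fraction_excluded <- agg$excluded / agg$cells
  agg
}
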