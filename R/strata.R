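#' Define the patient-group stratification
#'
#' Patient groups are the cells of a gender x five-year-age-band x
#' disease-group cross-classification, observed over a short panel of
#' calendar years. The full Dutch hospital configuration is 2 genders,
#' 21 age bands and 405 disease groups over 2012-2014; smaller
#' configurations are used for simulation and testing.
#'
#' @param n_genders Number of gender strata (default 2).
#' @param n_age_bands Number of five-year age bands (default 21,
#'   covering ages 0 to 95+).
#' @param n_diseases Number of disease groups (default 30; set to 405
#'   to mirror the full national classification).
#' @param years Ordered integer vector of calendar years (default
#'   `2012:2014`).
#' @return An object of class `strata_config`.
#' @examples
#' strata_config(n_diseases = 405)
#' @export
strata_config <- function(n_genders = 2L, n_age_bands = 21L,
                          n_diseases = 30L, years = 2012:2014) {
  n_genders <- as.integer(n_genders)
  n_age_bands <- as.integer(n_age_bands)
  n_diseases <- as.integer(n_diseases)
  years <- as.integer(years)
  if (any(c(n_genders, n_age_bands, n_diseases) < 1L))
    stop("all stratum counts must be >= 1", call. = FALSE)
  if (length(years) < 1L || is.unsorted(years, strictly = TRUE))
    stop("`years` must be strictly increasing", call. = FALSE)
  structure(
    list(n_genders = n_genders, n_age_bands = n_age_bands,
         n_diseases = n_diseases, years = years),
    class = "strata_config"
  )
}

#' @export
print.strata_config <- function(x, ...) {
  cat(sprintf(
    "Patient-group strata: %d genders x %d age bands x %d diseases = %d groups; years %s-%s\n",
    x$n_genders, x$n_age_bands, x$n_diseases,
    x$n_genders * x$n_age_bands * x$n_diseases,
    min(x$years), max(x$years)))
  invisible(x)
}

#' Enumerate all patient-group keys
#'
#' Returns the cartesian product of the strata, one row per possible
#' patient group. With the full configuration (2 x 21 x 405) this
#' enumerates 17,010 group keys.
#'
#' @param strata A [strata_config()].
#' @return A data frame with columns `group_id`, `gender` (1-based
#'   index), `age_band` (0-based index, band k covering ages 5k to
#'   5k+4), and `disease` (1-based index), ordered by (gender,
#'   age_band, disease).
#' @export
enumerate_groups <- function(strata) {
  stopifnot(inherits(strata, "strata_config"))
  keys <- expand.grid(disease = seq_len(strata$n_diseases),
                      age_band = seq_len(strata$n_age_bands) - 1L,
                      gender = seq_len(strata$n_genders),
                      KEEP.OUT.ATTRS = FALSE)
  keys <- keys[, c("gender", "age_band", "disease")]
  keys <- keys[order(keys$gender, keys$age_band, keys$disease), ]
  rownames(keys) <- NULL
  keys$group_id <- sprintf("g%d_a%02d_d%03d",
                           keys$gender, keys$age_band, keys$disease)
  keys[, c("group_id", "gender", "age_band", "disease")]
}
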