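# Life-table inputs: healthy life expectancy and last-year-of-life cost
# per (gender, age band), each with a dispersion used by the Monte Carlo.

# Published Dutch estimates of hospital spending in the last year of life,
# by five-year age band 0, 1-5, ..., 95+ (2014 euros).
.nl_lyol_costs <- c(
  25219, 8225, 7405, 8380, 10248, 12626, 15511, 17409, 18997, 22535,
  28168, 33159, 35690, 34355, 31097, 28362, 24053, 17086, 10969, 6607, 4249
)

#' Construct a life table
#'
#' A life table supplies, per gender and five-year age band, the remaining
#' healthy life expectancy (HLE, in undiscounted years) and the mean
#' hospital cost incurred in the last year of life (LYoL, in euros), each
#' with a standard deviation used when parameter uncertainty is propagated.
#'
#' @param gender,age_band Integer vectors identifying the stratum
#'   (gender 1-based, age band 0-based).
#' @param hle_years Healthy life expectancy, years (>= 0).
#' @param lyol_cost_eur Last-year-of-life cost, euros (>= 0).
#' @param hle_sd,lyol_sd Standard deviations; `lyol_sd` defaults to 10%
#'   of the mean cost, the conventional assumption when no source SD is
#'   available.
#' @return A data frame of class `life_table`.
#' @export
life_table <- function(gender, age_band, hle_years, lyol_cost_eur,
                       hle_sd = 0.05 * hle_years,
                       lyol_sd = 0.10 * lyol_cost_eur) {
  lt <- data.frame(gender = as.integer(gender),
                   age_band = as.integer(age_band),
                   hle_years = as.numeric(hle_years),
                   hle_sd = as.numeric(hle_sd),
                   lyol_cost_eur = as.numeric(lyol_cost_eur),
                   lyol_sd = as.numeric(lyol_sd))
  validate_life_table(lt)
}

validate_life_table <- function(lt) {
  req <- c("gender", "age_band", "hle_years", "hle_sd",
           "lyol_cost_eur", "lyol_sd")
  miss <- setdiff(req, names(lt))
  if (length(miss))
    stop("life table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(lt[, c("gender", "age_band")]))
    stop("life table has duplicate (gender, age_band) rows", call. = FALSE)
  if (any(lt$hle_years < 0) || any(lt$lyol_cost_eur < 0))
    stop("life table values must be non-negative", call. = FALSE)
  if (any(lt$hle_sd < 0) || any(lt$lyol_sd < 0))
    stop("life table SDs must be non-negative", call. = FALSE)
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Synthetic default life table
#'
#' Builds a plausible life table for a given stratification: healthy life
#' expectancy declines roughly linearly from about 66 years at birth to
#' just over a year in the oldest band (women slightly higher), and
#' last-year-of-life costs follow the hump-shaped age profile of published
#' Dutch estimates (peaking near €36k around ages 56-60 and falling in the
#' oldest bands). Values are synthetic defaults for simulation, not a
#' statistical agency product.
#'
#' @param strata A [strata_config()].
#' @return A `life_table` covering every (gender, age_band) in `strata`.
#' @export
synthetic_life_table <- function(strata) {
  stopifnot(inherits(strata, "strata_config"))
  bands <- seq_len(strata$n_age_bands) - 1L
  # map bands onto the 21-band reference cost profile
  ref_pos <- if (strata$n_age_bands == 1L) 1
             else 1 + (bands / max(bands)) * 20
  lyol <- stats::approx(seq_along(.nl_lyol_costs), .nl_lyol_costs,
                        xout = ref_pos, rule = 2)$y
  grid <- expand.grid(age_band = bands,
                      gender = seq_len(strata$n_genders),
                      KEEP.OUT.ATTRS = FALSE)
  hle <- pmax(1.2, 66 - 3.25 * grid$age_band + 1.5 * (grid$gender - 1))
  life_table(gender = grid$gender, age_band = grid$age_band,
             hle_years = hle, lyol_cost_eur = lyol[grid$age_band + 1L])
}

# lookup vector aligned to (gender, age_band) rows of `keys`
lookup_life_table <- function(lt, keys, column) {
  idx <- match(paste(keys$gender, keys$age_band),
               paste(lt$gender, lt$age_band))
  if (anyNA(idx)) {
    bad <- unique(paste0("(gender=", keys$gender[is.na(idx)],
                         ", age_band=", keys$age_band[is.na(idx)], ")"))
    stop("life table does not cover strata: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  lt[[column]][idx]
}
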