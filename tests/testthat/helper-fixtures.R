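# Shared fixtures, built in code at test time.

small_strata <- function(n_diseases = 8L, n_age_bands = 5L,
                         years = 2012:2014) {
  strata_config(n_genders = 2L, n_age_bands = n_age_bands,
                n_diseases = n_diseases, years = years)
}

# a tariff whose decrements are easy to hand-sum in oracle checks
fixture_tariff <- function() synthetic_tariff()

# small noisy panel plus its latent outcome panel and truth
small_generation <- function(seed = 7L, n_diseases = 8L, ...) {
  s <- small_strata(n_diseases = n_diseases)
  tr <- synthetic_truth(s, ...)
  gen <- generate_panel(s, tr, seed = seed)
  list(strata = s, truth = tr, gen = gen,
       panel = latent_outcome_panel(gen))
}

# hand-built outcome panel for direct estimation tests
manual_outcome_panel <- function(df) {
  df$morbidity_qaly <- df$morbidity_qaly %||% NA_real_
  df$death_qaly <- df$death_qaly %||% NA_real_
  df$gender <- df$gender %||% 1L
  df$age_band <- df$age_band %||% 0L
  df$disease <- df$disease %||% 1L
  df$time_index <- df$time_index %||% (df$year - min(df$year))
  df$excluded <- df$excluded %||% FALSE
  df$exclude_reason <- df$exclude_reason %||% NA_character_
  qalythreshold:::new_outcome_panel(as.data.frame(df))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent annuity-due oracle: explicit year-by-year summation
npv_oracle <- function(hle, rate) {
  total <- 0
  t <- 0
  remaining <- hle
  while (remaining > 1e-12) {
    slice <- min(1, remaining)
    total <- total + slice / (1 + rate)^t
    remaining <- remaining - slice
    t <- t + 1
  }
  total
}
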