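# Fixed-effects translog production function for hospital care.
#
# QALY loss Q of a patient group is modelled as a second-order
# log-polynomial in corrected spending C and patient count N with a
# linear time trend and a group fixed effect:
#
#   log Q_it = a_i + b T_t + c1 logC + c2 (logC)^2 + d1 logN
#              + d2 (logN)^2 + c3 logC logN + u_it
#
# The spending elasticity at a point is e = c1 + 2 c2 logC + c3 logN
# (negative: more spending, less QALY loss), and the marginal cost of a
# QALY at the arithmetic means is C / (|e| Q).

.translog_regressors <- c("time_index", "logC", "logC_sq",
                          "logN", "logN_sq", "logC_logN")

#' Build the translog design matrix
#'
#' Log-transforms the non-excluded cells of an outcome panel into the
#' translog regressors. Groups left with fewer than two observations
#' carry no within-group information and are dropped from the design.
#'
#' @param panel An `outcome_panel` (see [compute_outcomes()] or
#'   [latent_outcome_panel()]).
#' @return A data frame of class `translog_design` with columns
#'   `group_id`, `year`, `logQ`, `time_index`, `logC`, `logC_sq`,
#'   `logN`, `logN_sq`, `logC_logN`, ordered by (group, year);
#'   `attr(, "n_singleton_groups")` counts the dropped groups.
#' @export
build_design <- function(panel) {
  d <- panel[!panel$excluded, , drop = FALSE]
  if (any(d$qaly_loss <= 0 | d$corrected_eur <= 0 | d$patients <= 0))
    stop("internal error: nonpositive Q/C/N reached the design stage; ",
         "upstream exclusion failed", call. = FALSE)
  logC <- log(d$corrected_eur)
  logN <- log(d$patients)
  out <- data.frame(
    group_id = d$group_id, year = d$year,
    logQ = log(d$qaly_loss),
    time_index = d$year - min(panel$year),
    logC = logC, logC_sq = logC^2,
    logN = logN, logN_sq = logN^2,
    logC_logN = logC * logN
  )
  out <- out[order(out$group_id, out$year), ]
  rownames(out) <- NULL
  sizes <- table(out$group_id)
  singletons <- names(sizes)[sizes < 2L]
  out <- out[!(out$group_id %in% singletons), , drop = FALSE]
  if (!all(is.finite(as.matrix(out[, c("logQ", .translog_regressors)]))))
    stop("non-finite values in the design matrix", call. = FALSE)
  structure(out, n_singleton_groups = length(singletons),
            class = c("translog_design", "data.frame"))
}

# entity-demean columns of matrix m by group factor g
within_demean <- function(m, g) {
  means <- rowsum(m, g) / as.vector(table(g))
  m - means[as.character(g), , drop = FALSE]
}

#' Fit the translog model by the within (fixed-effects) estimator
#'
#' Entity-demeans the response and the six regressors and solves the
#' least-squares problem directly; this is numerically identical to
#' least squares with one indicator per group (LSDV) but scales to tens
#' of thousands of groups. Degrees of freedom, the within R-squared and
#' the F statistic account for the absorbed group means. Conventional
#' homoskedastic standard errors are the default; group-clustered
#' robust errors are available.
#'
#' @param design A [build_design()] result.
#' @param cluster Logical: report group-clustered robust standard
#'   errors instead of conventional ones.
#' @return An object of class `translog_fit`: named `coefficients`
#'   (`time_index`, `logC`, `logC_sq`, `logN`, `logN_sq`,
#'   `logC_logN`), `vcov`, `constant` (mean fixed effect, the LSDV
#'   intercept), `n`, `n_groups`, `df_residual`, `sigma`, `r_squared`
#'   (within), `f_statistic`.
#' @export
fit_fixed_effects <- function(design, cluster = FALSE) {
  stopifnot(inherits(design, "translog_design"))
  g <- factor(design$group_id)
  G <- nlevels(g)
  if (G < 2L) stop("need >= 2 groups with >= 2 observations", call. = FALSE)
  y <- design$logQ
  X <- as.matrix(design[, .translog_regressors])
  k <- ncol(X)

  Xd <- within_demean(X, g)
  yd <- within_demean(matrix(y, ncol = 1L), g)[, 1L]
  qrX <- qr(Xd)
  if (qrX$rank < k) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("design is singular after the within transformation; ",
         "collinear columns: ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qrX, yd)
  resid <- yd - Xd %*% beta
  n <- length(y)
  df <- n - G - k
  if (df <= 0) stop("not enough observations for the within fit",
                    call. = FALSE)
  ssr <- sum(resid^2)
  sst <- sum(yd^2)
  sigma2 <- ssr / df
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                 drop = FALSE]
  vc <- sigma2 * XtX_inv
  if (cluster) {
    Xe <- Xd * as.vector(resid)
    meat <- crossprod(rowsum(Xe, g))
    adj <- (G / (G - 1)) * ((n - 1) / df)
    vc <- adj * XtX_inv %*% meat %*% XtX_inv
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = stats::setNames(as.vector(beta), colnames(X)),
    vcov = vc,
    constant = mean(y) - sum(colMeans(X) * beta),
    n = n, n_groups = G, df_residual = df,
    sigma = sqrt(sigma2),
    r_squared = 1 - ssr / sst,
    f_statistic = ((sst - ssr) / k) / sigma2,
    cluster = cluster
  ), class = "translog_fit")
}

#' @export
print.translog_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tval <- x$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df = x$df_residual, lower.tail = FALSE)
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  cat(sprintf(
    "Fixed-effects translog fit: n = %d, groups = %d, within R2 = %.4f, F(%d,%d) = %.2f%s\n",
    x$n, x$n_groups, x$r_squared, length(x$coefficients), x$df_residual,
    x$f_statistic, if (x$cluster) " (clustered SEs)" else ""))
  stats::printCoefmat(tab, digits = 4)
  cat(sprintf("Constant (mean fixed effect): %.4f\n", x$constant))
  invisible(x)
}

#' Tidy coefficient table for a translog fit
#'
#' @param fit A [fit_fixed_effects()] result.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Data frame with term, estimate, SE, t, p and confidence
#'   bounds — the layout of a standard regression results table.
#' @export
coef_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "translog_fit"))
  se <- sqrt(diag(fit$vcov))
  tval <- fit$coefficients / se
  q <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df_residual)
  data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    std_error = unname(se),
    t_value = unname(tval),
    p_value = unname(2 * stats::pt(abs(tval), df = fit$df_residual,
                                   lower.tail = FALSE)),
    conf_low = unname(fit$coefficients - q * se),
    conf_high = unname(fit$coefficients + q * se)
  )
}

# pull (c1, c2, c3) out of a fit or a named vector/list
translog_terms <- function(object) {
  cf <- if (inherits(object, "translog_fit")) object$coefficients
        else unlist(object)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(cf)) return(unname(cf[[nm]]))
    stop("cannot find coefficient ", ..1, call. = FALSE)
  }
  list(c1 = pick("logC", "c1"), c2 = pick("logC_sq", "c2"),
       c3 = pick("logC_logN", "c3"))
}

#' Spending elasticity of QALY loss at a point
#'
#' Evaluates the derivative of log QALY loss with respect to log
#' corrected spending at the supplied point: `c1 + 2*c2*logC +
#' c3*logN`. The factor 2 arises because `c2` is the regression
#' coefficient on `(logC)^2`, i.e. half the Taylor curvature term.
#'
#' @param object A [fit_fixed_effects()] result, or a named vector /
#'   list supplying `logC` (or `c1`), `logC_sq` (`c2`) and `logC_logN`
#'   (`c3`).
#' @param mean_logC,mean_logN Evaluation point, conventionally the
#'   sample means of the logs.
#' @return The elasticity (dimensionless; negative means extra spending
#'   reduces QALY loss).
#' @examples
#' elasticity_at(c(c1 = -0.0461, c2 = 0.0033, c3 = -0.0372), 11.97, 5.10)
#' @export
elasticity_at <- function(object, mean_logC, mean_logN) {
  tm <- translog_terms(object)
  tm$c1 + 2 * tm$c2 * mean_logC + tm$c3 * mean_logN
}

#' Marginal cost per QALY (cost-effectiveness threshold)
#'
#' Converts the elasticity at the mean into a marginal effect at the
#' arithmetic means: the euros of extra spending needed to avert one
#' QALY of loss, `mean_C / (|e| * mean_Q)`. Also reports what a 1%
#' spending increase buys: `|e|/100 * mean_Q` QALYs for
#' `mean_C / 100` euros.
#'
#' @param e Spending elasticity (must be negative; a non-negative
#'   elasticity leaves the threshold undefined and is an error).
#' @param mean_Q Arithmetic mean QALY loss per group-year (> 0).
#' @param mean_C Arithmetic mean corrected spending, euros (> 0).
#' @return An object of class `threshold_estimate` with `threshold`
#'   (EUR/QALY), `elasticity`, `mean_Q`, `mean_C`, `gain_per_1pct`
#'   (QALYs) and `spend_1pct` (EUR).
#' @examples
#' qaly_threshold(-0.156818, 145.73, 1678091)
#' @export
qaly_threshold <- function(e, mean_Q, mean_C) {
  if (!is.finite(e) || e >= 0)
    stop("non-negative elasticity: the marginal cost per QALY is ",
         "undefined (spending does not reduce QALY loss at the mean)",
         call. = FALSE)
  if (mean_Q <= 0 || mean_C <= 0)
    stop("`mean_Q` and `mean_C` must be positive", call. = FALSE)
  structure(list(
    threshold = mean_C / (abs(e) * mean_Q),
    elasticity = e, mean_Q = mean_Q, mean_C = mean_C,
    gain_per_1pct = abs(e) / 100 * mean_Q,
    spend_1pct = mean_C / 100
  ), class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Cost-effectiveness threshold: EUR %s per QALY\n",
              format(round(x$threshold), big.mark = ",")))
  cat(sprintf("  elasticity %.4f at means (Q = %.2f, C = EUR %s)\n",
              x$elasticity, x$mean_Q,
              format(round(x$mean_C), big.mark = ",")))
  cat(sprintf("  a 1%% spending increase (EUR %s) averts %.2f QALYs of loss\n",
              format(round(x$spend_1pct), big.mark = ","), x$gain_per_1pct))
  if (!is.null(x$se))
    cat(sprintf("  bootstrap SE EUR %s; 95%% CI [%s, %s] (normal), [%s, %s] (percentile)\n",
                format(round(x$se), big.mark = ","),
                format(round(x$ci_normal[1]), big.mark = ","),
                format(round(x$ci_normal[2]), big.mark = ","),
                format(round(x$ci_percentile[1]), big.mark = ","),
                format(round(x$ci_percentile[2]), big.mark = ",")))
  invisible(x)
}

# sample means used for evaluation: means of logs for the elasticity,
# arithmetic means for the marginal effect
panel_means <- function(panel) {
  d <- panel[!panel$excluded, , drop = FALSE]
  list(mean_logC = mean(log(d$corrected_eur)),
       mean_logN = mean(log(d$patients)),
       mean_Q = mean(d$qaly_loss),
       mean_C = mean(d$corrected_eur))
}

#' Point estimate of the threshold from an outcome panel
#'
#' Convenience wrapper: builds the design, fits the within estimator,
#' evaluates the elasticity at the sample means of the logs, and
#' converts it to a threshold at the arithmetic means.
#'
#' @param panel An `outcome_panel`.
#' @param cluster Passed to [fit_fixed_effects()].
#' @return A `threshold_estimate` with the `translog_fit` attached as
#'   `$fit` and the evaluation point as `$mean_logC`, `$mean_logN`.
#' @export
estimate_threshold <- function(panel, cluster = FALSE) {
  fit <- fit_fixed_effects(build_design(panel), cluster = cluster)
  m <- panel_means(panel)
  e <- elasticity_at(fit, m$mean_logC, m$mean_logN)
  est <- qaly_threshold(e, m$mean_Q, m$mean_C)
  est$fit <- fit
  est$mean_logC <- m$mean_logC
  est$mean_logN <- m$mean_logN
  est
}

#' Cluster bootstrap of the threshold
#'
#' Resamples patient groups (each group's full time series) with
#' replacement, refits the translog model, and re-evaluates the
#' elasticity and threshold at the original sample's means — so the
#' replicate spread reflects coefficient uncertainty, assuming the
#' evaluation point fixed. The SE is the replicate standard deviation;
#' the normal-approximation interval is the point estimate ± 1.96 SE,
#' and a percentile interval is reported alongside. Replicates with a
#' non-negative elasticity leave the threshold undefined and are
#' excluded from the SE, with their count reported.
#'
#' @param panel An `outcome_panel`.
#' @param reps Bootstrap replicates (>= 2; 100 is the conventional
#'   choice at this problem size).
#' @param seed Integer seed; the same seed reproduces the replicate set
#'   exactly.
#' @return A `threshold_estimate` with `se`, `ci_normal`,
#'   `ci_percentile`, `reps_used`, `reps_failed`, and the replicate
#'   thresholds in `$replicates`.
#' @export
bootstrap_threshold <- function(panel, reps = 100L, seed = 1L) {
  reps <- as.integer(reps)
  if (reps < 2L) stop("`reps` must be >= 2", call. = FALSE)
  point <- estimate_threshold(panel)
  design <- build_design(panel)
  groups <- unique(design$group_id)
  rows_by_group <- split(seq_len(nrow(design)), design$group_id)

  draw <- with_stream(seed, 21L,
                      matrix(sample(length(groups), reps * length(groups),
                                    replace = TRUE),
                             nrow = reps))
  thr <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    picked <- groups[draw[r, ]]
    idx <- unlist(rows_by_group[picked], use.names = FALSE)
    rd <- design[idx, , drop = FALSE]
    # resampled copies of a group must act as distinct clusters
    rd$group_id <- rep(seq_along(picked),
                       lengths(rows_by_group[picked]))
    class(rd) <- class(design)
    fit_r <- fit_fixed_effects(rd)
    e_r <- elasticity_at(fit_r, point$mean_logC, point$mean_logN)
    if (is.finite(e_r) && e_r < 0)
      thr[r] <- point$mean_C / (abs(e_r) * point$mean_Q)
  }
  ok <- thr[!is.na(thr)]
  if (!length(ok)) stop("all bootstrap replicates failed", call. = FALSE)
  point$se <- if (length(ok) > 1L) stats::sd(ok) else 0
  point$ci_normal <- point$threshold + c(-1, 1) * 1.96 * point$se
  point$ci_percentile <- unname(stats::quantile(ok, c(0.025, 0.975)))
  point$reps_used <- length(ok)
  point$reps_failed <- reps - length(ok)
  point$replicates <- thr
  point
}

#' Thresholds per subgroup
#'
#' Evaluates the pooled fixed-effects fit's elasticity at each
#' stratum's own means of the logs and converts it at the stratum's
#' arithmetic means (the default), or refits the model within each
#' stratum. Strata too small to evaluate are flagged in the output
#' rather than dropped.
#'
#' @param panel An `outcome_panel`.
#' @param stratifier One of `"gender"`, `"age_band"`, `"disease"`.
#' @param refit Refit the translog model per stratum instead of
#'   evaluating the pooled fit at stratum means.
#' @return Data frame with one row per stratum: means, elasticity,
#'   threshold, and a `status` column (`"ok"`, `"too small"`,
#'   `"non-negative elasticity"`).
#' @export
subgroup_thresholds <- function(panel,
                                stratifier = c("gender", "age_band",
                                               "disease"),
                                refit = FALSE) {
  stratifier <- match.arg(stratifier)
  pooled <- if (!refit) fit_fixed_effects(build_design(panel)) else NULL
  strata <- sort(unique(panel[[stratifier]]))
  rows <- lapply(strata, function(s) {
    sub <- panel[panel[[stratifier]] == s, , drop = FALSE]
    class(sub) <- class(panel)
    base <- data.frame(stratum = s, n_cells = sum(!sub$excluded))
    m <- tryCatch(panel_means(sub), error = function(e) NULL)
    fit <- if (refit) {
      tryCatch(fit_fixed_effects(build_design(sub)),
               error = function(e) NULL)
    } else pooled
    if (is.null(fit) || is.null(m) || base$n_cells < 4L)
      return(cbind(base, elasticity = NA_real_, threshold = NA_real_,
                   status = "too small"))
    e <- elasticity_at(fit, m$mean_logC, m$mean_logN)
    if (!is.finite(e) || e >= 0)
      return(cbind(base, elasticity = e, threshold = NA_real_,
                   status = "non-negative elasticity"))
    cbind(base, elasticity = e,
          threshold = m$mean_C / (abs(e) * m$mean_Q), status = "ok")
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- stratifier
  out
}

#' Alternative model specifications
#'
#' Refits the production function under alternative structural forms
#' and outcome definitions, as robustness checks around the translog
#' main specification:
#' * `cobb_douglas` drops the quadratic and interaction terms; the
#'   elasticity is then the constant coefficient on `logC`.
#' * `linear` regresses levels (`Q` on `C`, `N`, trend, within groups);
#'   the coefficient on `C` is minus the marginal QALY gain per euro,
#'   so the threshold is `1/|coef|` directly.
#' * `outcome` swaps the response: total, death-related or
#'   morbidity-related QALY loss, or raw death counts.
#' * `time_dummies` replaces the linear trend with year indicators.
#' * `lagged_spending` relates year-`t` spending to year-`t+1`
#'   outcomes (the panel shrinks by one year; needs >= 3 years).
#'
#' @param panel An `outcome_panel` (must carry a `deaths` column for
#'   `outcome = "mortality_counts"`).
#' @param spec `"translog"`, `"cobb_douglas"` or `"linear"`.
#' @param outcome `"total"`, `"death_only"`, `"morbidity_only"` or
#'   `"mortality_counts"`.
#' @param time_dummies,lagged_spending Logical options.
#' @return A `threshold_estimate` (with `$fit`); for log
#'   specifications evaluated exactly like the main model.
#' @export
alternative_spec <- function(panel,
                             spec = c("translog", "cobb_douglas", "linear"),
                             outcome = c("total", "death_only",
                                         "morbidity_only",
                                         "mortality_counts"),
                             time_dummies = FALSE,
                             lagged_spending = FALSE) {
  spec <- match.arg(spec)
  outcome <- match.arg(outcome)
  p <- as.data.frame(panel)
  p$outcome_value <- switch(outcome,
    total = p$qaly_loss,
    death_only = p$death_qaly,
    morbidity_only = p$morbidity_qaly,
    mortality_counts = {
      if (is.null(p$deaths))
        stop("panel carries no `deaths` column", call. = FALSE)
      p$deaths
    })
  if (lagged_spending) {
    if (length(unique(p$year)) < 3L)
      stop("lagged spending requires >= 3 panel years", call. = FALSE)
    nxt <- p[, c("group_id", "year", "outcome_value")]
    nxt$year <- nxt$year - 1L
    key <- paste(p$group_id, p$year)
    p$outcome_value <- nxt$outcome_value[match(key,
                                               paste(nxt$group_id, nxt$year))]
    p <- p[!is.na(p$outcome_value), , drop = FALSE]
  }
  p$excluded <- p$excluded | is.na(p$outcome_value) |
    (spec != "linear" & p$outcome_value <= 0)
  d <- p[!p$excluded, , drop = FALSE]
  g <- factor(d$group_id)
  keep <- as.character(g) %in% names(which(table(g) >= 2L))
  d <- d[keep, , drop = FALSE]
  g <- factor(d$group_id)

  trend_mat <- if (time_dummies) {
    yrs <- sort(unique(d$year))
    m <- outer(d$year, yrs[-1L], `==`) * 1
    colnames(m) <- paste0("year_", yrs[-1L])
    m
  } else matrix(d$year - min(d$year), ncol = 1L,
                dimnames = list(NULL, "time_index"))

  if (spec == "linear") {
    X <- cbind(trend_mat, C = d$corrected_eur, N = d$patients)
    y <- d$outcome_value
  } else {
    logC <- log(d$corrected_eur); logN <- log(d$patients)
    X <- if (spec == "cobb_douglas")
      cbind(trend_mat, logC = logC, logN = logN)
    else cbind(trend_mat, logC = logC, logC_sq = logC^2,
               logN = logN, logN_sq = logN^2, logC_logN = logC * logN)
    y <- log(d$outcome_value)
  }
  fit <- within_ls(y, X, g)

  mean_Q <- mean(d$outcome_value)
  mean_C <- mean(d$corrected_eur)
  if (spec == "linear") {
    me <- unname(fit$coefficients[["C"]])
    if (!is.finite(me) || me >= 0)
      stop("non-negative marginal effect: threshold undefined",
           call. = FALSE)
    est <- structure(list(threshold = 1 / abs(me), elasticity = NA_real_,
                          marginal_effect = me, mean_Q = mean_Q,
                          mean_C = mean_C,
                          gain_per_1pct = abs(me) * mean_C / 100,
                          spend_1pct = mean_C / 100),
                     class = "threshold_estimate")
  } else {
    e <- if (spec == "cobb_douglas") unname(fit$coefficients[["logC"]])
         else elasticity_at(fit$coefficients, mean(log(d$corrected_eur)),
                            mean(log(d$patients)))
    est <- qaly_threshold(e, mean_Q, mean_C)
  }
  est$fit <- fit
  est$spec <- spec
  est$outcome <- outcome
  est
}

# generic within-group least squares used by alternative_spec
within_ls <- function(y, X, g) {
  Xd <- within_demean(X, g)
  yd <- within_demean(matrix(y, ncol = 1L), g)[, 1L]
  qrX <- qr(Xd)
  if (qrX$rank < ncol(X))
    stop("singular design in alternative specification", call. = FALSE)
  beta <- qr.coef(qrX, yd)
  n <- length(y); G <- nlevels(g); k <- ncol(X)
  resid <- yd - Xd %*% beta
  df <- n - G - k
  sigma2 <- sum(resid^2) / df
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                 drop = FALSE]
  vc <- sigma2 * XtX_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
       vcov = vc, n = n, n_groups = G, df_residual = df,
       r_squared = 1 - sum(resid^2) / sum(yd^2))
}

#' Reattribute deaths across patient groups by spending shares
#'
#' Multimorbidity device: deaths recorded against a primary-diagnosis
#' group are spread over the decedents' patient groups in proportion to
#' spending shares on secondary diagnoses. Total deaths are conserved
#' exactly.
#'
#' @param deaths Numeric vector: deaths per primary-diagnosis group.
#' @param shares Matrix with one row per primary-diagnosis group and
#'   one column per target patient group; each row must sum to 1
#'   (within 1e-9).
#' @return Numeric vector of reattributed deaths, one per target group
#'   (named after `colnames(shares)` when present).
#' @export
reattribute_deaths_proportional <- function(deaths, shares) {
  shares <- as.matrix(shares)
  if (length(deaths) != nrow(shares))
    stop("`deaths` must have one entry per row of `shares`", call. = FALSE)
  if (any(abs(rowSums(shares) - 1) > 1e-9))
    stop("each row of `shares` must sum to 1 (within 1e-9)", call. = FALSE)
  if (any(shares < 0)) stop("shares must be non-negative", call. = FALSE)
  out <- as.vector(crossprod(shares, deaths))
  names(out) <- colnames(shares)
  out
}
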