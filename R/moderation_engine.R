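#' Exposure-by-moderator interaction model
#'
#' Mean-centers the exposure and the moderator on the analysis sample, forms
#' their product after centering, and fits OLS of the outcome on exposure,
#' moderator, their product and any covariates. With centred inputs the
#' exposure main effect is the conditional exposure-outcome slope at the
#' average moderator level, and the slope at moderator level m is
#' `B_exposure + B_interaction * (m - mean(moderator))`. Conditional simple
#' slopes are reported at the moderator mean and one SD below/above it
#' (`slope_sd_offset` SDs via [analysis_config()]).
#'
#' @param exposure,moderator,outcome Numeric vectors.
#' @param covariates Optional named list or `data.frame`.
#' @param alpha Two-sided significance level for the interaction (default
#'   0.05).
#' @param sd_offset Moderator offset in SDs for the default simple slopes.
#' @return An object of class `moderation_result`: `b_interaction`, `se`,
#'   `p`, `r2`, `F`, `df`, `n`, `significant`, a `slopes` table, plus the
#'   coefficient vector/covariance and moderator moments needed by
#'   [simple_slopes()].
#' @export
fit_moderation <- function(exposure, moderator, outcome, covariates = NULL,
                           alpha = 0.05, sd_offset = 1.0) {
  covs <- if (is.null(covariates)) list() else as.list(as.data.frame(covariates))
  df <- data.frame(.x = exposure, .m = moderator, .y = outcome)
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 10L) abort("moderation needs >= 10 complete cases",
                     "insufficient_data")
  m_mean <- mean(df$.m); m_sd <- stats::sd(df$.m)
  x_mean <- mean(df$.x)
  df$.xc <- df$.x - x_mean
  df$.mc <- df$.m - m_mean
  df$.xm <- df$.xc * df$.mc
  rhs <- paste(c(".xc", ".mc", ".xm", names(covs)), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  if (anyNA(stats::coef(fit)))
    abort(paste0("collinear design; aliased term(s): ",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")), "collinear_design")
  sm <- suppressWarnings(summary(fit))  # zero-residual fixtures trip the perfect-fit warning
  ct <- sm$coefficients
  fs <- sm$fstatistic
  res <- structure(list(
    b_interaction = unname(ct[".xm", 1L]),
    se = unname(ct[".xm", 2L]),
    p = unname(ct[".xm", 4L]),
    b_exposure = unname(ct[".xc", 1L]),
    r2 = unname(sm$r.squared),
    F = unname(fs[1L]), df = unname(fs[2:3]),
    n = n, alpha = alpha,
    significant = unname(ct[".xm", 4L]) < alpha,
    coefs = stats::coef(fit), vcov = suppressWarnings(stats::vcov(fit)),
    df_residual = fit$df.residual,
    moderator_mean = m_mean, moderator_sd = m_sd,
    moderator_range = range(df$.m), exposure_mean = x_mean
  ), class = "moderation_result")
  res$slopes <- simple_slopes(
    res, m_mean + c(-sd_offset, 0, sd_offset) * m_sd)
  res
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("Interaction: B = %.4g (SE %.4g), p = %.3g, R2 = %.3f, n = %d\n",
              x$b_interaction, x$se, x$p, x$r2, x$n))
  print(x$slopes, row.names = FALSE)
  invisible(x)
}

#' Conditional simple slopes
#'
#' The conditional exposure-outcome slope at moderator level m is
#' `B_exposure + B_interaction * (m - mean(moderator))`; its standard error
#' comes from the coefficient covariance,
#' `sqrt(V_xx + mc^2 V_ii + 2 mc V_xi)`, with a two-sided t-test on the
#' model's residual degrees of freedom. Levels outside the observed
#' moderator range are computed with a warning.
#'
#' @param result A `moderation_result`.
#' @param levels Moderator values (raw scale) at which to evaluate.
#' @return `data.frame`: `level`, `level_centered`, `slope`, `se`, `p`.
#' @export
simple_slopes <- function(result, levels) {
  stopifnot(inherits(result, "moderation_result"))
  out_of_range <- levels < result$moderator_range[1] |
    levels > result$moderator_range[2]
  if (any(out_of_range))
    warn("simple-slope level(s) outside the observed moderator range")
  mc <- levels - result$moderator_mean
  V <- result$vcov
  bx <- result$coefs[".xc"]; bi <- result$coefs[".xm"]
  slope <- unname(bx + bi * mc)
  se <- sqrt(V[".xc", ".xc"] + mc^2 * V[".xm", ".xm"] +
               2 * mc * V[".xc", ".xm"])
  tval <- slope / se
  p <- 2 * stats::pt(abs(tval), df = result$df_residual, lower.tail = FALSE)
  data.frame(level = levels, level_centered = mc, slope = slope,
             se = unname(se), p = unname(p))
}

#' Tertile-coded methylation risk score
#'
#' For each moderating unit, empirical tertile cutpoints (quantiles at 1/3
#' and 2/3, linear interpolation) are computed on its non-missing values and
#' participants are coded -1/0/+1 by tertile, oriented by the unit's
#' interaction sign: a positive interaction puts the top tertile at +1, a
#' negative one at -1; the middle tertile is always 0; ties at a cutpoint go
#' to the lower tertile. The per-participant score is the sum over units
#' with available values (missing units contribute 0 and are counted).
#' Units with fewer than 3 distinct values are excluded with a warning.
#'
#' @param matrix Participants x units methylation matrix.
#' @param units `data.frame` with `unit_id` and `sign` (interaction signs),
#'   or a named sign vector.
#' @return An object of class `risk_score`: integer `score` per participant,
#'   `cutpoints` table, `contributions` matrix, `n_missing` per participant,
#'   `excluded` unit IDs.
#' @export
build_risk_score <- function(matrix, units) {
  if (is.data.frame(units)) {
    signs <- stats::setNames(units$sign, units$unit_id)
  } else signs <- units
  if (is.null(names(signs)) || !length(signs))
    abort("units must carry unit names", "lookup_error")
  absent <- setdiff(names(signs), colnames(matrix))
  if (length(absent))
    abort(paste0("unit(s) absent from matrix: ",
                 paste(absent, collapse = ", ")), "lookup_error")
  keep <- character(0); excluded <- character(0)
  cut_lo <- numeric(0); cut_hi <- numeric(0)
  contrib <- NULL
  for (u in names(signs)) {
    v <- matrix[, u]
    if (length(unique(v[!is.na(v)])) < 3L) {
      warn(paste0("unit '", u, "' has < 3 distinct values; excluded from risk score"))
      excluded <- c(excluded, u)
      next
    }
    q <- stats::quantile(v, c(1 / 3, 2 / 3), na.rm = TRUE, type = 7,
                         names = FALSE)
    code <- ifelse(is.na(v), 0L, ifelse(v <= q[1], -1L, ifelse(v <= q[2], 0L, 1L)))
    if (sign(signs[[u]]) < 0) code <- -code
    contrib <- cbind(contrib, code)
    keep <- c(keep, u); cut_lo <- c(cut_lo, q[1]); cut_hi <- c(cut_hi, q[2])
  }
  if (is.null(contrib))
    abort("no usable units for the risk score", "insufficient_data")
  colnames(contrib) <- keep
  rownames(contrib) <- rownames(matrix)
  score <- as.integer(rowSums(contrib))
  names(score) <- rownames(matrix)
  structure(list(
    score = score,
    cutpoints = data.frame(unit_id = keep, lower = cut_lo, upper = cut_hi,
                           sign = as.integer(sign(signs[keep])),
                           stringsAsFactors = FALSE),
    contributions = contrib,
    n_missing = rowSums(is.na(matrix[, keep, drop = FALSE])),
    excluded = excluded
  ), class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("Risk score over %d unit(s); range [%d, %d]\n",
              nrow(x$cutpoints), min(x$score), max(x$score)))
  print(table(x$score))
  invisible(x)
}

#' Cumulative moderation through the risk score
#'
#' Runs [fit_moderation()] with the tertile risk score as the moderator and
#' reports conditional exposure-outcome slopes at the mean score of each of
#' three equal score groups (low / mid / high score tertiles).
#'
#' @param x A `methylation_cohort` or `preprocessed_cohort`.
#' @param risk_score A [build_risk_score()] result.
#' @param covariates Phenotype column names to adjust for.
#' @param alpha Interaction significance level (default from config).
#' @return A `moderation_result` whose `group_slopes` field holds the
#'   low/mid/high conditional slopes and group mean scores.
#' @export
moderate_cumulative <- function(x, risk_score, covariates = character(0),
                                alpha = NULL) {
  co <- if (inherits(x, "preprocessed_cohort")) x$cohort else x
  stopifnot(inherits(co, "methylation_cohort"), inherits(risk_score, "risk_score"))
  alpha <- alpha %||% co$config$screen_alpha
  ph <- co$phenotypes
  score <- risk_score$score[as.character(ph$participant_id)]
  covs <- if (length(covariates)) ph[, covariates, drop = FALSE] else NULL
  res <- fit_moderation(ph$maltreatment, score, ph$depression,
                        covariates = covs, alpha = alpha,
                        sd_offset = co$config$slope_sd_offset)
  q <- stats::quantile(score, c(1 / 3, 2 / 3), na.rm = TRUE, type = 7,
                       names = FALSE)
  grp <- ifelse(score <= q[1], "low", ifelse(score <= q[2], "mid", "high"))
  means <- tapply(score, factor(grp, levels = c("low", "mid", "high")), mean)
  means <- means[!is.na(means)]  # a tertile can be empty under heavy ties
  st <- simple_slopes(res, as.numeric(means))
  st$group <- names(means)
  st$mean_score <- as.numeric(means)
  res$group_slopes <- st[, c("group", "mean_score", "slope", "se", "p")]
  res
}
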