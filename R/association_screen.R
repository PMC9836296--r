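#' Fit one linear model and extract a focal term
#'
#' Ordinary least squares with intercept on complete cases, reporting the
#' focal term's unstandardized coefficient, its standard error and two-sided
#' t-test p-value, together with whole-model R-squared, F statistic and
#' degrees of freedom.
#'
#' @param y Response vector.
#' @param predictors Named list (or data.frame) of predictor vectors.
#' @param focal Name of the predictor whose coefficient is reported.
#' @return An object of class `regression_result` with fields `term`, `B`,
#'   `SE`, `p`, `r2`, `F`, `df` (model, residual), `n`.
#' @examples
#' r <- fit_linear(c(2, 1, 4, 3, 5), list(x = 1:5), "x")
#' r$B
#' @export
fit_linear <- function(y, predictors, focal) {
  predictors <- as.data.frame(predictors, optional = TRUE)
  if (!focal %in% names(predictors))
    abort(paste0("focal term '", focal, "' not among predictors"),
          "config_error")
  df <- cbind(data.frame(.y = y), predictors)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < ncol(predictors) + 2L)
    abort(sprintf("too few complete cases (%d) for %d predictor(s)",
                  n, ncol(predictors)), "insufficient_data")
  if (stats::var(df$.y) == 0)
    abort("zero-variance response", "collinear_design")
  fit <- stats::lm(.y ~ ., data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    abort(paste0("collinear design; aliased term(s): ",
                 paste(bad, collapse = ", ")), "collinear_design")
  }
  sm <- suppressWarnings(summary(fit))  # zero-residual fixtures trip the perfect-fit warning
  ct <- sm$coefficients
  if (!focal %in% rownames(ct))
    abort(paste0("collinear design; focal term '", focal, "' not estimable"),
          "collinear_design")
  fs <- sm$fstatistic
  structure(list(
    term = focal,
    B = unname(ct[focal, 1L]),
    SE = unname(ct[focal, 2L]),
    p = unname(ct[focal, 4L]),
    r2 = unname(sm$r.squared),
    F = if (is.null(fs)) NA_real_ else unname(fs[1L]),
    df = if (is.null(fs)) c(NA_real_, NA_real_) else unname(fs[2:3]),
    n = n
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s: B = %.4g, SE = %.4g, p = %.3g, R2 = %.3f, F(%g, %g) = %.2f, n = %d\n",
              x$term, x$B, x$SE, x$p, x$r2, x$df[1], x$df[2], x$F, x$n))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values with enforced monotonicity,
#' clipped at 1, returned in the input order. Thin validated front-end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) abort("p-values must be numeric", "domain_error")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    abort("p-values outside [0, 1]", "domain_error")
  stats::p.adjust(p, method = "BH")
}

# One screen row: unadjusted and covariate-adjusted fit of a unit (or
# region) column against one phenotype, with per-row error capture.
#' @noRd
screen_one <- function(mvals, xvals, covs) {
  row <- list(b_unadj = NA_real_, se_unadj = NA_real_, p_unadj = NA_real_,
              r2_unadj = NA_real_, n_unadj = NA_integer_,
              b_adj = NA_real_, se_adj = NA_real_, p_adj = NA_real_,
              r2_adj = NA_real_, n_adj = NA_integer_, error = NA_character_)
  res <- tryCatch({
    un <- fit_linear(mvals, list(x = xvals), "x")
    row[c("b_unadj", "se_unadj", "p_unadj", "r2_unadj", "n_unadj")] <-
      list(un$B, un$SE, un$p, un$r2, un$n)
    if (length(covs)) {
      ad <- fit_linear(mvals, c(list(x = xvals), covs), "x")
      row[c("b_adj", "se_adj", "p_adj", "r2_adj", "n_adj")] <-
        list(ad$B, ad$SE, ad$p, ad$r2, ad$n)
    } else {
      row[c("b_adj", "se_adj", "p_adj", "r2_adj", "n_adj")] <-
        list(un$B, un$SE, un$p, un$r2, un$n)
    }
    row
  }, cpgmediate_error = function(e) {
    row$error <- conditionMessage(e)
    row
  })
  res
}

#' Per-unit linear screen
#'
#' Regresses each CpG unit (and, optionally, each multi-unit region) on one
#' phenotype: the unit's percent methylation is the dependent variable and
#' the exposure (maltreatment total) or the outcome (depression total) is
#' the independent variable, without and with covariate adjustment.
#' Benjamini-Hochberg adjusted p-values are computed over the family of
#' unit-level unadjusted p-values; region rows form their own family and are
#' never mixed with unit-level FDR. Fit failures (e.g. zero-variance units)
#' are recorded per row, not fatal.
#'
#' @param x A `methylation_cohort` or `preprocessed_cohort`.
#' @param side `"exposure"` screens methylation on the maltreatment total,
#'   `"outcome"` on the depression total.
#' @param covariates Phenotype column names used in the adjusted models.
#' @param include_regions Append region-level rows (requires a
#'   `preprocessed_cohort`).
#' @return A `data.frame` of class `screen_table` with one row per unit (and
#'   region): `unit_id`, `level`, B/SE/p/R2/n for both models, `fdr_p`,
#'   `sig_unadj`, `sig_adj`, `error`.
#' @export
screen_units <- function(x, side = c("exposure", "outcome"),
                         covariates = character(0),
                         include_regions = inherits(x, "preprocessed_cohort")) {
  side <- match.arg(side)
  pre <- if (inherits(x, "preprocessed_cohort")) x else NULL
  co <- if (is.null(pre)) x else pre$cohort
  stopifnot(inherits(co, "methylation_cohort"))
  alpha <- co$config$screen_alpha
  ph <- co$phenotypes
  xvals <- if (side == "exposure") ph$maltreatment else ph$depression
  covs <- lapply(stats::setNames(covariates, covariates),
                 function(cv) ph[[cv]])

  build <- function(mat, level) {
    rows <- lapply(colnames(mat), function(u)
      c(list(unit_id = u, level = level), screen_one(mat[, u], xvals, covs)))
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  tab <- build(co$methylation, "unit")
  tab$fdr_p <- fdr_adjust(tab$p_unadj)
  if (include_regions && !is.null(pre)) {
    multi <- pre$region_map$region_id[pre$region_map$n_members > 1L]
    if (length(multi)) {
      rt <- build(pre$regions[, multi, drop = FALSE], "region")
      rt$fdr_p <- fdr_adjust(rt$p_unadj)
      tab <- rbind(tab, rt)
    }
  }
  tab$sig_unadj <- !is.na(tab$p_unadj) & tab$p_unadj < alpha
  tab$sig_adj <- !is.na(tab$p_adj) & tab$p_adj < alpha
  rownames(tab) <- NULL
  structure(tab, class = c("screen_table", "data.frame"),
            side = side, covariates = covariates, alpha = alpha)
}

#' Data-driven confounder selection
#'
#' Retains a candidate covariate when a simple-regression association at
#' `p < alpha` is detected with the exposure, the outcome, or at least one
#' methylation unit. Qualifying associations are logged in the returned
#' vector's `"log"` attribute. Binary candidates with a single observed
#' level are excluded with a warning.
#'
#' @param x A `methylation_cohort` or `preprocessed_cohort`.
#' @param candidates Phenotype column names to consider.
#' @param alpha Retention threshold (default `confounder_alpha`, 0.10).
#' @return Character vector of retained candidate names, with a `"log"`
#'   attribute (`data.frame`: candidate, retained, n_unit_hits, p_exposure,
#'   p_outcome, min_p_units).
#' @export
select_confounders <- function(x, candidates = c("age", "drug_use", "smoking",
                                                 "alcohol", "bmi"),
                               alpha = NULL) {
  co <- if (inherits(x, "preprocessed_cohort")) x$cohort else x
  stopifnot(inherits(co, "methylation_cohort"))
  alpha <- alpha %||% co$config$confounder_alpha
  ph <- co$phenotypes
  candidates <- intersect(candidates, names(ph))
  log <- list()
  retained <- character(0)
  for (cand in candidates) {
    v <- ph[[cand]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      warn(paste0("candidate '", cand, "' has a single observed level; excluded"))
      log[[cand]] <- data.frame(candidate = cand, retained = FALSE,
                                n_unit_hits = NA_integer_,
                                p_exposure = NA_real_, p_outcome = NA_real_,
                                min_p_units = NA_real_)
      next
    }
    p_x <- simple_lm_p(v, ph$maltreatment)
    p_y <- simple_lm_p(v, ph$depression)
    p_units <- apply(co$methylation, 2L, function(m) simple_lm_p(v, m))
    hits <- sum(!is.na(p_units) & p_units < alpha)
    keep <- (!is.na(p_x) && p_x < alpha) || (!is.na(p_y) && p_y < alpha) ||
      hits > 0L
    if (keep) retained <- c(retained, cand)
    log[[cand]] <- data.frame(candidate = cand, retained = keep,
                              n_unit_hits = hits, p_exposure = p_x,
                              p_outcome = p_y,
                              min_p_units = suppressWarnings(
                                min(p_units, na.rm = TRUE)))
  }
  structure(retained, log = do.call(rbind, c(log, list(make.row.names = FALSE))))
}
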