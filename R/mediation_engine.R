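#' Select screening-gated mediation candidates
#'
#' Mediation is only attempted for units significantly associated with both
#' the exposure and the outcome. Returns the intersection of significant
#' units from the two screens, each annotated with the sign of its
#' exposure-association coefficient (used to orient the cumulative index).
#'
#' @param exposure_screen,outcome_screen `screen_table`s over the same unit
#'   universe (unit-level rows are compared).
#' @param use_adjusted Use covariate-adjusted significance flags and
#'   coefficients (default) instead of unadjusted ones.
#' @return `data.frame` with `unit_id`, `sign`, `b_exposure`, `b_outcome`;
#'   zero rows when the intersection is empty.
#' @export
select_mediation_candidates <- function(exposure_screen, outcome_screen,
                                        use_adjusted = TRUE) {
  ex <- exposure_screen[exposure_screen$level == "unit", , drop = FALSE]
  ou <- outcome_screen[outcome_screen$level == "unit", , drop = FALSE]
  if (!setequal(ex$unit_id, ou$unit_id))
    abort("screens cover different unit universes", "cohort_inconsistency")
  flag <- if (use_adjusted) "sig_adj" else "sig_unadj"
  bcol <- if (use_adjusted) "b_adj" else "b_unadj"
  both <- intersect(ex$unit_id[ex[[flag]]], ou$unit_id[ou[[flag]]])
  both <- ex$unit_id[ex$unit_id %in% both]  # keep screen order
  data.frame(
    unit_id = both,
    sign = as.integer(sign(ex[[bcol]][match(both, ex$unit_id)])),
    b_exposure = ex[[bcol]][match(both, ex$unit_id)],
    b_outcome = ou[[bcol]][match(both, ou$unit_id)],
    stringsAsFactors = FALSE
  )
}

#' Quasi-Bayesian Monte-Carlo mediation analysis
#'
#' Fits the two linear models of the product-of-coefficients mediation
#' estimator -- (1) mediator on exposure and (2) outcome on exposure and
#' mediator, both with covariates when supplied -- then draws `n_sims`
#' coefficient vectors from the multivariate-normal sampling distribution of
#' each model's estimates (quasi-Bayesian approximation). Per draw the
#' indirect effect is `a*b`, the direct effect `c'`, and the total effect
#' their sum; the outcome model carries no exposure-mediator interaction, so
#' the average causal mediation effect (ACME) is draw-wise `a*b`. Point
#' estimates come from the fitted coefficients; 95% percentile intervals and
#' a two-sided Monte-Carlo p-value for the ACME come from the draws. The
#' proportion mediated is `acme/total` per draw; draws with `|total| <
#' 1e-8` are excluded from that ratio's interval and counted. A
#' case-resampling bootstrap mode is provided for sensitivity.
#'
#' @param exposure,mediator,outcome Numeric vectors.
#' @param covariates Optional named list or `data.frame` of covariates.
#' @param n_sims Monte-Carlo draws (default 1000, minimum 100).
#' @param seed Integer seed for the draws.
#' @param method `"quasi-bayesian"` (default) or `"bootstrap"`.
#' @param conf_level Interval coverage (default 0.95).
#' @return An object of class `mediation_result`: `acme`, `ade`, `total`,
#'   `prop_mediated`, percentile intervals `ci_acme`, `ci_ade`, `ci_total`,
#'   `ci_prop`, `p_acme`, `n_sims`, `n`, and the component `a_path` /
#'   `b_path` regression results.
#' @export
fit_mediation <- function(exposure, mediator, outcome, covariates = NULL,
                          n_sims = 1000L, seed = NULL,
                          method = c("quasi-bayesian", "bootstrap"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (n_sims < 100L) abort("n_sims must be >= 100", "config_error")
  covs <- if (is.null(covariates)) list() else as.list(as.data.frame(covariates))
  df <- data.frame(.x = exposure, .m = mediator, .y = outcome)
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 10L) abort("mediation needs >= 10 complete cases", "insufficient_data")
  if (stats::var(df$.m) == 0)
    abort("degenerate mediator: zero variance", "degenerate_mediator")

  rhs <- paste(c(".x", names(covs)), collapse = " + ")
  m1 <- stats::lm(stats::as.formula(paste(".m ~", rhs)), data = df)
  m2 <- stats::lm(stats::as.formula(paste(".y ~", rhs, "+ .m")), data = df)
  a_hat <- unname(stats::coef(m1)[".x"])
  b_hat <- unname(stats::coef(m2)[".m"])
  cp_hat <- unname(stats::coef(m2)[".x"])
  if (anyNA(c(a_hat, b_hat, cp_hat)))
    abort("collinear mediation design", "collinear_design")

  if (!is.null(seed)) set.seed(as.integer(seed))
  if (method == "quasi-bayesian") {
    V1 <- suppressWarnings(stats::vcov(m1))  # zero-residual fits warn
    V2 <- suppressWarnings(stats::vcov(m2))
    th1 <- MASS::mvrnorm(n_sims, stats::coef(m1), V1)
    th2 <- MASS::mvrnorm(n_sims, stats::coef(m2), V2)
    ind <- th1[, ".x"] * th2[, ".m"]
    dir <- th2[, ".x"]
  } else {
    ind <- dir <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- df[idx, , drop = FALSE]
      f1 <- stats::lm(stats::as.formula(paste(".m ~", rhs)), data = d)
      f2 <- stats::lm(stats::as.formula(paste(".y ~", rhs, "+ .m")), data = d)
      ind[s] <- stats::coef(f1)[".x"] * stats::coef(f2)[".m"]
      dir[s] <- stats::coef(f2)[".x"]
    }
  }
  if (any(!is.finite(ind)) || any(!is.finite(dir)))
    abort(paste0("non-finite Monte-Carlo draws (seed ",
                 seed %||% "unset", ")"), "simulation_error")
  tot <- ind + dir
  keep <- abs(tot) >= 1e-8
  prop_draws <- ind[keep] / tot[keep]
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- function(v) if (length(v)) unname(stats::quantile(v, qs, type = 7))
        else c(NA_real_, NA_real_)
  p_acme <- 2 * min(mean(ind <= 0), mean(ind >= 0))

  a_path <- fit_linear(df$.m, df[, c(".x", names(covs)), drop = FALSE], ".x")
  b_path <- fit_linear(df$.y, df[, c(".x", names(covs), ".m"),
                                drop = FALSE], ".m")
  structure(list(
    acme = a_hat * b_hat, ade = cp_hat, total = a_hat * b_hat + cp_hat,
    prop_mediated = (a_hat * b_hat) / (a_hat * b_hat + cp_hat),
    ci_acme = ci(ind), ci_ade = ci(dir), ci_total = ci(tot),
    ci_prop = ci(prop_draws), p_acme = min(p_acme, 1),
    n_sims = as.integer(n_sims), n_excluded_ratio = sum(!keep),
    n = n, method = method, seed = seed,
    significant = {
      civ <- ci(ind); !is.na(civ[1]) && (civ[1] > 0 || civ[2] < 0)
    },
    a_path = a_path, b_path = b_path
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("ACME  %8.4f  [%.4f, %.4f]  p = %.3g\n",
              x$acme, x$ci_acme[1], x$ci_acme[2], x$p_acme))
  cat(sprintf("ADE   %8.4f  [%.4f, %.4f]\n", x$ade, x$ci_ade[1], x$ci_ade[2]))
  cat(sprintf("Total %8.4f  [%.4f, %.4f]\n", x$total, x$ci_total[1],
              x$ci_total[2]))
  cat(sprintf("Prop. mediated %.3f  [%.3f, %.3f]   (n = %d, %d sims)\n",
              x$prop_mediated, x$ci_prop[1], x$ci_prop[2], x$n, x$n_sims))
  invisible(x)
}

#' Cumulative mediator index
#'
#' Sums the methylation levels of the candidate units into one index per
#' participant. In the default sign-aligned mode each unit enters with the
#' sign of its exposure association (`+M_j` or `-M_j`), so units whose
#' methylation decreases with exposure do not cancel units whose methylation
#' increases with it; literal mode sums raw levels. Participants missing any
#' candidate get `NA` (downstream models are complete-case).
#'
#' @param matrix Participants x units methylation matrix.
#' @param candidates `data.frame` with `unit_id` and `sign` (as returned by
#'   [select_mediation_candidates()]), or a named sign vector.
#' @param mode `"sign-aligned"` (default) or `"literal"`.
#' @return Named numeric vector with attributes `mode` and `signs`.
#' @export
build_mediator_index <- function(matrix, candidates,
                                 mode = c("sign-aligned", "literal")) {
  mode <- match.arg(mode)
  if (is.data.frame(candidates)) {
    signs <- stats::setNames(candidates$sign, candidates$unit_id)
  } else {
    signs <- candidates
  }
  if (is.null(names(signs)) || !length(signs))
    abort("candidates must carry unit names", "lookup_error")
  missing_units <- setdiff(names(signs), colnames(matrix))
  if (length(missing_units))
    abort(paste0("candidate unit(s) absent from matrix: ",
                 paste(missing_units, collapse = ", ")), "lookup_error")
  sub <- matrix[, names(signs), drop = FALSE]
  if (any(colSums(!is.na(sub)) == 0L))
    abort("candidate unit fully missing", "insufficient_data")
  s <- if (mode == "sign-aligned") as.numeric(sign(signs)) else
    rep(1, length(signs))
  if (any(s == 0)) abort("candidate with zero sign", "lookup_error")
  idx <- drop(sub %*% s)
  names(idx) <- rownames(matrix)
  attr(idx, "mode") <- mode
  attr(idx, "signs") <- stats::setNames(s, names(signs))
  idx
}

#' Cumulative mediation through the summed index
#'
#' Builds the cumulative mediator index from the candidate units and runs
#' [fit_mediation()] with the index as the single mediator.
#'
#' @param x A `methylation_cohort` or `preprocessed_cohort`.
#' @param candidates As in [build_mediator_index()].
#' @param covariates Phenotype column names to adjust for.
#' @param n_sims,seed,method,mode Passed through; `mode` defaults to the
#'   cohort config's `index_mode`.
#' @return A `mediation_result` with the index in attribute `"index"`.
#' @export
mediate_cumulative <- function(x, candidates, covariates = character(0),
                               n_sims = NULL, seed = NULL,
                               method = "quasi-bayesian", mode = NULL) {
  co <- if (inherits(x, "preprocessed_cohort")) x$cohort else x
  stopifnot(inherits(co, "methylation_cohort"))
  n_sims <- n_sims %||% co$config$n_mediation_sims
  mode <- mode %||% co$config$index_mode
  idx <- build_mediator_index(co$methylation, candidates, mode = mode)
  ph <- co$phenotypes
  covs <- if (length(covariates)) ph[, covariates, drop = FALSE] else NULL
  res <- fit_mediation(ph$maltreatment, idx, ph$depression,
                       covariates = covs, n_sims = n_sims, seed = seed,
                       method = method)
  attr(res, "index") <- idx
  res
}
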