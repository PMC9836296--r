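#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults reproduce the study conditions of the candidate-gene analysis the
#' package implements: 3-SD winsorization of questionnaire totals, removal of
#' CpG units with more than 20% missing values or more than 80% zeros,
#' grouping of perfectly correlated units within a gene, region grouping at
#' r >= 0.50 within 500 bp, nominal screening at alpha = 0.05, confounder
#' retention at p < 0.10, FDR control at q = 0.20, and 1,000 Monte-Carlo
#' draws for mediation confidence intervals.
#'
#' @param winsor_k SD multiplier for winsorization bounds (mean +/- k*SD).
#' @param winsor_mode `"observed"` replaces out-of-bound scores with the most
#'   extreme observation still inside the bound; `"boundary"` replaces them
#'   with the bound itself.
#' @param missing_frac_max Units with a missing fraction strictly above this
#'   are removed.
#' @param zero_frac_min Units whose non-missing values are zero in a fraction
#'   strictly above this are removed.
#' @param duplicate_r Correlation defining a perfect duplicate (1.00).
#' @param duplicate_r_tol Numeric tolerance below `duplicate_r` still counted
#'   as perfect (floating-point r of exact copies can miss 1 by ulps).
#' @param region_r_min Minimum pairwise correlation for region grouping.
#' @param region_window_bp Maximum distance (bp) between nearest CpG
#'   coordinates of adjacent units joined into a region.
#' @param screen_alpha Two-sided nominal significance level for screens,
#'   mediation gating and moderation.
#' @param confounder_alpha Retention threshold for candidate confounders.
#' @param fdr_q False-discovery-rate threshold reported against
#'   Benjamini-Hochberg adjusted p-values.
#' @param n_mediation_sims Monte-Carlo draws for mediation intervals.
#' @param slope_sd_offset Moderator offset, in SDs, for simple slopes.
#' @param index_mode `"sign-aligned"` (default) or `"literal"` construction
#'   of the cumulative mediator index; see [build_mediator_index()].
#' @param use_adjusted Gate mediation and risk-score membership on
#'   covariate-adjusted significance flags (default) or unadjusted ones.
#' @param rng_seed Integer seed from which all pipeline randomness derives.
#'
#' @return An object of class `analysis_config` (a validated named list).
#' @examples
#' cfg <- analysis_config(rng_seed = 7L)
#' cfg$fdr_q
#' @export
analysis_config <- function(winsor_k = 3,
                            winsor_mode = c("observed", "boundary"),
                            missing_frac_max = 0.20,
                            zero_frac_min = 0.80,
                            duplicate_r = 1.00,
                            duplicate_r_tol = 1e-9,
                            region_r_min = 0.50,
                            region_window_bp = 500,
                            screen_alpha = 0.05,
                            confounder_alpha = 0.10,
                            fdr_q = 0.20,
                            n_mediation_sims = 1000L,
                            slope_sd_offset = 1.0,
                            index_mode = c("sign-aligned", "literal"),
                            use_adjusted = TRUE,
                            rng_seed = 1L) {
  winsor_mode <- match.arg(winsor_mode)
  index_mode <- match.arg(index_mode)
  cfg <- list(
    winsor_k = winsor_k, winsor_mode = winsor_mode,
    missing_frac_max = missing_frac_max, zero_frac_min = zero_frac_min,
    duplicate_r = duplicate_r, duplicate_r_tol = duplicate_r_tol,
    region_r_min = region_r_min, region_window_bp = region_window_bp,
    screen_alpha = screen_alpha, confounder_alpha = confounder_alpha,
    fdr_q = fdr_q, n_mediation_sims = as.integer(n_mediation_sims),
    slope_sd_offset = slope_sd_offset, index_mode = index_mode,
    use_adjusted = isTRUE(use_adjusted), rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  frac <- c("missing_frac_max", "zero_frac_min", "screen_alpha",
            "confounder_alpha", "fdr_q")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      abort(sprintf("config field '%s' must be a fraction in (0, 1)", f),
            "config_error")
  }
  pos <- c("winsor_k", "region_r_min", "region_window_bp", "slope_sd_offset",
           "duplicate_r")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      abort(sprintf("config field '%s' must be a positive number", f),
            "config_error")
  }
  if (cfg$n_mediation_sims < 1L)
    abort("n_mediation_sims must be >= 1", "config_error")
  if (cfg$duplicate_r_tol < 0 || cfg$duplicate_r_tol >= 1)
    abort("duplicate_r_tol must be in [0, 1)", "config_error")
  if (is.na(cfg$rng_seed))
    abort("rng_seed must be an integer", "config_error")
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Rebuild a config from a plain list (e.g. parsed JSON/YAML); unknown keys
# are a usage error so typos in config files fail loudly.
#' @rdname analysis_config
#' @param fields Named list of `analysis_config` fields to override.
#' @export
as_analysis_config <- function(fields = list()) {
  known <- names(formals(analysis_config))
  bad <- setdiff(names(fields), known)
  if (length(bad))
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          "config_error")
  do.call(analysis_config, fields)
}
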