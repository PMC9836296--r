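#' Run the full analysis pipeline
#'
#' End-to-end orchestration in the analysis order of the study design:
#' winsorization and CpG-unit QC, duplicate collapse, region grouping,
#' data-driven confounder selection, unadjusted and covariate-adjusted
#' screens of methylation on the exposure and on the outcome with
#' Benjamini-Hochberg correction, screening-gated per-unit and cumulative
#' mediation, per-unit moderation, the tertile risk score, and cumulative
#' moderation. All randomness derives from `config$rng_seed` through
#' deterministic per-stage child seeds, so two runs with the same inputs and
#' seed produce byte-identical reports.
#'
#' @param x A `methylation_cohort`, or `NULL` to simulate one from `truth`.
#' @param truth Optional [simulation_truth()] used when `x` is `NULL`.
#' @param config An [analysis_config()]; when `x` is given its embedded
#'   config is replaced by this one.
#' @param out_dir Optional directory; when given, reports and a JSON run
#'   summary are written via [write_report()].
#' @param covariate_candidates Candidate confounders offered to
#'   [select_confounders()].
#' @return Invisibly, a list of class `pipeline_run` with every stage's
#'   tables and the run summary.
#' @export
run_pipeline <- function(x = NULL, truth = NULL,
                         config = analysis_config(), out_dir = NULL,
                         covariate_candidates = c("age", "drug_use",
                                                  "smoking", "alcohol",
                                                  "bmi")) {
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(x)) {
      if (is.null(truth)) truth <- simulation_truth()
      x <- generate_cohort(truth, seed = child_seed(config$rng_seed, "simulate"))
    }
    x$config <- config

    stage <- "preprocess"
    pre <- preprocess_cohort(x)

    stage <- "confounders"
    confounders <- select_confounders(pre, candidates = covariate_candidates)

    stage <- "screen"
    scr_x <- screen_units(pre, "exposure", covariates = confounders)
    scr_y <- screen_units(pre, "outcome", covariates = confounders)

    stage <- "mediation"
    cand <- select_mediation_candidates(scr_x, scr_y,
                                        use_adjusted = config$use_adjusted)
    med_seed <- child_seed(config$rng_seed, "mediation")
    med_rows <- list()
    if (nrow(cand)) {
      for (i in seq_len(nrow(cand))) {
        u <- cand$unit_id[i]
        m <- fit_mediation(pre$cohort$phenotypes$maltreatment,
                           pre$cohort$methylation[, u],
                           pre$cohort$phenotypes$depression,
                           covariates = if (length(confounders))
                             pre$cohort$phenotypes[, confounders, drop = FALSE]
                           else NULL,
                           n_sims = config$n_mediation_sims,
                           seed = child_seed(med_seed, u))
        med_rows[[i]] <- mediation_row(u, m)
      }
    }
    med_units <- if (length(med_rows)) do.call(rbind, med_rows) else
      mediation_row(character(0), NULL)
    med_cum <- NULL
    if (nrow(cand)) {
      med_cum <- mediate_cumulative(pre, cand, covariates = confounders,
                                    seed = child_seed(med_seed, ".cumulative"))
    }

    stage <- "moderation"
    mod_tab <- moderation_table(pre, confounders)
    mod_tab$fdr_p <- fdr_adjust(mod_tab$p_unadj)
    flag <- if (config$use_adjusted) mod_tab$p_adj else mod_tab$p_unadj
    bcol <- if (config$use_adjusted) mod_tab$b_adj else mod_tab$b_unadj
    moderators <- mod_tab$unit_id[!is.na(flag) & flag < config$screen_alpha]
    risk <- NULL; mod_cum <- NULL
    if (length(moderators) >= 1L) {
      signs <- stats::setNames(
        as.integer(sign(bcol[match(moderators, mod_tab$unit_id)])), moderators)
      risk <- build_risk_score(pre$cohort$methylation, signs)
      if (length(unique(risk$score)) >= 3L)
        mod_cum <- moderate_cumulative(pre, risk, covariates = confounders)
    }

    stage <- "report"
    summary <- list(
      config = unclass(config),
      seed = config$rng_seed,
      n_participants = nrow(pre$cohort$methylation),
      accounting = pre$accounting,
      winsorization = pre$reports$winsorization,
      confounders = as.character(confounders),
      mediation_candidates = cand$unit_id,
      index_mode = config$index_mode,
      n_moderating_units = length(moderators),
      cumulative_mediation = if (!is.null(med_cum)) list(
        acme = med_cum$acme, ci_acme = med_cum$ci_acme,
        prop_mediated = med_cum$prop_mediated, ci_prop = med_cum$ci_prop,
        p_acme = med_cum$p_acme, n_excluded_ratio = med_cum$n_excluded_ratio),
      cumulative_moderation = if (!is.null(mod_cum)) list(
        b_interaction = mod_cum$b_interaction, se = mod_cum$se, p = mod_cum$p,
        r2 = mod_cum$r2, group_slopes = mod_cum$group_slopes),
      generation = attr(x, "generation")
    )
    run <- list(cohort = x, preprocessed = pre, confounders = confounders,
                screen_exposure = scr_x, screen_outcome = scr_y,
                mediation_candidates = cand, mediation_units = med_units,
                mediation_cumulative = med_cum, moderation = mod_tab,
                moderating_units = moderators, risk_score = risk,
                moderation_cumulative = mod_cum, summary = summary)
    class(run) <- "pipeline_run"
    if (!is.null(out_dir)) {
      tables <- list(
        screen_exposure = as.data.frame(scr_x),
        screen_outcome = as.data.frame(scr_y),
        qc_removals = pre$reports$qc,
        duplicate_merges = pre$reports$duplicates,
        region_map = pre$region_map,
        mediation_units = med_units,
        moderation = mod_tab
      )
      if (!is.null(med_cum))
        tables$mediation_cumulative <- mediation_row("cumulative_index", med_cum)
      if (!is.null(risk))
        tables$risk_score <- data.frame(
          participant_id = names(risk$score), score = risk$score,
          n_missing_units = unname(risk$n_missing),
          stringsAsFactors = FALSE)
      if (!is.null(mod_cum))
        tables$moderation_cumulative <- mod_cum$group_slopes
      write_report(tables, out_dir, summary = summary)
    }
    run
  }, cpgmediate_error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)), "pipeline_error")
  })
  invisible(res)
}

# Flatten a mediation_result into one report row (or an empty table).
#' @noRd
mediation_row <- function(unit_id, m) {
  if (is.null(m)) {
    return(data.frame(unit_id = character(0), acme = numeric(0),
                      acme_lo = numeric(0), acme_hi = numeric(0),
                      p_acme = numeric(0), ade = numeric(0),
                      total = numeric(0), prop_mediated = numeric(0),
                      prop_lo = numeric(0), prop_hi = numeric(0),
                      a_path_b = numeric(0), b_path_b = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(unit_id = unit_id, acme = m$acme, acme_lo = m$ci_acme[1],
             acme_hi = m$ci_acme[2], p_acme = m$p_acme, ade = m$ade,
             total = m$total, prop_mediated = m$prop_mediated,
             prop_lo = m$ci_prop[1], prop_hi = m$ci_prop[2],
             a_path_b = m$a_path$B, b_path_b = m$b_path$B, n = m$n,
             stringsAsFactors = FALSE)
}

# Per-unit moderation table (unadjusted and adjusted interaction models).
#' @noRd
moderation_table <- function(pre, confounders) {
  co <- pre$cohort
  ph <- co$phenotypes
  covs <- if (length(confounders)) ph[, confounders, drop = FALSE] else NULL
  rows <- lapply(colnames(co$methylation), function(u) {
    out <- data.frame(unit_id = u, b_unadj = NA_real_, se_unadj = NA_real_,
                      p_unadj = NA_real_, r2_unadj = NA_real_,
                      b_adj = NA_real_, se_adj = NA_real_, p_adj = NA_real_,
                      r2_adj = NA_real_, n = NA_integer_,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      un <- fit_moderation(ph$maltreatment, co$methylation[, u],
                           ph$depression, covariates = NULL,
                           alpha = co$config$screen_alpha,
                           sd_offset = co$config$slope_sd_offset)
      out$b_unadj <- un$b_interaction; out$se_unadj <- un$se
      out$p_unadj <- un$p; out$r2_unadj <- un$r2; out$n <- un$n
      if (!is.null(covs)) {
        ad <- fit_moderation(ph$maltreatment, co$methylation[, u],
                             ph$depression, covariates = covs,
                             alpha = co$config$screen_alpha,
                             sd_offset = co$config$slope_sd_offset)
        out$b_adj <- ad$b_interaction; out$se_adj <- ad$se
        out$p_adj <- ad$p; out$r2_adj <- ad$r2
      } else {
        out$b_adj <- out$b_unadj; out$se_adj <- out$se_unadj
        out$p_adj <- out$p_unadj; out$r2_adj <- out$r2_unadj
      }
      out
    }, cpgmediate_error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  do.call(rbind, rows)
}

#' @export
print.pipeline_run <- function(x, ...) {
  a <- x$summary$accounting
  cat("Candidate-gene methylation pipeline run\n")
  cat(sprintf("  units: %d in -> %d retained (%d missingness, %d zero-inflated, %d merged)\n",
              a$units_in, a$units_retained, a$removed_missingness,
              a$removed_zero_inflated, a$merged_away))
  cat(sprintf("  confounders retained: %s\n",
              if (length(x$confounders)) paste(x$confounders, collapse = ", ")
              else "(none)"))
  cat(sprintf("  exposure screen: %d/%d units significant (unadjusted)\n",
              sum(x$screen_exposure$sig_unadj[x$screen_exposure$level == "unit"]),
              sum(x$screen_exposure$level == "unit")))
  cat(sprintf("  outcome screen: %d/%d units significant (unadjusted)\n",
              sum(x$screen_outcome$sig_unadj[x$screen_outcome$level == "unit"]),
              sum(x$screen_outcome$level == "unit")))
  cat(sprintf("  mediation candidates: %d; moderating units: %d\n",
              nrow(x$mediation_candidates), length(x$moderating_units)))
  if (!is.null(x$mediation_cumulative))
    cat(sprintf("  cumulative ACME = %.4f [%.4f, %.4f]\n",
                x$mediation_cumulative$acme,
                x$mediation_cumulative$ci_acme[1],
                x$mediation_cumulative$ci_acme[2]))
  if (!is.null(x$moderation_cumulative))
    cat(sprintf("  cumulative interaction B = %.4f (p = %.3g)\n",
                x$moderation_cumulative$b_interaction,
                x$moderation_cumulative$p))
  invisible(x)
}
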