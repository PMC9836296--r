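#' Default candidate-gene CpG-unit panel
#'
#' A deterministic 191-unit annotation spread over the nine stress-related
#' candidate genes (COMT, FKBP5, IL6, IL10, MAOA, NR3C1, OXTR, SLC6A3,
#' SLC6A4), with EpiTYPER-style unit naming (`GENE_amplicon_CpG_k`,
#' `..._CpG_kand(k+1)`, `..._CpG_kto(k+n)`) and GRCh37 promoter-region
#' coordinates tiled at realistic spacing. Units cover 1-3 CpG positions.
#'
#' @param genes Optional character vector restricting the panel to a subset
#'   of the nine genes.
#' @return An annotation `data.frame` (see [cpg_annotation()]).
#' @export
default_panel <- function(genes = NULL) {
  layout <- list(
    COMT   = list(chrom = "chr22", start = 19950030L, n = 15L),
    FKBP5  = list(chrom = "chr6",  start = 35558440L, n = 15L),
    IL6    = list(chrom = "chr7",  start = 22763990L, n = 10L),
    IL10   = list(chrom = "chr1",  start = 206939900L, n = 12L),
    MAOA   = list(chrom = "chrX",  start = 43515330L, n = 30L),
    NR3C1  = list(chrom = "chr5",  start = 142782700L, n = 34L),
    OXTR   = list(chrom = "chr3",  start = 8810560L,  n = 17L),
    SLC6A3 = list(chrom = "chr5",  start = 1446000L,  n = 27L),
    SLC6A4 = list(chrom = "chr17", start = 28562380L, n = 31L)
  )
  if (!is.null(genes)) layout <- layout[intersect(names(layout), genes)]
  ncpg_cycle <- c(1L, 2L, 1L, 3L, 1L, 2L)
  ids <- character(0); gene <- character(0); chrom <- character(0)
  positions <- list()
  for (g in names(layout)) {
    s <- layout[[g]]
    amp_split <- ceiling(s$n / 2)
    pos <- s$start
    cpg_counter <- c(1L, 1L)  # per-amplicon CpG numbering
    for (i in seq_len(s$n)) {
      amp <- if (i <= amp_split) 1L else 2L
      ncpg <- ncpg_cycle[(i - 1L) %% length(ncpg_cycle) + 1L]
      k <- cpg_counter[amp]
      id <- if (ncpg == 1L) {
        sprintf("%s_%d_CpG_%d", g, amp, k)
      } else if (ncpg == 2L) {
        sprintf("%s_%d_CpG_%dand%d", g, amp, k, k + 1L)
      } else {
        sprintf("%s_%d_CpG_%dto%d", g, amp, k, k + ncpg - 1L)
      }
      cpg_counter[amp] <- k + ncpg
      p <- pos + cumsum(c(0L, rep(7L, ncpg - 1L)))
      pos <- pos + 7L * ncpg + 23L  # ~30 bp to the next unit
      if (i == amp_split) pos <- pos + 600L  # amplicon gap
      ids <- c(ids, id); gene <- c(gene, g); chrom <- c(chrom, s$chrom)
      positions <- c(positions, list(as.integer(p)))
    }
  }
  cpg_annotation(ids, gene, chrom, positions)
}

# Map a per-unit parameter onto the unit list: scalars recycle, named
# vectors land on their units (0 elsewhere).
#' @noRd
expand_unit_param <- function(x, unit_ids, what) {
  n <- length(unit_ids)
  if (is.null(x)) return(numeric(n))
  if (!is.null(names(x))) {
    bad <- setdiff(names(x), unit_ids)
    if (length(bad))
      abort(paste0(what, " names not in panel: ", paste(bad, collapse = ", ")),
            "truth_error")
    out <- numeric(n); names(out) <- unit_ids
    out[names(x)] <- x
    return(unname(out))
  }
  rep_len(as.numeric(x), n)
}

#' @noRd
default_cov_effects <- function(annotation) {
  n <- nrow(annotation)
  idx <- seq_len(n)
  age_m <- ifelse(idx %% 4L == 0L, 0.08, 0)    # %-methylation per year
  drug_m <- ifelse(idx %% 5L == 0L, 1.2, 0)    # %-methylation shift for users
  list(
    methylation = list(age = age_m, drug_use = drug_m),
    outcome = list(age = 0.15, drug_use = 2.5)  # BDI points
  )
}

#' Ground truth for cohort simulation
#'
#' Defines the generative structure recovered by downstream tests: per-unit
#' exposure-to-methylation slopes (`a`, percent per CTQ point),
#' methylation-to-outcome slopes (`b`, BDI points per percent), a direct
#' exposure effect (`c_prime`), exposure-by-methylation interaction slopes
#' (`omega`), covariate effects, noise scales, missingness, and optional
#' planted duplicate and correlated-region blocks. Defaults emulate the
#' study conditions: n = 156 men, CTQ totals with mean 37.43 and SD 11.04
#' (right-skewed, floor 25), BDI-II totals with mean about 10.48 and SD
#' about 8.79, a total maltreatment-depression effect of 0.25 BDI points per
#' CTQ point, and a null 191-unit methylation panel (effects are planted per
#' analysis).
#'
#' @param n_participants Cohort size.
#' @param annotation Unit panel (see [default_panel()]).
#' @param a,b,omega Per-unit structural slopes; scalar, unnamed vector, or
#'   named vector keyed by unit ID (unnamed units get 0).
#' @param c_prime Direct exposure-to-outcome slope.
#' @param unit_mean,unit_sd Per-unit methylation baseline (percent) and
#'   residual SD; defaults spread baselines over 10-70% with SD 3.
#' @param outcome_sd Residual SD of the depression score.
#' @param outcome_intercept Expected depression score at average exposure,
#'   methylation and covariates.
#' @param outcome_skew Use a right-skewed (centred gamma) outcome residual
#'   mimicking the floor effect of depression inventories; `FALSE` for
#'   Gaussian residuals.
#' @param round_outcome Round the outcome to integers (realism toggle;
#'   default keeps it continuous since the estimators target OLS).
#' @param exposure_mean,exposure_sd,exposure_floor,exposure_ceiling CTQ
#'   total distribution: shifted gamma matched to mean/SD, truncated.
#' @param cov_effects List with elements `methylation` (named list of
#'   per-unit slopes per covariate) and `outcome` (named list of scalar
#'   slopes per covariate).
#' @param missing_frac Per-unit MCAR missingness fraction (scalar or
#'   per-unit vector), in `[0, 1)`.
#' @param duplicate_map Named character vector `c(copy_id = source_id)`;
#'   the copy unit is generated as an exact duplicate of the source.
#' @param region_map List of character vectors; each block shares a latent
#'   factor giving pairwise correlation about `region_rho`.
#' @param region_rho Target within-block correlation.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_participants = 156L,
                             annotation = default_panel(),
                             a = 0, b = 0, c_prime = 0.25, omega = 0,
                             unit_mean = NULL, unit_sd = 3,
                             outcome_sd = 8.3, outcome_intercept = 10.48,
                             outcome_skew = TRUE, round_outcome = FALSE,
                             exposure_mean = 37.43, exposure_sd = 11.04,
                             exposure_floor = 25, exposure_ceiling = 125,
                             cov_effects = default_cov_effects(annotation),
                             missing_frac = 0.02,
                             duplicate_map = NULL,
                             region_map = NULL, region_rho = 0.7) {
  ids <- annotation$unit_id
  nu <- length(ids)
  if (is.null(unit_mean)) unit_mean <- rep_len(seq(10, 70, length.out = 24), nu)
  truth <- list(
    n_participants = as.integer(n_participants),
    annotation = annotation,
    a = expand_unit_param(a, ids, "a"),
    b = expand_unit_param(b, ids, "b"),
    omega = expand_unit_param(omega, ids, "omega"),
    c_prime = c_prime,
    unit_mean = rep_len(as.numeric(unit_mean), nu),
    unit_sd = rep_len(as.numeric(unit_sd), nu),
    outcome_sd = outcome_sd, outcome_intercept = outcome_intercept,
    outcome_skew = isTRUE(outcome_skew), round_outcome = isTRUE(round_outcome),
    exposure_mean = exposure_mean, exposure_sd = exposure_sd,
    exposure_floor = exposure_floor, exposure_ceiling = exposure_ceiling,
    cov_effects = cov_effects,
    missing_frac = rep_len(as.numeric(missing_frac), nu),
    duplicate_map = duplicate_map,
    region_map = region_map, region_rho = region_rho
  )
  if (any(truth$unit_sd < 0) || truth$outcome_sd < 0 || truth$exposure_sd <= 0)
    abort("noise SDs must be non-negative (exposure SD positive)", "truth_error")
  if (any(truth$missing_frac < 0 | truth$missing_frac >= 1))
    abort("missing_frac must lie in [0, 1)", "truth_error")
  if (!is.null(duplicate_map)) {
    if (is.null(names(duplicate_map)) ||
        !all(names(duplicate_map) %in% ids) ||
        !all(duplicate_map %in% ids))
      abort("duplicate_map must map existing unit ids to existing unit ids",
            "truth_error")
  }
  if (!is.null(region_map) && !all(unlist(region_map) %in% ids))
    abort("region_map references unknown units", "truth_error")
  structure(truth, class = "simulation_truth")
}

#' Generate a synthetic cohort with known structure
#'
#' Draws a cohort from a [simulation_truth()]: exposure from a shifted gamma
#' truncated to the CTQ range; methylation of unit j as
#' `mean_j + a_j (X - mean(X)) + covariate terms + latent region factor +
#' Gaussian noise`, clipped to the percent scale; outcome as
#' `intercept + c' (X - mean(X)) + sum_j b_j (M_j - mean(M_j)) +
#' sum_j omega_j (X - mean(X))(M_j - mean(M_j)) + covariate terms +
#' residual`, clipped to the BDI range. Interaction terms use centred
#' scales, so `c_prime` keeps its main-effect meaning. Duplicate and region
#' blocks are injected per the truth's maps, then MCAR missingness is
#' applied per unit. The same truth and seed always give a bit-identical
#' cohort; clipping fractions are recorded in `attr(x, "generation")`, and
#' a `degenerate_truth` warning is raised when any variable is clipped on
#' more than half the sample.
#'
#' @param truth A [simulation_truth()].
#' @param seed Integer seed.
#' @return A `methylation_cohort` with attributes `truth` and `generation`.
#' @export
generate_cohort <- function(truth, seed) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(as.integer(seed))
  n <- truth$n_participants
  ids <- truth$annotation$unit_id
  nu <- length(ids)

  # exposure: shifted gamma matched to the target mean/SD, truncated
  mu0 <- truth$exposure_mean - truth$exposure_floor
  shape <- (mu0 / truth$exposure_sd)^2
  scale <- truth$exposure_sd^2 / mu0
  x <- truth$exposure_floor + stats::rgamma(n, shape = shape, scale = scale)
  for (it in 1:20) {
    over <- x > truth$exposure_ceiling
    if (!any(over)) break
    x[over] <- truth$exposure_floor +
      stats::rgamma(sum(over), shape = shape, scale = scale)
  }
  x[x > truth$exposure_ceiling] <- truth$exposure_ceiling

  age <- round(stats::runif(n, 18, 35), 1)
  drug_use <- stats::rbinom(n, 1L, 0.30)
  smoking <- stats::rbinom(n, 1L, 0.30)
  alcohol <- pmin(stats::rpois(n, 2), 7L)
  bmi <- round(pmin(pmax(stats::rnorm(n, 24.5, 3.5), 16), 45), 1)
  covs <- data.frame(age = age, drug_use = drug_use, smoking = smoking,
                     alcohol = alcohol, bmi = bmi)

  xc <- x - mean(x)
  meth_eff <- matrix(0, n, nu)
  for (cv in names(truth$cov_effects$methylation %||% list())) {
    slopes <- rep_len(as.numeric(truth$cov_effects$methylation[[cv]]), nu)
    cc <- covs[[cv]] - mean(covs[[cv]])
    meth_eff <- meth_eff + outer(cc, slopes)
  }

  latent <- matrix(0, n, nu)
  for (block in truth$region_map %||% list()) {
    L <- stats::rnorm(n)
    j <- match(block, ids)
    lambda <- truth$unit_sd[j] * sqrt(truth$region_rho / (1 - truth$region_rho))
    latent[, j] <- latent[, j] + outer(L, lambda)
  }

  noise <- matrix(stats::rnorm(n * nu), n, nu) *
    matrix(truth$unit_sd, n, nu, byrow = TRUE)
  M <- matrix(truth$unit_mean, n, nu, byrow = TRUE) +
    outer(xc, truth$a) + meth_eff + latent + noise
  clip_lo <- M < 0; clip_hi <- M > 100
  M[clip_lo] <- 0; M[clip_hi] <- 100
  meth_clip_frac <- colMeans(clip_lo | clip_hi)

  if (!is.null(truth$duplicate_map)) {
    for (copy in names(truth$duplicate_map))
      M[, match(copy, ids)] <- M[, match(truth$duplicate_map[[copy]], ids)]
  }

  Mc <- sweep(M, 2L, colMeans(M))
  out_eff <- numeric(n)
  for (cv in names(truth$cov_effects$outcome %||% list())) {
    cc <- covs[[cv]] - mean(covs[[cv]])
    out_eff <- out_eff + truth$cov_effects$outcome[[cv]] * cc
  }
  if (truth$outcome_skew) {
    th <- truth$outcome_sd / sqrt(2)
    resid <- stats::rgamma(n, shape = 2, scale = th) - 2 * th
  } else {
    resid <- stats::rnorm(n, 0, truth$outcome_sd)
  }
  y <- truth$outcome_intercept + truth$c_prime * xc +
    drop(Mc %*% truth$b) + drop((xc * Mc) %*% truth$omega) + out_eff + resid
  y_lo <- y < 0; y_hi <- y > 63
  y[y_lo] <- 0; y[y_hi] <- 63
  outcome_clip_frac <- mean(y_lo | y_hi)
  if (truth$round_outcome) y <- round(y)

  for (j in seq_len(nu)) {
    if (truth$missing_frac[j] > 0)
      M[stats::runif(n) < truth$missing_frac[j], j] <- NA_real_
  }

  degenerate <- any(meth_clip_frac > 0.5) || outcome_clip_frac > 0.5
  if (degenerate)
    warn("degenerate truth: more than 50% of values clipped at a bound",
         "degenerate_truth")

  colnames(M) <- ids
  pid <- sprintf("P%04d", seq_len(n))
  rownames(M) <- pid
  ph <- data.frame(participant_id = pid, maltreatment = x, depression = y,
                   covs, stringsAsFactors = FALSE)
  co <- cohort(ph, M, truth$annotation)
  attr(co, "truth") <- truth
  attr(co, "generation") <- list(
    seed = as.integer(seed),
    methylation_clip_frac = stats::setNames(meth_clip_frac, ids),
    outcome_clip_frac = outcome_clip_frac,
    degenerate = degenerate
  )
  co
}
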