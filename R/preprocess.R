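#' Winsorize questionnaire totals
#'
#' Caps scores farther than `k` sample SDs from the sample mean. Moments are
#' computed once on the input values; in the default `"observed"` mode an
#' out-of-bound score is replaced by the most extreme input value still
#' inside the bound (largest value at or below `mean + k*SD` above, smallest
#' value at or above `mean - k*SD` below); `"boundary"` mode replaces it with
#' the bound itself. Missing values are passed through untouched and excluded
#' from the moments. Order is preserved.
#'
#' @param values Numeric vector (>= 3 non-missing values).
#' @param k SD multiplier (default 3).
#' @param mode `"observed"` (default) or `"boundary"`.
#' @return List with `values` (adjusted vector), `n_modified`, and the
#'   `lower`/`upper` bounds used.
#' @export
winsorize_scores <- function(values, k = 3, mode = c("observed", "boundary")) {
  mode <- match.arg(mode)
  if (k <= 0) abort("k must be positive", "config_error")
  obs <- values[!is.na(values)]
  if (length(obs) < 3L)
    abort("winsorization needs at least 3 non-missing values",
          "insufficient_data")
  m <- mean(obs); s <- stats::sd(obs)
  if (s == 0) {
    warn("all values identical (SD = 0); winsorization is a no-op")
    return(list(values = values, n_modified = 0L, lower = m, upper = m))
  }
  lo <- m - k * s; hi <- m + k * s
  out <- values
  above <- !is.na(values) & values > hi
  below <- !is.na(values) & values < lo
  if (mode == "observed") {
    out[above] <- max(obs[obs <= hi])
    out[below] <- min(obs[obs >= lo])
  } else {
    out[above] <- hi
    out[below] <- lo
  }
  list(values = out, n_modified = sum(above) + sum(below),
       lower = lo, upper = hi)
}

#' Quality-control filter for CpG units
#'
#' Applies the two unit-level filters in fixed order: first remove units with
#' a missing-value fraction strictly above `missing_frac_max`, then, among
#' the survivors, remove units whose non-missing values are exactly zero in a
#' fraction strictly above `zero_frac_min`.
#'
#' @param matrix Participants x units methylation matrix.
#' @param missing_frac_max Missingness threshold (default 0.20).
#' @param zero_frac_min Zero-inflation threshold (default 0.80).
#' @return List with `matrix` (surviving columns) and `report` (a
#'   `data.frame` of `unit_id`, `reason` in `{"missingness",
#'   "zero-inflated"}`, and the offending `statistic`).
#' @export
qc_filter_units <- function(matrix, missing_frac_max = 0.20,
                            zero_frac_min = 0.80) {
  miss <- colMeans(is.na(matrix))
  drop1 <- miss > missing_frac_max
  rep1 <- data.frame(unit_id = colnames(matrix)[drop1],
                     reason = rep("missingness", sum(drop1)),
                     statistic = unname(miss[drop1]),
                     stringsAsFactors = FALSE)
  kept <- matrix[, !drop1, drop = FALSE]
  zf <- apply(kept, 2L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) 1 else mean(v == 0)
  })
  drop2 <- zf > zero_frac_min
  rep2 <- data.frame(unit_id = colnames(kept)[drop2],
                     reason = rep("zero-inflated", sum(drop2)),
                     statistic = unname(zf[drop2]),
                     stringsAsFactors = FALSE)
  kept <- kept[, !drop2, drop = FALSE]
  if (ncol(kept) == 0L)
    abort("all units removed by QC filters", "all_units_removed")
  list(matrix = kept, report = rbind(rep1, rep2))
}

# Pairwise Pearson correlation on pairwise-complete observations; NA (with
# an optional warning) when fewer than 3 complete pairs or a zero variance.
#' @noRd
pairwise_r <- function(u, v, warn_insufficient = TRUE, label = NULL) {
  ok <- !is.na(u) & !is.na(v)
  if (sum(ok) < 3L) {
    if (warn_insufficient)
      warn(paste0("correlation undefined (<3 complete pairs)",
                  if (!is.null(label)) paste0(" for ", label)),
           "undefined_correlation")
    return(NA_real_)
  }
  if (stats::sd(u[ok]) == 0 || stats::sd(v[ok]) == 0) return(NA_real_)
  stats::cor(u[ok], v[ok])
}

#' Collapse perfectly correlated units within a gene
#'
#' Units of the same gene whose pairwise Pearson correlation (on
#' pairwise-complete observations) is at least `1 - tol` are grouped
#' transitively (connected components) into a single unit whose value is the
#' per-participant available-case mean of the members and whose coordinate
#' set is the union. Cross-gene pairs are never merged. The merged unit keeps
#' the ID of its left-most (by first coordinate) member.
#'
#' @param matrix Participants x units matrix (post-QC).
#' @param annotation Annotation for the matrix columns.
#' @param tol Tolerance below r = 1 still counted as perfect (default 1e-9).
#' @return List with `matrix`, updated `annotation`, and `report`
#'   (`data.frame` of `unit_id`, `members`, `min_r`).
#' @export
collapse_perfect_duplicates <- function(matrix, annotation, tol = 1e-9) {
  ids <- colnames(matrix)
  ann <- annotation[match(ids, annotation$unit_id), , drop = FALSE]
  keep_cols <- list(); keep_ann <- list(); report <- list()
  for (g in unique(ann$gene)) {
    j <- which(ann$gene == g)
    edges <- list()
    rmat <- matrix(NA_real_, length(j), length(j))
    if (length(j) > 1L) {
      for (p in 1:(length(j) - 1L)) for (q in (p + 1L):length(j)) {
        r <- pairwise_r(matrix[, j[p]], matrix[, j[q]],
                        label = paste(ids[j[p]], ids[j[q]]))
        rmat[p, q] <- rmat[q, p] <- r
        if (!is.na(r) && r >= 1 - tol) edges <- c(edges, list(c(p, q)))
      }
    }
    # transitive closure via union-find
    parent <- seq_along(j)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in edges) {
      ri <- find(e[1]); rj <- find(e[2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
    comp <- vapply(seq_along(j), find, 1L)
    for (cid in unique(comp)) {
      mem <- j[comp == cid]
      first_pos <- vapply(parse_positions(ann$positions[mem]), min, 1L)
      mem <- mem[order(first_pos)]
      if (length(mem) == 1L) {
        keep_cols[[length(keep_cols) + 1L]] <- matrix[, mem, drop = FALSE]
        keep_ann[[length(keep_ann) + 1L]] <- ann[mem, , drop = FALSE]
      } else {
        vals <- rowMeans(matrix[, mem, drop = FALSE], na.rm = TRUE)
        vals[is.nan(vals)] <- NA_real_
        newid <- ids[mem[1L]]
        col <- matrix(vals, ncol = 1L, dimnames = list(rownames(matrix), newid))
        keep_cols[[length(keep_cols) + 1L]] <- col
        pos <- sort(unique(unlist(parse_positions(ann$positions[mem]))))
        a <- ann[mem[1L], , drop = FALSE]
        a$positions <- paste(pos, collapse = ";")
        a$n_cpgs <- length(pos)
        keep_ann[[length(keep_ann) + 1L]] <- a
        sub <- match(mem, j)
        report[[length(report) + 1L]] <- data.frame(
          unit_id = newid,
          members = paste(ids[mem], collapse = ";"),
          min_r = min(rmat[sub, sub], na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(cbind, keep_cols)
  out_ann <- do.call(rbind, keep_ann)
  # restore original column order (by input position of the surviving id)
  ord <- order(match(colnames(out), ids))
  out <- out[, ord, drop = FALSE]
  out_ann <- out_ann[ord, , drop = FALSE]
  rownames(out_ann) <- NULL
  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(unit_id = character(0), members = character(0),
               min_r = numeric(0), stringsAsFactors = FALSE)
  list(matrix = out, annotation = out_ann, report = rep_df)
}

#' Group correlated nearby units into regions
#'
#' Within each gene, units are sorted by first coordinate and adjacent units
#' are chained into a region when the gap between their nearest coordinates
#' is at most `window_bp` and their pairwise correlation is at least
#' `r_min`; regions are maximal chains under this rule. A region's value is
#' the per-participant available-case mean of its members; singleton units
#' pass through unchanged. The returned region matrix carries every unit
#' exactly once (as a member or a singleton).
#'
#' @param matrix Participants x units matrix (post-collapse).
#' @param annotation Annotation for the matrix columns.
#' @param r_min Minimum pairwise correlation (default 0.50).
#' @param window_bp Maximum nearest-coordinate gap in bp (default 500).
#' @return List with `matrix` (region-level), and `map` (`data.frame` of
#'   `region_id`, `gene`, `members`, `n_members`).
#' @export
group_regions <- function(matrix, annotation, r_min = 0.50, window_bp = 500) {
  ids <- colnames(matrix)
  ann <- annotation[match(ids, annotation$unit_id), , drop = FALSE]
  cols <- list(); map <- list()
  for (g in unique(ann$gene)) {
    j <- which(ann$gene == g)
    pos <- parse_positions(ann$positions[j])
    ord <- order(vapply(pos, min, 1L))
    j <- j[ord]; pos <- pos[ord]
    k <- length(j)
    join <- logical(max(k - 1L, 0L))
    if (k > 1L) for (i in seq_len(k - 1L)) {
      gap <- min(pos[[i + 1L]]) - max(pos[[i]])
      if (gap <= window_bp) {
        r <- pairwise_r(matrix[, j[i]], matrix[, j[i + 1L]],
                        label = paste(ids[j[i]], ids[j[i + 1L]]))
        join[i] <- !is.na(r) && r >= r_min
      }
    }
    grp <- cumsum(c(1L, !join))
    for (gi in unique(grp)) {
      mem <- j[grp == gi]
      if (length(mem) == 1L) {
        cols[[length(cols) + 1L]] <-
          matrix[, mem, drop = FALSE]
        map[[length(map) + 1L]] <- data.frame(
          region_id = ids[mem], gene = g, members = ids[mem],
          n_members = 1L, stringsAsFactors = FALSE)
      } else {
        rid <- sprintf("%s_region_%d", g, sum(vapply(map, function(m)
          m$gene == g & m$n_members > 1L, TRUE)) + 1L)
        vals <- rowMeans(matrix[, mem, drop = FALSE], na.rm = TRUE)
        vals[is.nan(vals)] <- NA_real_
        cols[[length(cols) + 1L]] <-
          matrix(vals, ncol = 1L, dimnames = list(rownames(matrix), rid))
        map[[length(map) + 1L]] <- data.frame(
          region_id = rid, gene = g,
          members = paste(ids[mem], collapse = ";"),
          n_members = length(mem), stringsAsFactors = FALSE)
      }
    }
  }
  list(matrix = do.call(cbind, cols), map = do.call(rbind, map))
}

#' Run the full preprocessing cascade on a cohort
#'
#' Applies, in fixed order: winsorization of the maltreatment and depression
#' totals, the missingness filter, the zero-inflation filter, perfect-
#' duplicate collapse within genes, and correlation/distance region grouping.
#' Unit bookkeeping (`units_in = removed + merged_away + retained`) is
#' asserted and returned.
#'
#' @param x A `methylation_cohort`.
#' @return An object of class `preprocessed_cohort`: the updated cohort, the
#'   region-level matrix and map, per-stage reports, and an `accounting`
#'   list.
#' @export
preprocess_cohort <- function(x) {
  stopifnot(inherits(x, "methylation_cohort"))
  cfg <- x$config
  ph <- x$phenotypes
  w_ctq <- winsorize_scores(ph$maltreatment, cfg$winsor_k, cfg$winsor_mode)
  w_bdi <- winsorize_scores(ph$depression, cfg$winsor_k, cfg$winsor_mode)
  ph$maltreatment <- w_ctq$values
  ph$depression <- w_bdi$values

  n_in <- ncol(x$methylation)
  qc <- qc_filter_units(x$methylation, cfg$missing_frac_max, cfg$zero_frac_min)
  dup <- collapse_perfect_duplicates(qc$matrix, x$annotation,
                                     tol = cfg$duplicate_r_tol)
  reg <- group_regions(dup$matrix, dup$annotation,
                       r_min = cfg$region_r_min,
                       window_bp = cfg$region_window_bp)

  n_missing <- sum(qc$report$reason == "missingness")
  n_zero <- sum(qc$report$reason == "zero-inflated")
  n_merged_away <- ncol(qc$matrix) - ncol(dup$matrix)
  n_out <- ncol(dup$matrix)
  stopifnot(n_in == n_missing + n_zero + n_merged_away + n_out)

  out <- cohort(ph, dup$matrix, dup$annotation, config = cfg)
  structure(list(
    cohort = out,
    regions = reg$matrix,
    region_map = reg$map,
    reports = list(
      winsorization = data.frame(
        field = c("maltreatment", "depression"),
        n_modified = c(w_ctq$n_modified, w_bdi$n_modified),
        lower = c(w_ctq$lower, w_bdi$lower),
        upper = c(w_ctq$upper, w_bdi$upper)),
      qc = qc$report,
      duplicates = dup$report),
    accounting = list(units_in = n_in, removed_missingness = n_missing,
                      removed_zero_inflated = n_zero,
                      merged_away = n_merged_away, units_retained = n_out,
                      regions = sum(reg$map$n_members > 1L))
  ), class = "preprocessed_cohort")
}

#' @export
print.preprocessed_cohort <- function(x, ...) {
  a <- x$accounting
  cat(sprintf(paste0("Preprocessed cohort: %d units in -> %d missingness, ",
                     "%d zero-inflated, %d merged -> %d retained ",
                     "(%d multi-unit regions)\n"),
              a$units_in, a$removed_missingness, a$removed_zero_inflated,
              a$merged_away, a$units_retained, a$regions))
  invisible(x)
}
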