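#' CpG-unit annotation table
#'
#' Validates an annotation of EpiTYPER-style CpG units. A unit covers one or
#' more adjacent CpG dinucleotides on one chromosome and is measured as a
#' single percent-methylation value.
#'
#' @param unit_id Character vector of unique unit identifiers
#'   (e.g. `"NR3C1_2_CpG_49to52"`).
#' @param gene Gene symbol per unit.
#' @param chrom Chromosome per unit (GRCh37 naming, e.g. `"chr5"`).
#' @param positions Either a list of integer vectors of 1-based GRCh37
#'   coordinates, or a character vector of semicolon-joined coordinates.
#' @return A `data.frame` with columns `unit_id`, `gene`, `chrom`,
#'   `positions` (semicolon-joined), `n_cpgs`.
#' @export
cpg_annotation <- function(unit_id, gene, chrom, positions) {
  if (anyDuplicated(unit_id))
    abort("duplicate unit_id in annotation", "annotation_error")
  if (is.character(positions)) positions <- parse_positions(positions)
  if (length(positions) != length(unit_id))
    abort("positions must align with unit_id", "annotation_error")
  for (i in seq_along(positions)) {
    p <- positions[[i]]
    if (length(p) == 0L || anyNA(p))
      abort(paste0("unit ", unit_id[i], ": positions empty or missing"),
            "annotation_error")
    if (is.unsorted(p, strictly = TRUE))
      abort(paste0("unit ", unit_id[i], ": positions not strictly increasing"),
            "annotation_error")
  }
  data.frame(
    unit_id = as.character(unit_id),
    gene = as.character(gene),
    chrom = as.character(chrom),
    positions = vapply(positions, paste, "", collapse = ";"),
    n_cpgs = vapply(positions, length, 1L),
    stringsAsFactors = FALSE
  )
}

#' @noRd
parse_positions <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(p) as.integer(p))
}

#' Assemble and validate a cohort
#'
#' Binds a phenotype table, a percent-methylation matrix and a CpG-unit
#' annotation into one validated object. Participant order is canonicalized
#' by sorted ID so downstream results do not depend on file order; unit order
#' follows the annotation.
#'
#' @param phenotypes `data.frame` with `participant_id`, `maltreatment`
#'   (CTQ-SF total, floor 25), `depression` (BDI-II total, 0-63) and optional
#'   covariates `age`, `drug_use`, `smoking`, `alcohol`, `bmi`.
#' @param methylation Numeric matrix, participants x units, percent scale
#'   0-100, `NA` allowed; `rownames` are participant IDs, `colnames` unit IDs.
#' @param annotation Annotation `data.frame` as from [cpg_annotation()].
#' @param config An [analysis_config()].
#' @return An object of class `methylation_cohort`.
#' @export
cohort <- function(phenotypes, methylation, annotation,
                   config = analysis_config()) {
  if (!"participant_id" %in% names(phenotypes))
    abort("phenotype table lacks participant_id", "cohort_inconsistency")
  for (f in c("maltreatment", "depression"))
    if (!f %in% names(phenotypes))
      abort(paste0("phenotype table lacks ", f), "cohort_inconsistency")
  pid <- as.character(phenotypes$participant_id)
  if (anyDuplicated(pid))
    abort("duplicate participant_id in phenotype table", "cohort_inconsistency")
  if (is.null(rownames(methylation)))
    abort("methylation matrix lacks participant rownames", "cohort_inconsistency")
  if (!setequal(pid, rownames(methylation)))
    abort("participant ID sets of phenotypes and methylation differ",
          "cohort_inconsistency")
  if (anyDuplicated(annotation$unit_id))
    abort("duplicate unit_id in annotation", "annotation_error")
  if (!setequal(colnames(methylation), annotation$unit_id))
    abort("methylation columns do not match annotation unit_id set",
          "annotation_error")

  vals <- methylation[!is.na(methylation)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 100))
    abort("methylation values outside [0, 100]", "value_domain_error")
  with_val <- function(f, ok, msg) {
    v <- phenotypes[[f]]
    if (!is.null(v) && any(!is.na(v) & !ok(v))) abort(msg, "value_domain_error")
  }
  with_val("maltreatment", function(v) v >= 25, "maltreatment total below scale floor 25")
  with_val("depression", function(v) v >= 0, "depression total below 0")
  with_val("age", function(v) v > 0, "non-positive age")
  with_val("bmi", function(v) v > 0, "non-positive bmi")

  ord <- order(pid)
  phenotypes <- phenotypes[ord, , drop = FALSE]
  rownames(phenotypes) <- NULL
  methylation <- methylation[as.character(phenotypes$participant_id),
                             annotation$unit_id, drop = FALSE]
  storage.mode(methylation) <- "double"
  structure(list(phenotypes = phenotypes, methylation = methylation,
                 annotation = annotation, config = config),
            class = "methylation_cohort")
}

#' @export
print.methylation_cohort <- function(x, ...) {
  cat(sprintf("Methylation cohort: %d participants x %d CpG units (%d genes)\n",
              nrow(x$methylation), ncol(x$methylation),
              length(unique(x$annotation$gene))))
  cat(sprintf("  missing methylation cells: %.1f%%\n",
              100 * mean(is.na(x$methylation))))
  invisible(x)
}

#' Read a cohort from delimited text files
#'
#' Accepts tab- or comma-separated files. The methylation file holds one row
#' per participant (first column `participant_id`, remaining columns one per
#' unit); the annotation file holds `unit_id`, `gene`, `chrom`, `positions`
#' (semicolon-joined 1-based GRCh37 coordinates). Missing methylation cells
#' may be empty or `"NA"`; values outside the percent scale are rejected.
#'
#' @param phenotype_path,methylation_path,annotation_path File paths.
#' @param config An [analysis_config()].
#' @return A validated `methylation_cohort`.
#' @export
read_cohort <- function(phenotype_path, methylation_path, annotation_path,
                        config = analysis_config()) {
  ph <- read_delim_auto(phenotype_path)
  me <- read_delim_auto(methylation_path)
  an <- read_delim_auto(annotation_path)
  if (!"participant_id" %in% names(me))
    abort("methylation file lacks participant_id column", "cohort_inconsistency")
  for (f in c("unit_id", "gene", "chrom", "positions"))
    if (!f %in% names(an))
      abort(paste0("annotation file lacks column ", f), "annotation_error")
  mat <- as.matrix(me[, setdiff(names(me), "participant_id"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(me$participant_id)
  ann <- cpg_annotation(an$unit_id, an$gene, an$chrom, an$positions)
  cohort(ph, mat, ann, config = config)
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: writes `phenotypes.tsv`, `methylation.tsv`
#' and `annotation.tsv` under `dir`. Numeric values are rendered so that
#' reading the files back reproduces the cohort bit-for-bit, including the
#' missingness pattern (`NA` sentinel).
#'
#' @param x A `methylation_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "methylation_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("phenotypes.tsv", "methylation.tsv",
                            "annotation.tsv"))
  write_tsv(x$phenotypes, paths[1])
  me <- data.frame(participant_id = rownames(x$methylation),
                   x$methylation, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(me, paths[2])
  write_tsv(x$annotation, paths[3])
  invisible(paths)
}

#' Write analysis reports
#'
#' Writes one deterministic TSV per analysis family plus a machine-readable
#' JSON run summary (effective configuration, seed, stage accounting).
#' Re-running with identical inputs yields byte-identical files: no
#' timestamps, fixed column order, full-precision numerics.
#'
#' @param tables Named list of `data.frame`s, one per analysis family
#'   (e.g. `screen_exposure`, `screen_outcome`, `mediation`, `moderation`).
#' @param out_dir Output directory.
#' @param summary Named list embedded as `run_summary.json` (config, seed,
#'   accounting, warnings).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(tables, out_dir, summary = list()) {
  if (!is.list(tables) || (length(tables) && is.null(names(tables))))
    abort("tables must be a named list of data.frames", "report_error")
  ok <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.access(out_dir, 2) == 0
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write to ", out_dir), "io_error")
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(as.data.frame(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  sp <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, sp))
}

#' Substitute raw phenotype values
#'
#' Returns a copy of the cohort with the given raw values written into one
#' phenotype field for the given participants; the input cohort is untouched.
#' Intended for planting extreme scores when testing winsorization.
#'
#' @param x A `methylation_cohort`.
#' @param field Phenotype column name.
#' @param values Replacement values (recycled against `ids` must match).
#' @param ids Participant IDs to modify.
#' @return A new `methylation_cohort`.
#' @export
inject_outliers <- function(x, field, values, ids) {
  stopifnot(inherits(x, "methylation_cohort"))
  if (length(values) != length(ids))
    abort("values and ids must have equal length", "lookup_error")
  if (!field %in% names(x$phenotypes))
    abort(paste0("unknown phenotype field: ", field), "lookup_error")
  idx <- match(as.character(ids), as.character(x$phenotypes$participant_id))
  if (anyNA(idx))
    abort(paste0("unknown participant id(s): ",
                 paste(ids[is.na(idx)], collapse = ", ")), "lookup_error")
  ph <- x$phenotypes
  ph[[field]][idx] <- values
  cohort(ph, x$methylation, x$annotation, config = x$config)
}
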