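# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "cpgmediate_error", "error")))
}

#' @noRd
warn <- function(message, class = "cpgmediate_warning") {
  warning(warningCondition(message, class = c(class, "cpgmediate_warning", "warning")))
}

# Deterministic per-stage child seed so adding a stage never perturbs the
# random stream of earlier stages. Polynomial string hash folded with the
# run seed, kept inside the 32-bit integer range R requires of set.seed().
#' @noRd
child_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

# Simple-regression two-sided p-value from the pairwise-complete correlation;
# algebraically identical to the t-test on the slope of lm(y ~ x).
#' @noRd
simple_lm_p <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) return(NA_real_)
  sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- stats::cor(x[ok], y[ok])
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
}

# Write a data.frame as deterministic TSV: numeric columns rendered with
# %.17g so doubles round-trip exactly, NA written as "NA".
#' @noRd
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

# Field-delimited read with separator sniffing (tab default, comma accepted).
#' @noRd
read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), "io_error")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("NA", ""), check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}
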