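# Shared fixtures and independent oracles for the test suite.

# Residualize v against the columns of X (plus intercept); the result is
# exactly orthogonal to them, which lets fixtures plant exact coefficients.
orth_resid <- function(v, ...) {
  X <- data.frame(...)
  unname(stats::resid(stats::lm(v ~ ., data = cbind(data.frame(v = v), X))))
}

# Brute-force Benjamini-Hochberg: sort, scale by m/rank, cumulative minimum
# from the largest p downwards, clip at 1, unsort.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force OLS via the normal equations, with classical standard errors.
ols_brute <- function(y, X) {
  X1 <- cbind(`(Intercept)` = 1, as.matrix(X))
  XtX_inv <- solve(t(X1) %*% X1)
  beta <- XtX_inv %*% t(X1) %*% y
  res <- y - X1 %*% beta
  df_res <- length(y) - ncol(X1)
  s2 <- sum(res^2) / df_res
  se <- sqrt(diag(XtX_inv) * s2)
  tss <- sum((y - mean(y))^2)
  list(beta = drop(beta), se = se, r2 = 1 - sum(res^2) / tss)
}

# Small hand-buildable cohort: explicit matrix and phenotypes, valid ranges.
make_tiny_cohort <- function(mat, genes = NULL, config = analysis_config()) {
  n <- nrow(mat)
  ids <- colnames(mat)
  if (is.null(genes)) genes <- rep("GENE1", length(ids))
  ann <- cpg_annotation(ids, genes, rep("chr1", length(ids)),
                        as.list(seq(100L, by = 1000L,
                                    length.out = length(ids))))
  rownames(mat) <- sprintf("S%02d", seq_len(n))
  ph <- data.frame(participant_id = rownames(mat),
                   maltreatment = seq(26, 70, length.out = n),
                   depression = seq(1, 40, length.out = n),
                   stringsAsFactors = FALSE)
  cohort(ph, mat, ann, config = config)
}

# Mediation fixture with exact planted path coefficients: the mediator's
# residual is orthogonalized against {1, x}, and the outcome is an exact
# linear combination, so OLS recovers a, b and c' without error.
make_exact_mediation <- function(n = 156, a = 0.04, b = 1.12, cp = 0.25,
                                 m_noise_sd = 1, seed = 42) {
  set.seed(seed)
  x <- rnorm(n, 37, 11)
  e <- orth_resid(rnorm(n), x = x)
  e <- e / stats::sd(e) * m_noise_sd
  m <- 10 + a * x + e
  y <- 2 + cp * x + b * m
  list(x = x, m = m, y = y)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() {
  p <- system.file("cli", "cpgmediate.R", package = "cpgmediate")
  stopifnot(nzchar(p))
  p
}
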