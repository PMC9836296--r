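make_screen_stub <- function(ids, sig, b) {
  data.frame(unit_id = ids, level = "unit",
             b_unadj = b, b_adj = b, p_unadj = ifelse(sig, 0.01, 0.5),
             p_adj = ifelse(sig, 0.01, 0.5),
             sig_unadj = sig, sig_adj = sig, stringsAsFactors = FALSE)
}

test_that("mediation candidates are the signed screen intersection", {
  ids <- paste0("u", 1:6)
  ex <- make_screen_stub(ids, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
                         c(0.04, -0.05, 0.02, 0.01, 0.01, 0.03))
  ou <- make_screen_stub(ids, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                         c(0.5, -0.4, 0.2, 0.3, 0.1, 0.2))
  cand <- select_mediation_candidates(ex, ou)
  expect_identical(cand$unit_id, c("u1", "u2", "u6"))
  expect_identical(cand$sign, c(1L, -1L, 1L))
  expect_equal(cand$b_exposure, c(0.04, -0.05, 0.03))

  # disjoint significance sets give a valid empty result
  ex2 <- make_screen_stub(ids, c(TRUE, TRUE, rep(FALSE, 4)), 0.1)
  ou2 <- make_screen_stub(ids, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE), 0.1)
  expect_identical(nrow(select_mediation_candidates(ex2, ou2)), 0L)

  expect_error(select_mediation_candidates(ex, ou[1:3, ]),
               class = "cohort_inconsistency")
})

test_that("a noiseless mediation chain is recovered exactly", {
  # M = 0.5 X + tiny exactly-orthogonal jitter (so the outcome design has
  # rank 3), Y = 2 M exactly: a = 0.5, b = 2, c' = 0, ACME = 1
  set.seed(8)
  n <- 40
  x <- rnorm(n, 30, 5)
  e <- orth_resid(rnorm(n), x = x)
  m <- 0.5 * x + e / sd(e) * 1e-4
  y <- 2 * m
  res <- fit_mediation(x, m, y, n_sims = 200, seed = 1)
  expect_equal(res$acme, 1, tolerance = 1e-10)
  expect_equal(res$ade, 0, tolerance = 1e-8)
  expect_lt(diff(res$ci_acme), 1e-3)
})

test_that("point estimates obey the printed-path arithmetic", {
  fx <- make_exact_mediation(a = 0.04, b = 1.12, cp = 0.25)
  res <- fit_mediation(fx$x, fx$m, fx$y, n_sims = 1000, seed = 3)
  expect_equal(res$a_path$B, 0.04, tolerance = 1e-10)
  expect_equal(res$b_path$B, 1.12, tolerance = 1e-10)
  expect_equal(res$acme, 0.04 * 1.12, tolerance = 1e-10)  # 0.0448
  expect_equal(round(res$acme, 2), 0.04)
  expect_equal(res$total, res$acme + res$ade, tolerance = 1e-12)
  expect_equal(res$prop_mediated, 0.0448 / (0.0448 + 0.25), tolerance = 1e-10)
})

test_that("effect decomposition and interval mechanics hold on noisy data", {
  set.seed(14)
  n <- 200
  x <- rnorm(n, 37, 11)
  m <- 20 + 0.06 * x + rnorm(n, 0, 2)
  y <- 5 + 0.2 * x + 0.5 * m + rnorm(n, 0, 6)
  res <- fit_mediation(x, m, y, n_sims = 1000, seed = 5)
  expect_lt(abs(res$ade + res$acme - res$total), 1e-10)
  expect_true(res$ci_acme[1] <= res$acme && res$acme <= res$ci_acme[2])
  expect_true(res$p_acme >= 0 && res$p_acme <= 1)

  # seed determinism and seed sensitivity
  res2 <- fit_mediation(x, m, y, n_sims = 1000, seed = 5)
  expect_identical(res2$ci_acme, res$ci_acme)
  res3 <- fit_mediation(x, m, y, n_sims = 1000, seed = 6)
  expect_false(identical(res3$ci_acme, res$ci_acme))

  # bootstrap mode agrees on the point estimate and roughly on the interval
  resb <- fit_mediation(x, m, y, n_sims = 300, seed = 5, method = "bootstrap")
  expect_identical(resb$acme, res$acme)
  expect_lt(abs(diff(resb$ci_acme) - diff(res$ci_acme)),
            0.75 * diff(res$ci_acme))
})

test_that("Monte-Carlo intervals have converged by 1,000 draws", {
  set.seed(15)
  n <- 156
  x <- rnorm(n, 37, 11)
  m <- 20 + 0.05 * x + rnorm(n, 0, 2.5)
  y <- 5 + 0.2 * x + 0.6 * m + rnorm(n, 0, 7)
  r1k <- fit_mediation(x, m, y, n_sims = 1000, seed = 9)
  r10k <- fit_mediation(x, m, y, n_sims = 10000, seed = 9)
  w <- diff(r1k$ci_acme)
  expect_lt(max(abs(r10k$ci_acme - r1k$ci_acme)), 0.25 * w)
})

test_that("mediation rejects degenerate inputs", {
  x <- rnorm(30)
  expect_error(fit_mediation(x, rep(1, 30), rnorm(30), n_sims = 100),
               class = "degenerate_mediator")
  expect_error(fit_mediation(x[1:5], rnorm(5), rnorm(5), n_sims = 100),
               class = "insufficient_data")
  expect_error(fit_mediation(x, rnorm(30), rnorm(30), n_sims = 10),
               class = "config_error")
})

test_that("the cumulative index respects signs and modes", {
  mat <- cbind(u1 = c(10, 20, 30), u2 = c(1, 2, 3), u3 = c(5, 5, 6))
  rownames(mat) <- paste0("S", 1:3)
  cand <- data.frame(unit_id = c("u1", "u2"), sign = c(1L, -1L))

  # singleton identity
  idx1 <- build_mediator_index(mat, data.frame(unit_id = "u1", sign = 1L))
  expect_equal(unname(idx1), mat[, "u1"], ignore_attr = TRUE)

  # sign-aligned: M1 - M2; literal: M1 + M2
  idx <- build_mediator_index(mat, cand, mode = "sign-aligned")
  expect_equal(as.numeric(idx), c(9, 18, 27))
  idx_lit <- build_mediator_index(mat, cand, mode = "literal")
  expect_equal(as.numeric(idx_lit), c(11, 22, 33))
  expect_identical(attr(idx, "mode"), "sign-aligned")

  matNA <- mat; matNA[, "u2"] <- NA_real_
  expect_error(build_mediator_index(matNA, cand),
               class = "insufficient_data")
})

test_that("a sign-aligned index of opposing a-paths tracks the exposure", {
  ann <- default_panel("IL6")
  u_pos <- ann$unit_id[1]; u_neg <- ann$unit_id[6]
  tr <- simulation_truth(n_participants = 400, annotation = ann,
                         a = setNames(c(0.06, -0.06), c(u_pos, u_neg)),
                         missing_frac = 0)
  co <- generate_cohort(tr, seed = 17)
  cand <- data.frame(unit_id = c(u_pos, u_neg), sign = c(1L, -1L))
  idx <- build_mediator_index(co$methylation, cand)
  slope <- fit_linear(idx, list(x = co$phenotypes$maltreatment), "x")
  expect_gt(slope$B, 0)
  expect_lt(slope$p, 0.05)
})

test_that("cumulative mediation recovers a planted two-mediator truth", {
  ann <- default_panel("IL6")
  u <- ann$unit_id[c(1, 6)]
  tr <- simulation_truth(n_participants = 500, annotation = ann,
                         a = setNames(c(0.05, -0.05), u),
                         b = setNames(c(0.6, -0.6), u),
                         c_prime = 0.2, outcome_intercept = 30,
                         outcome_skew = FALSE, missing_frac = 0)
  co <- generate_cohort(tr, seed = 19)
  cand <- data.frame(unit_id = u, sign = c(1L, -1L))
  res <- mediate_cumulative(co, cand, n_sims = 1000, seed = 23)
  # analytic ACME of the sign-aligned index: a_idx = 0.10, b_idx = 0.6
  a_se <- res$a_path$SE
  expect_lt(abs(res$a_path$B - 0.10), 3 * a_se)
  expect_true(res$significant)
  expect_true(res$ci_acme[1] > 0)
})
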