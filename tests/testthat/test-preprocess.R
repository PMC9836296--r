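test_that("winsorization replaces only out-of-bound scores", {
  expect_identical(winsorize_scores(c(1, 2, 3), k = 3)$n_modified, 0L)
  expect_equal(winsorize_scores(c(1, 2, 3), k = 3)$values, c(1, 2, 3))

  # twenty 30s plus one 100: the 100 exceeds mean + 3 SD and is pulled back
  v <- c(rep(30, 20), 100)
  hi <- mean(v) + 3 * sd(v)
  expect_lt(hi, 100)
  w <- winsorize_scores(v, k = 3)
  expect_identical(w$n_modified, 1L)
  expect_equal(w$values, c(rep(30, 20), max(v[v <= hi])))
  expect_equal(w$values[21], 30)

  # boundary mode substitutes the bound itself
  wb <- winsorize_scores(v, k = 3, mode = "boundary")
  expect_equal(wb$values[21], hi)

  # NA pass-through, order preserved
  v2 <- c(5, NA, 6, 7, 100, NA)
  w2 <- winsorize_scores(c(v2, rep(6, 10)), k = 2)
  expect_true(all(is.na(w2$values[c(2, 6)])))
})

test_that("winsorization converges to a fixed point within a few passes", {
  set.seed(404)
  battery <- c(
    lapply(1:6, function(i) rgamma(80, shape = 1.5, scale = 10)),
    lapply(1:6, function(i) c(rnorm(60, 40, 5), runif(3, 80, 120)))
  )
  for (v in battery) {
    prev <- v
    n_first <- winsorize_scores(prev, k = 3)$n_modified
    converged <- FALSE
    for (pass in 1:5) {
      w <- winsorize_scores(prev, k = 3)
      expect_lte(w$n_modified, max(n_first, w$n_modified))
      if (identical(w$values, prev)) { converged <- TRUE; break }
      prev <- w$values
    }
    if (!converged)
      converged <- identical(winsorize_scores(prev, k = 3)$values, prev)
    expect_true(converged)
  }
})

test_that("winsorization degenerate inputs are handled", {
  expect_warning(winsorize_scores(rep(5, 10), k = 3))
  expect_error(winsorize_scores(c(1, 2), k = 3), class = "insufficient_data")
})

test_that("QC removes high-missingness then zero-inflated units, in order", {
  set.seed(1)
  n <- 10
  mat <- cbind(
    clean = runif(n, 10, 60),
    holey = c(rep(NA, 3), runif(7, 10, 60)),     # 30% missing
    zeros = c(rep(0, 9), 25),                    # 9/10 zeros
    both  = c(rep(NA, 4), rep(0, 6))             # fails both; missingness wins
  )
  rownames(mat) <- sprintf("S%02d", 1:n)
  res <- qc_filter_units(mat, 0.20, 0.80)
  expect_identical(colnames(res$matrix), "clean")
  expect_identical(res$report$reason[res$report$unit_id == "holey"], "missingness")
  expect_identical(res$report$reason[res$report$unit_id == "zeros"], "zero-inflated")
  expect_identical(res$report$reason[res$report$unit_id == "both"], "missingness")
  expect_equal(res$report$statistic[res$report$unit_id == "holey"], 0.3)
  expect_equal(res$report$statistic[res$report$unit_id == "zeros"], 0.9)

  clean <- mat[, "clean", drop = FALSE]
  res2 <- qc_filter_units(clean, 0.20, 0.80)
  expect_identical(res2$matrix, clean)
  expect_identical(nrow(res2$report), 0L)

  expect_error(qc_filter_units(mat[, "zeros", drop = FALSE], 0.2, 0.8),
               class = "all_units_removed")
})

test_that("perfect duplicates merge within genes only, transitively", {
  set.seed(2)
  n <- 12
  base <- runif(n, 20, 40)
  mat <- cbind(a1 = base, a2 = base, a3 = base + rnorm(n),  # a1==a2 exactly (r=1)
               b1 = base)                                   # same values, other gene
  rownames(mat) <- sprintf("S%02d", 1:n)
  ann <- cpg_annotation(colnames(mat), c("A", "A", "A", "B"),
                        rep("chr1", 4), list(100L, 300L, 700L, 9000L))
  res <- collapse_perfect_duplicates(mat, ann)
  expect_identical(colnames(res$matrix), c("a1", "a3", "b1"))
  expect_equal(unname(res$matrix[, "a1"]), unname(base))  # mean of identical columns
  expect_identical(res$report$members, "a1;a2")
  expect_identical(res$annotation$positions[res$annotation$unit_id == "a1"],
                   "100;300")
  expect_identical(res$annotation$n_cpgs[res$annotation$unit_id == "a1"], 2L)

  # transitive closure: three exact copies collapse to one unit
  mat3 <- cbind(c1 = base, c2 = base, c3 = base)
  rownames(mat3) <- rownames(mat)
  ann3 <- cpg_annotation(colnames(mat3), rep("C", 3), rep("chr2", 3),
                         list(10L, 20L, 30L))
  res3 <- collapse_perfect_duplicates(mat3, ann3)
  expect_identical(ncol(res3$matrix), 1L)
  expect_identical(res3$report$members, "c1;c2;c3")

  # nothing at r = 1 -> identity
  mat_id <- cbind(d1 = base, d2 = base + rnorm(n))
  rownames(mat_id) <- rownames(mat)
  ann_id <- cpg_annotation(colnames(mat_id), rep("D", 2), rep("chr3", 2),
                           list(10L, 40L))
  res_id <- collapse_perfect_duplicates(mat_id, ann_id)
  expect_identical(res_id$matrix, mat_id)
  expect_identical(nrow(res_id$report), 0L)
})

test_that("duplicate collapse skips pairs with <3 complete observations", {
  mat <- cbind(e1 = c(1, 2, NA, NA, NA, 6),
               e2 = c(1, NA, 3, NA, NA, 6))
  rownames(mat) <- sprintf("S%02d", 1:6)
  ann <- cpg_annotation(colnames(mat), c("E", "E"), c("chr1", "chr1"),
                        list(10L, 20L))
  expect_warning(res <- collapse_perfect_duplicates(mat, ann),
                 class = "undefined_correlation")
  expect_identical(ncol(res$matrix), 2L)
})

test_that("collapse is invariant to participant and unit input order", {
  set.seed(3)
  n <- 10
  base <- runif(n, 20, 40)
  mat <- cbind(a1 = base, a2 = base, a3 = base + rnorm(n))
  rownames(mat) <- sprintf("S%02d", 1:n)
  ann <- cpg_annotation(colnames(mat), rep("A", 3), rep("chr1", 3),
                        list(100L, 200L, 300L))
  ref <- collapse_perfect_duplicates(mat, ann)
  perm_p <- sample(n); perm_u <- c(3, 1, 2)
  res <- collapse_perfect_duplicates(mat[perm_p, perm_u],
                                     ann[perm_u, , drop = FALSE])
  expect_identical(sort(colnames(res$matrix)), sort(colnames(ref$matrix)))
  expect_equal(res$matrix[rownames(ref$matrix), colnames(ref$matrix)],
               ref$matrix)
})

test_that("region grouping chains adjacent correlated units", {
  set.seed(4)
  n <- 60
  z <- rnorm(n)
  u1 <- 30 + 3 * z + rnorm(n)   # pairwise r about 0.9 via shared factor
  u2 <- 28 + 3 * z + rnorm(n)
  u3 <- 35 + 3 * z + rnorm(n)
  mat <- cbind(r1 = u1, r2 = u2, r3 = u3)
  rownames(mat) <- sprintf("S%03d", 1:n)
  # 400 bp between neighbours: one chained region of 3
  ann <- cpg_annotation(colnames(mat), rep("G", 3), rep("chr1", 3),
                        list(1000L, 1400L, 1800L))
  res <- group_regions(mat, ann, r_min = 0.5, window_bp = 500)
  expect_identical(res$map$n_members, 3L)
  expect_equal(unname(res$matrix[, 1]), unname(rowMeans(mat)))

  # same correlation but 600 bp apart: two singletons
  ann2 <- cpg_annotation(c("r1", "r2"), rep("G", 2), rep("chr1", 2),
                         list(1000L, 1600L))
  res2 <- group_regions(mat[, 1:2], ann2, r_min = 0.5, window_bp = 500)
  expect_identical(res2$map$n_members, c(1L, 1L))
  expect_identical(res2$matrix, mat[, 1:2])

  # close but uncorrelated: two singletons
  mat3 <- cbind(q1 = rnorm(n, 30), q2 = rnorm(n, 30))
  rownames(mat3) <- rownames(mat)
  ann3 <- cpg_annotation(colnames(mat3), rep("Q", 2), rep("chr1", 2),
                         list(1000L, 1100L))
  expect_identical(group_regions(mat3, ann3, 0.5, 500)$map$n_members,
                   c(1L, 1L))

  # a single unit in a gene passes through unchanged
  res4 <- group_regions(mat[, 1, drop = FALSE],
                        ann[1, , drop = FALSE], 0.5, 500)
  expect_identical(res4$matrix, mat[, 1, drop = FALSE])
})

test_that("planted duplicate and region maps are recovered exactly", {
  ann <- default_panel("IL10")
  ids <- ann$unit_id
  dup_map <- setNames(ids[2], ids[3])       # unit 3 is a copy of unit 2
  region_block <- ids[7:9]
  tr <- simulation_truth(n_participants = 120, annotation = ann,
                         missing_frac = 0,
                         duplicate_map = dup_map,
                         region_map = list(region_block), region_rho = 0.7)
  co <- generate_cohort(tr, seed = 11)
  pre <- preprocess_cohort(co)
  # the merge report recovers exactly the planted duplicate pair
  expect_identical(nrow(pre$reports$duplicates), 1L)
  expect_setequal(strsplit(pre$reports$duplicates$members, ";")[[1]],
                  c(ids[2], ids[3]))
  # the planted latent block is grouped; the adjacent-unit chain covers it
  multi <- pre$region_map[pre$region_map$n_members > 1L, ]
  mem <- unlist(strsplit(multi$members, ";"))
  expect_true(all(region_block %in% mem))
})

test_that("preprocessing bookkeeping always balances", {
  ann <- default_panel("IL6")
  ids <- ann$unit_id
  tr <- simulation_truth(n_participants = 50, annotation = ann,
                         missing_frac = setNames(c(0.6, rep(0, 9)), ids),
                         duplicate_map = setNames(ids[4], ids[5]),
                         unit_mean = c(30, 30, 0, rep(30, 7)),
                         unit_sd = c(3, 3, 0, rep(3, 7)))
  co <- generate_cohort(tr, seed = 13)
  pre <- preprocess_cohort(co)
  a <- pre$accounting
  expect_identical(a$units_in,
                   a$removed_missingness + a$removed_zero_inflated +
                     a$merged_away + a$units_retained)
  expect_identical(a$removed_missingness, 1L)
  expect_identical(a$removed_zero_inflated, 1L)  # the all-zero unit
  expect_identical(a$merged_away, 1L)
})
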