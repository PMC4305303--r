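make_counts <- function(n_tf, n_gene, seed = 1, lambda = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_tf * n_gene, lambda), nrow = n_tf,
              dimnames = list(sprintf("TF%02d", seq_len(n_tf)),
                              sprintf("g%02d", seq_len(n_gene))))
  storage.mode(m) <- "integer"
  class(m) <- c("hit_count_matrix", class(m))
  m
}

test_that("observed_statistic sums DE-gene counts and validates ids", {
  counts <- make_counts(3, 6)
  counts["TF01", ] <- 0L
  counts["TF02", c("g01", "g02")] <- c(2L, 3L)
  gl <- gene_list(c("g01", "g02"), colnames(counts))
  expect_identical(observed_statistic(counts, gl, "TF01"), 0L)
  expect_identical(observed_statistic(counts, gl, "TF02"), 5L)
  expect_error(observed_statistic(counts, gl, "nope"), "nope")
  gl2 <- gene_list("x01", c(colnames(counts), "x01", "x02"))
  expect_error(observed_statistic(counts, gl2, "TF01"), "x01")

  # naive per-gene summation oracle on a random 20 x 50 matrix
  counts <- make_counts(20, 50, seed = 5)
  de <- sample(colnames(counts), 8)
  gl <- gene_list(de, colnames(counts))
  for (tf in rownames(counts)) {
    acc <- 0L
    for (g in de) acc <- acc + counts[tf, g]
    expect_identical(observed_statistic(counts, gl, tf), as.integer(acc))
  }
  # promoter-level indicator statistic
  expect_identical(observed_statistic(counts, gl, "TF01", "genes_with_hit"),
                   as.integer(sum(counts["TF01", de] > 0)))
})

test_that("resample_null is exchangeable, deterministic, and seed-isolated", {
  counts <- make_counts(2, 8)
  counts["TF01", ] <- 3L   # identical counts: every subset has the same total
  gl <- gene_list(c("g01", "g02", "g03"), colnames(counts))
  nd <- resample_null(counts, gl, "TF01", n_resamples = 200, seed = 9)
  expect_true(all(nd$samples == observed_statistic(counts, gl, "TF01")))

  one <- resample_null(counts, gl, "TF02", n_resamples = 1, seed = 3)
  two <- resample_null(counts, gl, "TF02", n_resamples = 1, seed = 3)
  expect_identical(one$samples, two$samples)
  expect_length(one$samples, 1L)

  # calling the resampler must not disturb the caller's RNG stream
  set.seed(77); a <- runif(1)
  set.seed(77); invisible(resample_null(counts, gl, "TF02", 10, seed = 1))
  expect_identical(runif(1), a)

  gl_bad <- gene_list("g01", c(colnames(counts), "missing"))
  expect_error(resample_null(counts, gl_bad, "TF01", 10, 1), "missing")
})

test_that("empirical p-value uses the +1 correction with floor and ceiling", {
  null <- structure(list(tf_id = "t", samples = rep(1L, 9999), seed = 1),
                    class = "null_distribution")
  expect_equal(empirical_pvalue(100, null), 1 / 10000)
  expect_equal(empirical_pvalue(0, null), 1)
  expect_equal(empirical_pvalue(1, null), 1)  # ties count as >= observed

  set.seed(4)
  samples <- sample(seq_len(10000))   # distinct values
  obs <- sort(samples)[5001]          # 5000 samples >= obs
  expect_equal(empirical_pvalue(obs, samples), 5001 / 10001)
})

test_that("exact enumeration handles degenerate structures and refuses blowups", {
  counts <- make_counts(2, 10, seed = 2)
  # DE genes carry the only nonzero counts -> unique maximal subset
  counts["TF01", ] <- 0L
  gl <- gene_list(c("g01", "g02", "g03"), colnames(counts))
  counts["TF01", c("g01", "g02", "g03")] <- 5L
  ex <- exact_null_enumeration(counts, gl, "TF01")
  expect_equal(ex$p_exact, 1 / choose(10, 3))

  counts["TF02", ] <- 7L
  expect_equal(exact_null_enumeration(counts, gl, "TF02")$p_exact, 1)

  big <- make_counts(1, 50)
  gl_big <- gene_list(colnames(big)[1:20], colnames(big))
  expect_error(exact_null_enumeration(big, gl_big, "TF01"), "refusing")
})

test_that("resampling p agrees with exact enumeration within Monte-Carlo error", {
  counts <- make_counts(5, 10, seed = 8, lambda = 3)
  gl <- gene_list(colnames(counts)[c(2, 5, 7, 9)], colnames(counts))
  n_res <- 20000L
  enr <- enrich_tfs(counts, gl, n_resamples = n_res, seed = 13)
  for (tf in rownames(counts)) {
    p_exact <- exact_null_enumeration(counts, gl, tf)$p_exact
    p_emp <- enr$p_empirical[enr$tf_id == tf]
    tol <- 3 * sqrt(p_exact * (1 - p_exact) / n_res) + 2 / n_res
    expect_lt(abs(p_emp - p_exact), tol + 1e-12)
  }
})

test_that("rank_tfs sorts by p, breaks ties by z then id, and assigns tiers", {
  res <- data.frame(
    tf_id = c("b", "a", "c", "d"),
    observed = c(10L, 50L, 30L, 5L),
    null_mean = c(5, 10, 25, 5),
    null_sd = c(1, 2, 5, 0),
    p_empirical = c(0.02, 0.02, 0.2, 0.004)
  )
  ranked <- rank_tfs(res)
  # d: lowest p; then the p = 0.02 tie is broken by z (a: z = 20 > b: z = 5)
  expect_identical(ranked$tf_id, c("d", "a", "b", "c"))
  expect_identical(ranked$rank, 1:4)
  expect_identical(ranked$tier,
                   c("stringent_0.01", "significant_0.05",
                     "significant_0.05", "ns"))
  single <- rank_tfs(res[1, ])
  expect_identical(single$rank, 1L)

  # random instance against an independent sort oracle
  set.seed(31)
  res <- data.frame(tf_id = sprintf("t%02d", 1:20), observed = 1:20,
                    null_mean = runif(20), null_sd = runif(20) + 0.5,
                    p_empirical = sample(c(0.01, 0.04, 0.2), 20, TRUE))
  ranked <- rank_tfs(res)
  z <- (res$observed - res$null_mean) / res$null_sd
  want <- res$tf_id[order(res$p_empirical, -z, res$tf_id)]
  expect_identical(ranked$tf_id, want)
})

test_that("enrich_tfs is deterministic given the seed and consistent with per-TF ops", {
  counts <- make_counts(8, 30, seed = 17)
  gl <- gene_list(colnames(counts)[1:6], colnames(counts))
  a <- enrich_tfs(counts, gl, n_resamples = 500, seed = 42)
  b <- enrich_tfs(counts, gl, n_resamples = 500, seed = 42)
  expect_identical(a, b)
  expect_setequal(a$rank, 1:8)
  expect_true(all(a$p_empirical >= 1 / 501))
  # observed column equals the documented observed statistic
  for (tf in rownames(counts)) {
    expect_identical(a$observed[a$tf_id == tf],
                     observed_statistic(counts, gl, tf))
  }
  # the matrix fast path and the per-TF resampler target the same null:
  # their p-values agree within joint Monte-Carlo error
  nd <- resample_null(counts, gl, "TF01", n_resamples = 4000, seed = 7)
  p_tf <- empirical_pvalue(a$observed[a$tf_id == "TF01"], nd)
  big <- enrich_tfs(counts, gl, n_resamples = 4000, seed = 8)
  p_mat <- big$p_empirical[big$tf_id == "TF01"]
  expect_lt(abs(p_tf - p_mat), 4 * sqrt(0.25 / 4000) * 2)
})

test_that("gene_list enforces the subset invariants", {
  expect_error(gene_list(character(0), c("a", "b")), "non-empty")
  expect_error(gene_list(c("a", "z"), c("a", "b")), "z")
  expect_error(gene_list(c("a", "b"), c("a", "b")), "larger")
})

test_that("enrichment tables round-trip through TSV", {
  counts <- make_counts(4, 12, seed = 3)
  gl <- gene_list(colnames(counts)[1:3], colnames(counts))
  enr <- enrich_tfs(counts, gl, n_resamples = 200, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(enr, path)
  back <- utils::read.delim(path)
  expect_identical(back$tf_id, enr$tf_id)
  expect_equal(back$p_empirical, enr$p_empirical, tolerance = 1e-12)

  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_hit_counts(counts, cpath)
  expect_identical(read_hit_counts(cpath), counts)
})
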