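small_cfg <- function(seed = 1, ...) {
  scenario_config(seed = seed, n_genes = 60L, n_de = 8L,
                  promoter_length = 300L, n_tfs = 8L, ...)
}

test_that("the full scenario is byte-identical across runs with one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_scenario(small_cfg(seed = 5), dir = d1)
  generate_scenario(small_cfg(seed = 5), dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_scenario(small_cfg(seed = 6), dir = d3)
  expect_false(identical(readLines(file.path(d1, "promoters.fasta")),
                         readLines(file.path(d3, "promoters.fasta"))))
})

test_that("background sequences track the configured GC content", {
  set.seed(71)
  cfg <- scenario_config(seed = 71, n_genes = 100L, n_de = 10L,
                         promoter_length = 1000L, gc_content = 0.5,
                         active_tfs = character(0),
                         focal_tfs = character(0), silent_tfs = character(0))
  prom <- generate_promoters(cfg, generate_motifs(cfg))
  chars <- strsplit(paste(prom$promoters, collapse = ""), "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)    # 1e5 bases: binomial sd ~ 0.0016

  set.seed(72)
  cfg2 <- scenario_config(seed = 72, n_genes = 100L, n_de = 10L,
                          gc_content = 0.3, active_tfs = character(0),
                          focal_tfs = character(0),
                          silent_tfs = character(0))
  prom2 <- generate_promoters(cfg2, generate_motifs(cfg2))
  chars2 <- strsplit(paste(prom2$promoters, collapse = ""), "")[[1]]
  expect_lt(abs(mean(chars2 %in% c("G", "C")) - 0.3), 0.01)
})

test_that("motif planting respects rates and records the truth", {
  set.seed(73)
  cfg <- small_cfg(seed = 73, plant_rate_de = 0, plant_rate_bg = 0)
  prom <- generate_promoters(cfg, generate_motifs(cfg))
  expect_identical(nrow(prom$planted), 0L)

  set.seed(74)
  cfg <- small_cfg(seed = 74, plant_rate_de = 1, plant_rate_bg = 0,
                   active_tfs = "TF001")
  motifs <- generate_motifs(cfg)
  prom <- generate_promoters(cfg, motifs)
  cons <- consensus(motifs[["TF001"]])
  for (g in prom$de_genes) {
    s <- prom$promoters[[g]]
    expect_true(grepl(cons, s, fixed = TRUE) ||
                  grepl(cons, revcomp(s), fixed = TRUE), label = g)
  }
  # every recorded insertion is an exact consensus occurrence at its position
  for (i in seq_len(nrow(prom$planted))) {
    rec <- prom$planted[i, ]
    s <- prom$promoters[[rec$gene_id]]
    L <- nchar(cons)
    window <- substr(s, rec$start + 1, rec$start + L)
    expect_identical(if (rec$strand == "+") window else revcomp(window),
                     cons)
  }
})

test_that("generated motifs are informative with distinct consensus strings", {
  set.seed(75)
  cfg <- scenario_config(seed = 75, n_tfs = 50L)
  motifs <- generate_motifs(cfg)
  cons <- vapply(motifs, consensus, character(1))
  expect_identical(anyDuplicated(cons), 0L)
  for (m in motifs) {
    L <- ncol(m$counts)
    expect_true(L >= 8L && L <= 12L)
    # dominant base weight >= 0.8 in every column
    expect_true(all(apply(m$counts, 2, max) / colSums(m$counts) >= 0.8))
  }
  set.seed(75)
  again <- generate_motifs(cfg)
  expect_identical(motifs, again)
})

test_that("expression generator separates expressed TFs from the control floor", {
  set.seed(76)
  cfg <- small_cfg(seed = 76, silent_tfs = c("TF002", "TF005"))
  expr <- generate_expression(cfg)
  res <- expression_filter(cfg$tf_ids, expr, k_sd = 2)
  expect_identical(sort(res$tf_id[res$status == "removed"]),
                   c("TF002", "TF005"))
  expect_true(all(res$status[!res$tf_id %in% c("TF002", "TF005")] == "pass"))

  # no silent TFs configured: nothing removed
  set.seed(77)
  cfg2 <- small_cfg(seed = 77, silent_tfs = character(0))
  expr2 <- generate_expression(cfg2)
  res2 <- expression_filter(cfg2$tf_ids, expr2, k_sd = 2)
  expect_true(all(res2$status == "pass"))
})

test_that("miRNA table reproduces the four-group induction profile", {
  # noiseless: regression recovers the configured slope exactly
  set.seed(78)
  cfg <- scenario_config(seed = 78, mir_sdlog = 0, noise_sd = 0,
                         target_slopes = c(t1 = -0.1))
  rec <- generate_mirna_target_table(cfg)
  res <- regress_target(composite_score(rec), rec$t1)
  expect_equal(res$slope, -0.1, tolerance = 1e-10)
  expect_equal(res$r2, 1, tolerance = 1e-10)

  # group mean folds approach the configured induction over replicates
  set.seed(79)
  folds <- replicate(60, {
    tab <- generate_mirna_target_table(
      scenario_config(seed = 1, mir_fold_10d = 5))
    mean(tab$mir_a[tab$group == "obs_10d"])
  })
  expect_lt(abs(mean(folds) - 5), 0.2)
  # sham group is normalized to mean 1 exactly
  tab <- generate_mirna_target_table(scenario_config(seed = 80))
  expect_equal(mean(tab$mir_a[tab$group == "sham"]), 1, tolerance = 1e-12)
  expect_equal(mean(tab$mir_b[tab$group == "sham"]), 1, tolerance = 1e-12)
})

test_that("focal promoter carries one planted site per focal TF", {
  set.seed(81)
  cfg <- small_cfg(seed = 81, focal_tfs = sprintf("TF%03d", 1:5))
  motifs <- generate_motifs(cfg)
  focal <- generate_focal_promoter(cfg, motifs)
  expect_identical(sort(focal$planted$tf_id), sprintf("TF%03d", 1:5))
  pwms <- lapply(motifs, pwm_from_counts)
  found <- focal_promoter_tfs(pwms, focal$sequence, rel_threshold = 1)
  expect_true(all(sprintf("TF%03d", 1:5) %in% found))

  # empty focal set leaves pure background
  cfg0 <- small_cfg(seed = 81, focal_tfs = character(0))
  set.seed(82)
  f0 <- generate_focal_promoter(cfg0, motifs)
  expect_null(f0$planted)

  # too-short promoter cannot host all sites
  cfg_tiny <- scenario_config(seed = 1, n_genes = 30L, n_de = 4L,
                              promoter_length = 24L, n_tfs = 8L,
                              focal_tfs = sprintf("TF%03d", 1:8))
  set.seed(83)
  expect_error(generate_focal_promoter(cfg_tiny, generate_motifs(cfg_tiny)),
               "too short")
})

test_that("scenario truth record is sufficient to score the pipeline stages", {
  scen <- generate_scenario(small_cfg(seed = 85))
  tr <- scen$truth
  expect_setequal(tr$expected_candidates,
                  setdiff(intersect(tr$active_tfs, tr$focal_tfs),
                          tr$silent_tfs))
  expect_true(all(tr$planted_positions$gene_id %in% scen$universe))
  expect_true(all(names(tr$coupled_targets) %in%
                    names(scen$mirna_targets)))
  # every planted site is an exact consensus occurrence
  for (i in seq_len(nrow(tr$planted_positions))) {
    rec <- tr$planted_positions[i, ]
    cons <- tr$consensus[[rec$tf_id]]
    window <- substr(scen$promoters[[rec$gene_id]], rec$start + 1,
                     rec$start + nchar(cons))
    expect_identical(if (rec$strand == "+") window else revcomp(window),
                     cons)
  }
})

test_that("scenario_config rejects inconsistent designs", {
  expect_error(scenario_config(n_de = 2000L), "n_de")
  expect_error(scenario_config(gc_content = 1.2), "gc_content")
  expect_error(scenario_config(plant_rate_de = 0.1, plant_rate_bg = 0.5),
               "plant_rate")
  expect_error(scenario_config(active_tfs = "TF999"), "active_tfs")
  expect_error(scenario_config(promoter_length = 10L), "promoter_length")
})
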