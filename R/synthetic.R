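#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study: promoter/motif scale, which TFs
#' are transcriptionally "active" (their motifs planted preferentially in DE
#' promoters), which have sites in the focal promoter, which are silent on
#' the array, the four-group sample design, the miRNA induction profile and
#' the miRNA-target coupling. Defaults emulate the study design the pipeline
#' assumes: ~1,000 background genes with 50 DE, 1 kb promoters, 50 TFs,
#' 6-8 animals per group, 5-fold miRNA induction at 10 days of obstruction
#' with partial normalization on de-obstruction, and a 9-target panel of
#' which 4 are inversely coupled to the composite miRNA score.
#'
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @param n_genes,n_de Universe size and DE-set size (n_de < n_genes).
#' @param promoter_length Promoter window length in bases.
#' @param gc_content Background GC fraction in (0, 1).
#' @param n_tfs Number of TF motifs to generate.
#' @param motif_length_range Inclusive range of motif lengths.
#' @param active_tfs TF ids whose consensus is planted preferentially in DE
#'   promoters (default: first 5 TFs).
#' @param plant_rate_de,plant_rate_bg Per-promoter planting probabilities for
#'   active TFs in DE and background promoters (defaults 0.8 and 0.1).
#' @param focal_tfs TF ids whose consensus is planted in the focal promoter
#'   (default: 8 TFs, 3 of them active).
#' @param silent_tfs TF ids whose array expression is drawn from the
#'   negative-control distribution (default: 10 non-active TFs, 2 of them
#'   focal-only).
#' @param n_per_group Named integer vector of samples per group, in order
#'   sham, obs_10d, obs_6w, deobs (default 7, 7, 6, 6).
#' @param mir_fold_10d miRNA fold induction at 10 days (default 5; the study
#'   design this emulates saw 3-7-fold).
#' @param mir_fold_6w,mir_fold_deobs Group mean folds at 6 weeks (default
#'   0.6 * mir_fold_10d) and after de-obstruction (default 1.2, near sham).
#' @param mir_sdlog Log-normal sdlog of per-sample miRNA noise.
#' @param mir_b_scale Raw abundance of the second miRNA relative to the
#'   first before normalization (the second, lower-expressed cluster member).
#' @param target_slopes Named numeric vector, gene id -> true slope of
#'   `target_fc = 1 + slope * (composite - 2) + noise`; slope 0 means
#'   uncoupled. Default: a 9-gene validated-target panel with 4 coupled.
#' @param noise_sd SD of the additive target residual noise.
#' @param n_nc_probes,nc_mean,nc_sd Negative-control probe count and their
#'   baseline normal distribution (expression units).
#' @param probes_per_tf Array probes per TF.
#' @return Validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_genes = 1000L,
                            n_de = 50L,
                            promoter_length = 1000L,
                            gc_content = 0.5,
                            n_tfs = 50L,
                            motif_length_range = c(8L, 12L),
                            active_tfs = NULL,
                            plant_rate_de = 0.8,
                            plant_rate_bg = 0.1,
                            focal_tfs = NULL,
                            silent_tfs = NULL,
                            n_per_group = c(sham = 7L, obs_10d = 7L,
                                            obs_6w = 6L, deobs = 6L),
                            mir_fold_10d = 5,
                            mir_fold_6w = NULL,
                            mir_fold_deobs = 1.2,
                            mir_sdlog = 0.15,
                            mir_b_scale = 0.4,
                            target_slopes = NULL,
                            noise_sd = 0.1,
                            n_nc_probes = 20L,
                            nc_mean = 6,
                            nc_sd = 0.5,
                            probes_per_tf = 2L) {
  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  if (is.null(active_tfs)) active_tfs <- tf_ids[seq_len(min(5L, n_tfs))]
  if (is.null(focal_tfs)) {
    # 8 focal TFs: 3 active plus 5 others, mirroring an 8-member Venn overlap
    # candidate list of which only some are truly active.
    focal_tfs <- unique(c(utils::head(active_tfs, 3L),
                          setdiff(tf_ids, active_tfs)[seq_len(
                            min(5L, n_tfs - length(active_tfs)))]))
  }
  if (is.null(silent_tfs)) {
    pool <- setdiff(tf_ids, active_tfs)
    silent_tfs <- unique(c(utils::head(setdiff(focal_tfs, active_tfs), 2L),
                           utils::head(setdiff(pool, focal_tfs), 8L)))
  }
  if (is.null(mir_fold_6w)) mir_fold_6w <- 0.6 * mir_fold_10d
  if (is.null(target_slopes)) {
    target_slopes <- c(Mecp2 = -0.08, Ep300 = -0.06, Pnkd = -0.05,
                       Jarid1a = -0.04, Sh3bp5 = 0, Ripk2 = 0, Foxo3 = 0,
                       Pten = 0, Rasa1 = 0)
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_de = as.integer(n_de), promoter_length = as.integer(promoter_length),
    gc_content = gc_content, n_tfs = as.integer(n_tfs),
    motif_length_range = as.integer(motif_length_range),
    tf_ids = tf_ids, active_tfs = active_tfs,
    plant_rate_de = plant_rate_de, plant_rate_bg = plant_rate_bg,
    focal_tfs = focal_tfs, silent_tfs = silent_tfs,
    n_per_group = n_per_group,
    mir_fold_10d = mir_fold_10d, mir_fold_6w = mir_fold_6w,
    mir_fold_deobs = mir_fold_deobs, mir_sdlog = mir_sdlog,
    mir_b_scale = mir_b_scale,
    target_slopes = target_slopes, noise_sd = noise_sd,
    n_nc_probes = as.integer(n_nc_probes), nc_mean = nc_mean, nc_sd = nc_sd,
    probes_per_tf = as.integer(probes_per_tf)
  ), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, msg) if (!cond) bad <<- c(bad, msg)
  chk(cfg$n_de >= 1L && cfg$n_de < cfg$n_genes, "n_de must satisfy 1 <= n_de < n_genes")
  chk(cfg$gc_content > 0 && cfg$gc_content < 1, "gc_content must be in (0, 1)")
  chk(cfg$plant_rate_de >= 0 && cfg$plant_rate_de <= 1, "plant_rate_de must be in [0, 1]")
  chk(cfg$plant_rate_bg >= 0 && cfg$plant_rate_bg <= 1, "plant_rate_bg must be in [0, 1]")
  chk(cfg$plant_rate_de >= cfg$plant_rate_bg, "plant_rate_de must be >= plant_rate_bg")
  chk(all(cfg$active_tfs %in% cfg$tf_ids), "active_tfs must be generated TF ids")
  chk(all(cfg$focal_tfs %in% cfg$tf_ids), "focal_tfs must be generated TF ids")
  chk(all(cfg$silent_tfs %in% cfg$tf_ids), "silent_tfs must be generated TF ids")
  chk(length(cfg$n_per_group) == 4L && all(cfg$n_per_group >= 1L) &&
        identical(names(cfg$n_per_group), c("sham", "obs_10d", "obs_6w", "deobs")),
      "n_per_group must name sham, obs_10d, obs_6w, deobs, all >= 1")
  chk(all(c(cfg$mir_fold_10d, cfg$mir_fold_6w, cfg$mir_fold_deobs) > 0),
      "miRNA group folds must be positive")
  chk(cfg$noise_sd >= 0 && cfg$mir_sdlog >= 0, "noise SDs must be non-negative")
  chk(cfg$motif_length_range[1] >= 4L &&
        cfg$motif_length_range[2] >= cfg$motif_length_range[1],
      "motif_length_range must be an increasing range with minimum >= 4")
  chk(cfg$promoter_length >= 2L * cfg$motif_length_range[2],
      "promoter_length too short for motif insertions")
  if (length(bad) > 0L) stop("invalid scenario config:\n  - ",
                             paste(bad, collapse = "\n  - "))
  invisible(cfg)
}

# Random i.i.d. DNA strings at the configured GC content; one draw for all
# `count` sequences of length `n`.
random_dna <- function(n, gc_content, count = 1L) {
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  raw_bases <- charToRaw("ACGT")
  draws <- raw_bases[sample.int(4L, n * count, replace = TRUE, prob = p)]
  if (count == 1L) return(rawToChar(draws))
  vapply(seq_len(count),
         function(i) rawToChar(draws[((i - 1L) * n + 1L):(i * n)]),
         character(1))
}

#' Generate random informative motifs
#'
#' Each motif has length drawn from `motif_length_range` and, per column, a
#' dominant base with weight >= 0.8 (counts out of 100); consensus strings
#' are guaranteed pairwise distinct.
#'
#' @param cfg A `scenario_config`. Draws from the current RNG stream; seed
#'   via [generate_scenario()] or `set.seed()` for reproducibility.
#' @return Named list of `pfm` objects, one per TF id.
#' @export
generate_motifs <- function(cfg) {
  seen <- character(0)
  out <- vector("list", cfg$n_tfs)
  for (i in seq_len(cfg$n_tfs)) {
    repeat {
      L <- sample(seq(cfg$motif_length_range[1], cfg$motif_length_range[2]),
                  1L)
      counts <- matrix(0, nrow = 4L, ncol = L,
                       dimnames = list(DNA_BASES, NULL))
      dom <- sample.int(4L, L, replace = TRUE)
      for (j in seq_len(L)) {
        dc <- sample(80:95, 1L)
        rest <- stats::rmultinom(1L, 100L - dc, rep(1 / 3, 3))
        counts[dom[j], j] <- dc
        counts[-dom[j], j] <- rest
      }
      cons <- paste(DNA_BASES[dom], collapse = "")
      if (!cons %in% seen) {
        seen <- c(seen, cons)
        out[[i]] <- pfm(cfg$tf_ids[i], counts)
        break
      }
    }
  }
  names(out) <- cfg$tf_ids
  out
}

# Insert `what` into `sequence` at a random start that does not overlap any
# interval in `occupied` (2-col matrix start,end half-open, 0-based).
# Returns list(sequence, start) or NULL if no slot found.
insert_nonoverlapping <- function(sequence, what, occupied, max_tries = 100L) {
  n <- nchar(sequence)
  L <- nchar(what)
  if (n < L) return(NULL)
  for (t in seq_len(max_tries)) {
    s <- sample.int(n - L + 1L, 1L) - 1L
    if (is.null(occupied) || nrow(occupied) == 0L ||
        all(s + L <= occupied[, 1] | s >= occupied[, 2])) {
      substr(sequence, s + 1L, s + L) <- what
      return(list(sequence = sequence, start = s))
    }
  }
  NULL
}

#' Generate promoter sequences with planted active-TF motifs
#'
#' Background promoters are i.i.d. nucleotides at the configured GC content.
#' For each active TF, its exact consensus (on a random strand) is inserted
#' at a uniform random non-overlapping position in a fraction
#' `plant_rate_de` of DE promoters and `plant_rate_bg` of the remaining
#' promoters. All insertions are recorded.
#'
#' @param cfg A `scenario_config`.
#' @param motifs Named list of `pfm` objects (from [generate_motifs()]).
#' @return List: `promoters` (named character), `de_genes`, `universe`,
#'   `planted` (data.frame tf_id, gene_id, start, strand).
#' @export
generate_promoters <- function(cfg, motifs) {
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  de_genes <- sort(sample(gene_ids, cfg$n_de))
  proms <- stats::setNames(
    random_dna(cfg$promoter_length, cfg$gc_content, count = cfg$n_genes),
    gene_ids)
  occupied <- stats::setNames(vector("list", cfg$n_genes), gene_ids)
  planted <- list()
  for (tf in cfg$active_tfs) {
    cons <- consensus(motifs[[tf]])
    if (nchar(cons) > cfg$promoter_length) {
      stop("promoter too short for consensus of ", tf)
    }
    is_de <- gene_ids %in% de_genes
    rate <- ifelse(is_de, cfg$plant_rate_de, cfg$plant_rate_bg)
    chosen <- gene_ids[stats::runif(cfg$n_genes) < rate]
    for (g in chosen) {
      strand <- sample(c("+", "-"), 1L)
      ins <- insert_nonoverlapping(
        proms[[g]], if (strand == "+") cons else revcomp(cons), occupied[[g]])
      if (is.null(ins)) next   # promoter saturated; skip this insertion
      proms[[g]] <- ins$sequence
      occupied[[g]] <- rbind(occupied[[g]],
                             c(ins$start, ins$start + nchar(cons)))
      planted[[length(planted) + 1L]] <-
        data.frame(tf_id = tf, gene_id = g, start = ins$start,
                   strand = strand, stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted) > 0L) do.call(rbind, planted) else
    data.frame(tf_id = character(0), gene_id = character(0),
               start = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  list(promoters = proms, de_genes = de_genes, universe = gene_ids,
       planted = planted)
}

#' Generate the focal promoter with one consensus site per focal TF
#'
#' @inheritParams generate_promoters
#' @return List: `sequence` (single string), `planted` (data.frame).
#' @export
generate_focal_promoter <- function(cfg, motifs) {
  seqn <- random_dna(cfg$promoter_length, cfg$gc_content)
  occupied <- NULL
  planted <- list()
  for (tf in cfg$focal_tfs) {
    cons <- consensus(motifs[[tf]])
    strand <- sample(c("+", "-"), 1L)
    ins <- insert_nonoverlapping(
      seqn, if (strand == "+") cons else revcomp(cons), occupied)
    if (is.null(ins)) {
      stop("focal promoter too short to place all focal TF sites")
    }
    seqn <- ins$sequence
    occupied <- rbind(occupied, c(ins$start, ins$start + nchar(cons)))
    planted[[length(planted) + 1L]] <-
      data.frame(tf_id = tf, gene_id = "focal_promoter", start = ins$start,
                 strand = strand, stringsAsFactors = FALSE)
  }
  list(sequence = seqn, planted = do.call(rbind, planted))
}

sample_ids <- function(cfg) {
  unlist(lapply(names(cfg$n_per_group), function(g) {
    sprintf("%s_%02d", g, seq_len(cfg$n_per_group[[g]]))
  }), use.names = FALSE)
}

sample_groups <- function(cfg) {
  rep(names(cfg$n_per_group), unname(cfg$n_per_group))
}

#' Generate an expression table with a negative-control floor
#'
#' Negative-control probes are drawn from a baseline normal; probes of
#' "silent" TFs come from the same distribution; probes of expressed TFs are
#' shifted at least 4 baseline SDs above it.
#'
#' @param cfg A `scenario_config`.
#' @return data.frame: `probe_id`, `gene_id`, `is_negative_control`, one
#'   column per sample.
#' @export
generate_expression <- function(cfg) {
  sids <- sample_ids(cfg)
  n_s <- length(sids)
  rows <- list()
  for (i in seq_len(cfg$n_nc_probes)) {
    rows[[length(rows) + 1L]] <- c(
      list(probe_id = sprintf("NC%03d", i), gene_id = NA_character_,
           is_negative_control = TRUE),
      as.list(stats::rnorm(n_s, cfg$nc_mean, cfg$nc_sd)))
  }
  for (tf in cfg$tf_ids) {
    silent <- tf %in% cfg$silent_tfs
    for (p in seq_len(cfg$probes_per_tf)) {
      mu <- if (silent) cfg$nc_mean else
        cfg$nc_mean + stats::runif(1L, 4, 8) * cfg$nc_sd
      rows[[length(rows) + 1L]] <- c(
        list(probe_id = sprintf("%s_p%d", tf, p), gene_id = tf,
             is_negative_control = FALSE),
        as.list(stats::rnorm(n_s, mu, cfg$nc_sd)))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, col.names = c(
      "probe_id", "gene_id", "is_negative_control", sids))
  }))
  names(out) <- c("probe_id", "gene_id", "is_negative_control", sids)
  out
}

#' Generate the four-group miRNA / target fold-change table
#'
#' Group mean miRNA folds: sham 1, obstructed 10 d `mir_fold_10d`,
#' obstructed 6 wk `mir_fold_6w`, de-obstructed `mir_fold_deobs`, with
#' log-normal per-sample noise; both miRNA columns are then normalized to a
#' sham mean of exactly 1. Each coupled target g is
#' `1 + slope_g * (composite - 2) + N(0, noise_sd)` (clamped at 0.01 to keep
#' fold changes positive); uncoupled targets are pure noise around 1.
#'
#' @param cfg A `scenario_config`.
#' @return data.frame: `sample_id`, `group`, `mir_a`, `mir_b`, one column
#'   per target gene.
#' @export
generate_mirna_target_table <- function(cfg) {
  sids <- sample_ids(cfg)
  grp <- sample_groups(cfg)
  fold <- c(sham = 1, obs_10d = cfg$mir_fold_10d, obs_6w = cfg$mir_fold_6w,
            deobs = cfg$mir_fold_deobs)[grp]
  n <- length(sids)
  mir_a <- fold * stats::rlnorm(n, 0, cfg$mir_sdlog)
  mir_b <- cfg$mir_b_scale * fold * stats::rlnorm(n, 0, cfg$mir_sdlog)
  sham <- grp == "sham"
  mir_a <- mir_a / mean(mir_a[sham])
  mir_b <- mir_b / mean(mir_b[sham])
  records <- data.frame(sample_id = sids, group = grp, mir_a = mir_a,
                        mir_b = mir_b, stringsAsFactors = FALSE)
  comp <- composite_score(records)
  for (g in names(cfg$target_slopes)) {
    y <- 1 + cfg$target_slopes[[g]] * (comp - 2) +
      stats::rnorm(n, 0, cfg$noise_sd)
    records[[g]] <- pmax(y, 0.01)
  }
  records
}

#' Generate a complete synthetic scenario
#'
#' Runs every generator under a single seed and assembles the ground-truth
#' record. If `dir` is given, writes the standard file set consumed by the
#' pipeline: `promoters.fasta`, `focal.fasta`, `motifs.jaspar`,
#' `de_genes.txt`, `universe.txt`, `expression.tsv`, `mirna_targets.tsv`,
#' `truth.json`.
#'
#' @param cfg A `scenario_config`.
#' @param dir Optional output directory (created if needed).
#' @return List of class `scenario`: `cfg`, `motifs` (pfm list),
#'   `promoters`, `de_genes`, `universe`, `focal_sequence`, `expression`,
#'   `mirna_targets`, `truth`.
#' @export
generate_scenario <- function(cfg, dir = NULL) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  motifs <- generate_motifs(cfg)
  prom <- generate_promoters(cfg, motifs)
  focal <- generate_focal_promoter(cfg, motifs)
  expr <- generate_expression(cfg)
  mirna <- generate_mirna_target_table(cfg)
  truth <- list(
    seed = cfg$seed,
    active_tfs = cfg$active_tfs,
    silent_tfs = cfg$silent_tfs,
    focal_tfs = cfg$focal_tfs,
    expected_candidates = sort(setdiff(
      intersect(cfg$active_tfs, cfg$focal_tfs), cfg$silent_tfs)),
    coupled_targets = as.list(
      cfg$target_slopes[cfg$target_slopes != 0]),
    uncoupled_targets = names(cfg$target_slopes)[cfg$target_slopes == 0],
    planted_positions = prom$planted,
    focal_planted = focal$planted,
    consensus = stats::setNames(
      vapply(motifs, consensus, character(1)), names(motifs))
  )
  scen <- structure(list(
    cfg = cfg, motifs = motifs, promoters = prom$promoters,
    de_genes = prom$de_genes, universe = prom$universe,
    focal_sequence = focal$sequence, expression = expr,
    mirna_targets = mirna, truth = truth
  ), class = "scenario")
  if (!is.null(dir)) write_scenario(scen, dir)
  scen
}

#' @rdname generate_scenario
#' @param scen A `scenario` object.
#' @export
write_scenario <- function(scen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(scen$promoters, file.path(dir, "promoters.fasta"))
  write_fasta(c(focal_promoter = scen$focal_sequence),
              file.path(dir, "focal.fasta"))
  write_jaspar(scen$motifs, file.path(dir, "motifs.jaspar"))
  write_gene_list(scen$de_genes, file.path(dir, "de_genes.txt"))
  write_gene_list(scen$universe, file.path(dir, "universe.txt"))
  write_expression(scen$expression, file.path(dir, "expression.tsv"))
  write_mirna_targets(scen$mirna_targets, file.path(dir, "mirna_targets.tsv"))
  jsonlite::write_json(scen$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
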