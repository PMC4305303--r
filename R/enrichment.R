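#' Construct a DE-gene / universe gene list
#'
#' @param de_genes Character vector of differentially expressed gene ids.
#' @param universe Character vector of all measured gene ids; must strictly
#'   contain `de_genes`.
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(de_genes, universe) {
  de_genes <- unique(as.character(de_genes))
  universe <- unique(as.character(universe))
  if (length(de_genes) < 1L) stop("de_genes must be non-empty")
  if (!all(de_genes %in% universe)) {
    stop("de_genes not in universe: ",
         paste(utils::head(setdiff(de_genes, universe), 5), collapse = ", "))
  }
  if (length(universe) <= length(de_genes)) {
    stop("universe must be strictly larger than the DE set")
  }
  structure(list(de_genes = de_genes, universe = universe),
            class = "gene_list")
}

check_matrix_genes <- function(hits, genes) {
  missing <- setdiff(genes$universe, colnames(hits))
  if (length(missing) > 0L) {
    stop("universe gene(s) missing from hit-count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
}

# Per-TF statistic over an arbitrary gene subset.
tf_statistic <- function(row_counts, gene_idx, statistic) {
  x <- row_counts[gene_idx]
  if (statistic == "total") sum(x) else sum(x > 0L)
}

#' Observed enrichment statistic for one TF
#'
#' The observed number of binding motifs in the DE-gene promoters: the total
#' hit count of the TF summed over the DE genes (default), or the number of
#' DE promoters carrying at least one hit (`statistic = "genes_with_hit"`).
#'
#' @param hits A `hit_count_matrix` (TFs x genes).
#' @param genes A `gene_list`.
#' @param tf_id TF row to use.
#' @param statistic `"total"` (default) or `"genes_with_hit"`.
#' @return Integer statistic value.
#' @export
observed_statistic <- function(hits, genes, tf_id,
                               statistic = c("total", "genes_with_hit")) {
  statistic <- match.arg(statistic)
  if (!tf_id %in% rownames(hits)) stop("unknown tf_id: ", tf_id)
  missing <- setdiff(genes$de_genes, colnames(hits))
  if (length(missing) > 0L) {
    stop("DE gene(s) missing from hit-count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  as.integer(tf_statistic(hits[tf_id, ], match(genes$de_genes, colnames(hits)),
                          statistic))
}

#' Resampling null distribution for one TF
#'
#' Each null sample recomputes the enrichment statistic over a uniform random
#' subset of the universe of size |DE set|, drawn without replacement.
#'
#' @inheritParams observed_statistic
#' @param n_resamples Number of null draws (>= 1).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return List of class `null_distribution` with fields `tf_id`, `samples`
#'   (integer vector of length `n_resamples`) and `seed`.
#' @export
resample_null <- function(hits, genes, tf_id, n_resamples = 10000L,
                          seed = 1L,
                          statistic = c("total", "genes_with_hit")) {
  statistic <- match.arg(statistic)
  stopifnot(n_resamples >= 1L)
  if (!tf_id %in% rownames(hits)) stop("unknown tf_id: ", tf_id)
  check_matrix_genes(hits, genes)
  uni_idx <- match(genes$universe, colnames(hits))
  k <- length(genes$de_genes)
  row_counts <- hits[tf_id, ]
  samples <- integer(n_resamples)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (i in seq_len(n_resamples)) {
    sub <- uni_idx[sample.int(length(uni_idx), k)]
    samples[i] <- tf_statistic(row_counts, sub, statistic)
  }
  structure(list(tf_id = tf_id, samples = samples, seed = seed),
            class = "null_distribution")
}

#' Empirical p-value with the +1 correction
#'
#' `p = (1 + #{null samples >= observed}) / (1 + N)`, one-sided in the
#' enrichment direction; never zero.
#'
#' @param observed Observed statistic value.
#' @param null A `null_distribution` (or bare integer vector of null samples).
#' @return The empirical p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  samples <- if (inherits(null, "null_distribution")) null$samples else null
  if (length(samples) == 0L) stop("null distribution is empty")
  (1 + sum(samples >= observed)) / (1 + length(samples))
}

#' Exact permutation p-value by subset enumeration
#'
#' Enumerates every size-k subset of the universe and computes the fraction
#' whose statistic is at least the observed one. Used as a brute-force oracle
#' for the resampling test on small universes.
#'
#' @inheritParams observed_statistic
#' @param max_subsets Refuse when `choose(n, k)` exceeds this (default 1e6).
#' @return List with `p_exact`, `observed`, `n_subsets`.
#' @export
exact_null_enumeration <- function(hits, genes, tf_id,
                                   statistic = c("total", "genes_with_hit"),
                                   max_subsets = 1e6) {
  statistic <- match.arg(statistic)
  check_matrix_genes(hits, genes)
  n <- length(genes$universe)
  k <- length(genes$de_genes)
  n_subsets <- choose(n, k)
  if (n_subsets > max_subsets) {
    stop("refusing exact enumeration: choose(", n, ", ", k, ") = ",
         format(n_subsets, big.mark = ","), " subsets exceeds max_subsets")
  }
  obs <- observed_statistic(hits, genes, tf_id, statistic)
  row_counts <- hits[tf_id, ]
  uni_idx <- match(genes$universe, colnames(hits))
  subsets <- utils::combn(uni_idx, k)
  stats <- apply(subsets, 2L, function(sub) {
    tf_statistic(row_counts, sub, statistic)
  })
  list(p_exact = sum(stats >= obs) / n_subsets, observed = obs,
       n_subsets = n_subsets)
}

#' Rank TFs and assign significance tiers
#'
#' Sorts ascending by empirical p; ties broken by descending z-score
#' `(observed - null_mean) / null_sd`, then lexically by tf_id. Tiers:
#' `stringent_0.01` (p < 0.01), `significant_0.05` (p < 0.05), else `ns`.
#'
#' @param results data.frame with columns `tf_id`, `observed`, `null_mean`,
#'   `null_sd`, `p_empirical`.
#' @return The same data.frame sorted, with `rank` and `tier` columns added.
#' @export
rank_tfs <- function(results) {
  stopifnot(all(c("tf_id", "observed", "null_mean", "null_sd", "p_empirical")
                %in% names(results)))
  z <- (results$observed - results$null_mean) / results$null_sd
  z[results$null_sd == 0] <- sign(results$observed -
                                    results$null_mean)[results$null_sd == 0] * Inf
  z[is.nan(z)] <- 0
  ord <- order(results$p_empirical, -z, results$tf_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tier <- ifelse(out$p_empirical < 0.01, "stringent_0.01",
                     ifelse(out$p_empirical < 0.05, "significant_0.05", "ns"))
  rownames(out) <- NULL
  out
}

#' Resampling enrichment test over all TFs
#'
#' Runs the full resampling-and-ranking procedure: for every TF, the observed
#' motif-hit statistic in the DE promoters is compared to its distribution
#' over `n_resamples` random gene sets of the same size drawn from the
#' universe. The same resampled gene sets are shared across TFs, which keeps
#' the run reproducible and fast without changing any TF's marginal null.
#'
#' @inheritParams resample_null
#' @return data.frame with one row per TF: `tf_id`, `observed`, `null_mean`,
#'   `null_sd`, `p_empirical`, `rank`, `tier`, and a supplementary
#'   Benjamini-Hochberg `bh_q` column (not part of the headline tiers).
#' @export
enrich_tfs <- function(hits, genes, n_resamples = 10000L, seed = 1L,
                       statistic = c("total", "genes_with_hit")) {
  statistic <- match.arg(statistic)
  stopifnot(n_resamples >= 1L)
  check_matrix_genes(hits, genes)
  counts <- unclass(hits)[, genes$universe, drop = FALSE]
  if (statistic == "genes_with_hit") counts <- (counts > 0L) * 1L
  k <- length(genes$de_genes)
  n_uni <- ncol(counts)
  observed <- as.integer(rowSums(counts[, genes$de_genes, drop = FALSE]))

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # Null statistics for all TFs at once: counts %*% subset-indicator matrix,
  # in chunks to bound memory.
  n_tf <- nrow(counts)
  null_mean <- numeric(n_tf)
  null_m2 <- numeric(n_tf)
  n_ge <- integer(n_tf)
  done <- 0L
  chunk <- 2000L
  while (done < n_resamples) {
    m <- min(chunk, n_resamples - done)
    ind <- matrix(0, nrow = n_uni, ncol = m)
    for (j in seq_len(m)) ind[sample.int(n_uni, k), j] <- 1
    stats <- counts %*% ind            # TFs x m
    n_ge <- n_ge + rowSums(stats >= observed)
    null_mean <- null_mean + rowSums(stats)
    null_m2 <- null_m2 + rowSums(stats^2)
    done <- done + m
  }
  mu <- null_mean / n_resamples
  sdv <- sqrt(pmax(0, null_m2 / n_resamples - mu^2) *
                n_resamples / max(1, n_resamples - 1))
  res <- data.frame(
    tf_id = rownames(counts),
    observed = observed,
    null_mean = mu,
    null_sd = sdv,
    p_empirical = (1 + n_ge) / (1 + n_resamples),
    stringsAsFactors = FALSE
  )
  res <- rank_tfs(res)
  res$bh_q <- stats::p.adjust(res$p_empirical, method = "BH")
  res
}

#' Write an enrichment table as TSV
#' @param results Output of [enrich_tfs()].
#' @param path Output path.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(format_num_df(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
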