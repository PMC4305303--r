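#' TFs with predicted binding sites in a focal promoter
#'
#' Scans a single promoter sequence (e.g. the promoter of the miRNA cluster
#' under study) with every motif and returns the ids of TFs with at least one
#' above-threshold hit.
#'
#' @param motifs List of `pwm` (or `pfm`) objects.
#' @param focal_sequence A single non-empty DNA string.
#' @param rel_threshold Relative score threshold in \[0, 1\].
#' @return Character vector of TF ids.
#' @export
focal_promoter_tfs <- function(motifs, focal_sequence, rel_threshold = 0.8) {
  if (!nzchar(focal_sequence)) stop("focal sequence is empty")
  counts <- count_hits(motifs, c(focal = focal_sequence), rel_threshold)
  rownames(counts)[counts[, 1] > 0L]
}

#' Venn cross-reference of enriched and focal-promoter TF sets
#'
#' @param enriched Character vector: TFs significantly enriched in DE-gene
#'   promoters.
#' @param focal Character vector: TFs with sites in the focal promoter.
#' @return List of class `crossref_result` with disjoint sets
#'   `enriched_only`, `both`, `focal_only`.
#' @export
venn_crossref <- function(enriched, focal) {
  enriched <- unique(as.character(enriched))
  focal <- unique(as.character(focal))
  structure(list(
    enriched_only = sort(setdiff(enriched, focal)),
    both = sort(intersect(enriched, focal)),
    focal_only = sort(setdiff(focal, enriched))
  ), class = "crossref_result")
}

#' @export
print.crossref_result <- function(x, ...) {
  cat("<crossref_result> enriched-only:", length(x$enriched_only),
      " | both:", length(x$both),
      " | focal-only:", length(x$focal_only), "\n")
  invisible(x)
}

# Pooled negative-control floor: mean + k_sd * sd over all negative-control
# probe/sample values.
nc_floor <- function(expr, k_sd) {
  vals <- as.matrix(expr[expr$is_negative_control,
                         expr_value_cols(expr), drop = FALSE])
  if (nrow(vals) < 2L) {
    stop("expression table must contain at least 2 negative-control probes")
  }
  mean(vals) + k_sd * stats::sd(as.vector(vals))
}

expr_value_cols <- function(expr) {
  setdiff(names(expr), c("probe_id", "gene_id", "is_negative_control"))
}

#' Remove TFs whose expression equals the negative-control floor
#'
#' A TF passes the filter iff the mean expression of its best (highest-mean)
#' probe across all samples strictly exceeds
#' `mean(negative controls) + k_sd * sd(negative controls)` (pooled over all
#' negative-control probe/sample values). TFs with no probe in the table are
#' removed and flagged `unmeasured` rather than silently dropped.
#'
#' @param candidates Character vector of TF/gene ids to triage.
#' @param expr Expression table: data.frame with columns `probe_id`,
#'   `gene_id`, `is_negative_control` (logical) and one numeric column per
#'   sample.
#' @param k_sd Number of negative-control standard deviations above the
#'   negative-control mean defining the detection floor (default 2).
#' @return data.frame with one row per candidate: `tf_id`, `expression_mean`
#'   (best-probe mean; NA if unmeasured), `floor`, `status` in
#'   `pass` / `removed` / `unmeasured`.
#' @export
expression_filter <- function(candidates, expr, k_sd = 2) {
  stopifnot(is.data.frame(expr),
            all(c("probe_id", "gene_id", "is_negative_control") %in%
                  names(expr)))
  floor_val <- nc_floor(expr, k_sd)
  vcols <- expr_value_cols(expr)
  meas <- expr[!expr$is_negative_control, , drop = FALSE]
  probe_means <- rowMeans(as.matrix(meas[, vcols, drop = FALSE]))
  best <- tapply(probe_means, meas$gene_id, max)
  expression_mean <- unname(best[candidates])
  status <- ifelse(is.na(expression_mean), "unmeasured",
                   ifelse(expression_mean > floor_val, "pass", "removed"))
  data.frame(tf_id = candidates,
             expression_mean = expression_mean,
             floor = floor_val,
             status = status,
             stringsAsFactors = FALSE)
}

#' Full candidate triage: Venn cross-reference plus expression filter
#'
#' Intersects the enrichment-significant TF set with the focal-promoter TF
#' set, then keeps only intersection members whose expression clears the
#' negative-control floor. Final candidates are ordered by enrichment
#' p-value.
#'
#' @param enrichment Output of [enrich_tfs()].
#' @param focal Character vector of focal-promoter TF ids
#'   (from [focal_promoter_tfs()]).
#' @param expr Expression table (see [expression_filter()]).
#' @param alpha Enrichment significance level defining the "enriched" circle
#'   (default 0.05, raw p).
#' @param k_sd Expression-floor multiplier (default 2).
#' @return List of class `crossref_result` with the Venn sets plus
#'   `expressed_pass`, `final_candidates` (ordered TF ids), and a `table`
#'   data.frame (tf_id, venn_class, expression columns, enrichment p, tier).
#' @export
crossref_candidates <- function(enrichment, focal, expr, alpha = 0.05,
                                k_sd = 2) {
  enriched <- enrichment$tf_id[enrichment$p_empirical < alpha]
  venn <- venn_crossref(enriched, focal)
  filt <- expression_filter(venn$both, expr, k_sd = k_sd)
  pass <- filt$tf_id[filt$status == "pass"]
  p_of <- stats::setNames(enrichment$p_empirical, enrichment$tf_id)
  tier_of <- stats::setNames(enrichment$tier, enrichment$tf_id)
  final <- pass[order(p_of[pass], pass)]
  all_ids <- c(venn$enriched_only, venn$both, venn$focal_only)
  venn_class <- rep(c("enriched_only", "both", "focal_only"),
                    c(length(venn$enriched_only), length(venn$both),
                      length(venn$focal_only)))
  tab <- data.frame(tf_id = all_ids, venn_class = venn_class,
                    stringsAsFactors = FALSE)
  tab <- merge(tab, filt, by = "tf_id", all.x = TRUE, sort = FALSE)
  tab$enrichment_p <- unname(p_of[tab$tf_id])
  tab$tier <- unname(tier_of[tab$tf_id])
  tab <- tab[order(match(tab$venn_class,
                         c("both", "enriched_only", "focal_only")),
                   tab$enrichment_p, tab$tf_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(c(venn,
              list(expressed_pass = pass, final_candidates = final,
                   table = tab)),
            class = "crossref_result")
}

#' Read / write an expression table TSV
#'
#' Columns: `probe_id`, `gene_id`, `is_negative_control` (TRUE/FALSE), then
#' one numeric column per sample.
#'
#' @param expr Expression table data.frame.
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(format_num_df(expr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_negative_control <- as.logical(df$is_negative_control)
  df
}
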