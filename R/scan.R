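# Integer coding for the C++ scanner: A=0, C=1, G=2, T=3, anything else -1.
encode_sequence <- function(sequence) {
  codes <- match(strsplit(toupper(sequence), "")[[1]], DNA_BASES) - 1L
  codes[is.na(codes)] <- -1L
  codes
}

# Absolute score threshold for a relative threshold in [0, 1]; capped at
# max_score so that a perfect-consensus window always qualifies at
# rel_threshold = 1 despite floating-point rounding.
abs_threshold <- function(pwm, rel_threshold) {
  min(pwm$min_score + rel_threshold * (pwm$max_score - pwm$min_score),
      pwm$max_score)
}

#' Scan one sequence for motif hits on both strands
#'
#' Scores every length-L window on the forward strand, and on the reverse
#' strand via the reverse-complemented weight matrix, keeping windows with
#' score at or above `min_score + rel_threshold * (max_score - min_score)`.
#' Windows containing any non-ACGT character (e.g. N) are skipped.
#'
#' @param pwm A `pwm` object (see [pwm_from_counts()]).
#' @param sequence A single DNA string.
#' @param rel_threshold Relative score threshold in \[0, 1\] (default 0.8).
#' @param gene_id Optional gene id recorded in the output.
#' @return A data.frame with columns `tf_id`, `gene_id`, `start` (0-based),
#'   `end` (half-open), `strand` (`+`/`-`), `score` (bits), sorted by start
#'   then strand. Sequences shorter than the motif yield zero rows.
#' @export
scan_sequence <- function(pwm, sequence, rel_threshold = 0.8,
                          gene_id = NA_character_) {
  stopifnot(inherits(pwm, "pwm"), is.character(sequence),
            length(sequence) == 1L)
  if (rel_threshold < 0 || rel_threshold > 1) {
    stop("rel_threshold must lie in [0, 1]")
  }
  codes <- encode_sequence(sequence)
  thr <- abs_threshold(pwm, rel_threshold)
  fwd <- scan_codes_cpp(codes, pwm$log_odds, thr)
  rev <- scan_codes_cpp(codes, revcomp_log_odds(pwm$log_odds), thr)
  L <- ncol(pwm$log_odds)
  n_hits <- nrow(fwd) + nrow(rev)
  hits <- data.frame(
    tf_id = rep(pwm$tf_id, n_hits),
    gene_id = rep(gene_id, n_hits),
    start = as.integer(c(fwd[, 1], rev[, 1])),
    strand = rep(c("+", "-"), c(nrow(fwd), nrow(rev))),
    score = c(fwd[, 2], rev[, 2]),
    stringsAsFactors = FALSE
  )
  hits$end <- hits$start + L
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("tf_id", "gene_id", "start", "end", "strand", "score")]
}

#' Count motif hits for every TF in every promoter
#'
#' @param motifs A list of `pwm` objects (or `pfm` objects, converted with
#'   default PWM parameters).
#' @param promoters Named character vector of promoter sequences
#'   (gene id -> sequence).
#' @param rel_threshold Relative score threshold in \[0, 1\].
#' @return An integer matrix, TFs x genes, of above-threshold window counts
#'   (both strands; overlapping hits all counted). Class `hit_count_matrix`.
#' @export
count_hits <- function(motifs, promoters, rel_threshold = 0.8) {
  if (length(promoters) == 0L) stop("promoter set is empty")
  if (is.null(names(promoters)) || anyDuplicated(names(promoters))) {
    stop("promoters must be uniquely named by gene id")
  }
  motifs <- lapply(motifs, function(m) {
    if (inherits(m, "pfm")) pwm_from_counts(m) else m
  })
  code_list <- lapply(unname(promoters), encode_sequence)
  counts <- matrix(0L, nrow = length(motifs), ncol = length(promoters),
                   dimnames = list(vapply(motifs, `[[`, "", "tf_id"),
                                   names(promoters)))
  if (anyDuplicated(rownames(counts))) stop("duplicate tf_id in motif set")
  for (i in seq_along(motifs)) {
    lo <- motifs[[i]]$log_odds
    counts[i, ] <- count_codes_list_cpp(code_list, lo, revcomp_log_odds(lo),
                                        abs_threshold(motifs[[i]],
                                                      rel_threshold))
  }
  class(counts) <- c("hit_count_matrix", class(counts))
  counts
}

#' Full hit table for a promoter set
#'
#' Like [count_hits()] but returns every individual hit.
#'
#' @inheritParams count_hits
#' @return data.frame of hits (see [scan_sequence()]) over all TFs and genes.
#' @export
scan_promoters <- function(motifs, promoters, rel_threshold = 0.8) {
  motifs <- lapply(motifs, function(m) {
    if (inherits(m, "pfm")) pwm_from_counts(m) else m
  })
  out <- vector("list", length(motifs) * length(promoters))
  k <- 0L
  for (m in motifs) {
    for (g in names(promoters)) {
      k <- k + 1L
      out[[k]] <- scan_sequence(m, promoters[[g]], rel_threshold, gene_id = g)
    }
  }
  do.call(rbind, out)
}

#' Write a per-hit table as TSV (tf_id, gene_id, start, end, strand, score)
#' @param hits data.frame of hits from [scan_sequence()] or
#'   [scan_promoters()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(format_num_df(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a hit-count matrix as TSV (rows = TFs, columns = genes)
#' @param counts A `hit_count_matrix`.
#' @param path Output path.
#' @export
write_hit_counts <- function(counts, path) {
  df <- data.frame(tf_id = rownames(counts),
                   unclass(counts)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_counts
#' @export
read_hit_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  class(m) <- c("hit_count_matrix", class(m))
  m
}
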