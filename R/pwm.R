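#' @keywords internal
"_PACKAGE"

#' @useDynLib tfbscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Nucleotide alphabet used throughout (fixed order)
#' @export
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix (PFM)
#'
#' @param tf_id Motif identifier.
#' @param counts Numeric 4 x L matrix of per-position base counts, rows in
#'   A, C, G, T order. L must be at least 4, all counts non-negative, and
#'   every column must have at least one positive count.
#' @param name Optional display name (defaults to `tf_id`).
#' @return An object of class `pfm`.
#' @export
pfm <- function(tf_id, counts, name = tf_id) {
  stopifnot(is.character(tf_id), length(tf_id) == 1L, nzchar(tf_id))
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM '", tf_id, "': counts must have 4 rows")
  if (ncol(counts) < 4L) {
    stop("PFM '", tf_id, "': motif length must be >= 4 (got ",
         ncol(counts), ")")
  }
  if (any(counts < 0)) stop("PFM '", tf_id, "': negative count")
  if (any(colSums(counts) <= 0)) {
    stop("PFM '", tf_id, "': column with all-zero counts")
  }
  rownames(counts) <- DNA_BASES
  structure(list(tf_id = tf_id, name = name, counts = counts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> ", x$tf_id, " (", x$name, "), length ", ncol(x$counts),
      ", consensus ", consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus string of a motif (highest-count base per column)
#' @param x A `pfm` or `pwm` object.
#' @return A character scalar over A/C/G/T.
#' @export
consensus <- function(x) {
  m <- if (inherits(x, "pfm")) x$counts else x$log_odds
  paste(DNA_BASES[apply(m, 2L, which.max)], collapse = "")
}

#' Build a log-odds position weight matrix from a PFM
#'
#' Each cell is
#' `log2( (counts[b,j] + pseudocount) / (colsum[j] + 4*pseudocount) / background[b] )`,
#' i.e. the log2 ratio of the smoothed position-specific base probability to
#' the background probability.
#'
#' @param x A `pfm` object.
#' @param pseudocount Non-negative smoothing constant added to every cell
#'   (default 0.25).
#' @param background Strictly positive base-probability 4-vector summing to 1
#'   (default uniform).
#' @return An object of class `pwm` with fields `tf_id`, `log_odds` (4 x L,
#'   bits), `background`, `pseudocount`, `max_score`, `min_score`, and the
#'   consensus string.
#' @export
pwm_from_counts <- function(x, pseudocount = 0.25,
                            background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pfm"))
  if (length(pseudocount) != 1L || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 4 strictly positive probabilities summing to 1")
  }
  cs <- colSums(x$counts)
  if (pseudocount == 0 && any(x$counts == 0)) {
    stop("PWM '", x$tf_id,
         "': zero count with pseudocount 0 gives -Inf log-odds; ",
         "use a positive pseudocount")
  }
  prob <- sweep(x$counts + pseudocount, 2L, cs + 4 * pseudocount, "/")
  lo <- log2(prob / background)
  rownames(lo) <- DNA_BASES
  structure(list(
    tf_id = x$tf_id,
    name = x$name,
    log_odds = lo,
    background = background,
    pseudocount = pseudocount,
    max_score = sum(apply(lo, 2L, max)),
    min_score = sum(apply(lo, 2L, min)),
    consensus = consensus(x)
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$tf_id, ", length ", ncol(x$log_odds),
      sprintf(", score range [%.2f, %.2f] bits", x$min_score, x$max_score),
      ", consensus ", x$consensus, "\n", sep = "")
  invisible(x)
}

# Log-odds matrix for the reverse strand: complement rows, reverse columns.
# A hit of the motif on the minus strand at [start, start+L) of the forward
# sequence is exactly a plus-strand match of this matrix there.
revcomp_log_odds <- function(lo) {
  lo[4:1, ncol(lo):1, drop = FALSE]
}

#' Reverse complement of a DNA string (keeps N)
#' @param x Character vector of sequences over A/C/G/T/N.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
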