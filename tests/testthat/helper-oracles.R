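# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (no shared code paths with the package internals
# beyond the public PWM fields).

# Reverse complement without Biostrings.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

# Score one window of a character vector against a 4 x L log-odds matrix;
# NA if the window contains a non-ACGT character.
oracle_window_score <- function(chars, lo) {
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(lo[cbind(idx, seq_along(idx))])
}

# Naive double-loop scanner: scores every window on the forward sequence and
# on the reverse-complemented sequence, maps minus-strand coordinates back,
# and keeps windows with score >= min + rel * (max - min).
naive_scan <- function(pwm, sequence, rel_threshold) {
  lo <- pwm$log_odds
  L <- ncol(lo)
  thr <- min(pwm$min_score + rel_threshold * (pwm$max_score - pwm$min_score),
             pwm$max_score)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(sequence) else oracle_revcomp(sequence)
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    if (n < L) next
    for (i in 0:(n - L)) {
      sc <- oracle_window_score(chars[(i + 1):(i + L)], lo)
      if (!is.na(sc) && sc >= thr) {
        start <- if (strand == "+") i else n - i - L
        hits[[length(hits) + 1L]] <- data.frame(
          tf_id = pwm$tf_id, start = start, end = start + L,
          strand = strand, score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(tf_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Closed-form simple linear regression of y on x with the two-sided t test
# of slope = 0 on n - 2 df.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  se <- sqrt(sse / (n - 2) / sxx)
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = slope, intercept = intercept, r2 = r2, p = p)
}

# Small deterministic helpers used across test files.
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_pfm <- function(tf_id, consensus, dom = 85) {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  counts <- matrix(5, nrow = 4, ncol = length(idx))
  counts[cbind(idx, seq_along(idx))] <- dom
  pfm(tf_id, counts)
}
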