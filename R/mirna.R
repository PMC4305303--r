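#' Composite score from two same-seed miRNAs
#'
#' Each miRNA's fold changes are divided by their mean over the sham group,
#' then the two normalized values are summed per sample, so the sham-group
#' mean of the composite is exactly 2. Because the two miRNAs share a seed
#' sequence (hence targets), their normalized sum is used as a single
#' predictor of target repression.
#'
#' @param records data.frame with columns `sample_id`, `group` (one level
#'   must be `sham`), `mir_a`, `mir_b` (positive fold changes).
#' @return Numeric vector of composite scores, one per row of `records`.
#' @export
composite_score <- function(records) {
  stopifnot(all(c("group", "mir_a", "mir_b") %in% names(records)))
  sham <- records$group == "sham"
  if (!any(sham)) stop("no sham samples; cannot normalize")
  if (any(records$mir_a <= 0) || any(records$mir_b <= 0)) {
    stop("miRNA fold changes must be positive")
  }
  ma <- mean(records$mir_a[sham])
  mb <- mean(records$mir_b[sham])
  if (ma == 0 || mb == 0) stop("sham mean of a miRNA is zero")
  records$mir_a / ma + records$mir_b / mb
}

#' Regress one target's fold change on the composite miRNA score
#'
#' Ordinary least squares of `target_fc` on `composite`; the p-value is the
#' two-sided t test of slope = 0 on n - 2 degrees of freedom.
#'
#' @param composite Numeric predictor (composite miRNA score per sample).
#' @param target_fc Numeric response (target mRNA fold change per sample).
#' @param gene_id Optional gene id recorded in the result.
#' @return One-row data.frame: `gene_id`, `slope`, `intercept`, `r2`, `p`,
#'   `n`, `direction` (`inverse` / `positive` / `none`), `significant`
#'   (p < 0.05).
#' @export
regress_target <- function(composite, target_fc, gene_id = NA_character_) {
  if (length(composite) != length(target_fc)) {
    stop("composite and target_fc lengths differ")
  }
  if (anyNA(composite) || anyNA(target_fc)) stop("missing values not allowed")
  n <- length(composite)
  if (n < 3L) stop("need at least 3 samples for the regression")
  if (stats::var(composite) == 0) {
    stop("degenerate design: composite score has zero variance")
  }
  if (stats::var(target_fc) == 0) {
    # flat response: no fit to test
    return(data.frame(gene_id = gene_id, slope = 0,
                      intercept = target_fc[1], r2 = 0, p = 1, n = n,
                      direction = "none", significant = FALSE,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(target_fc ~ composite)
  # summary.lm warns on numerically perfect fits; those are legitimate here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  co <- sm$coefficients
  p <- if (nrow(co) >= 2L && !is.nan(co[2L, 4L])) co[2L, 4L] else 0
  # A numerically perfect fit can yield p = 0 / NaN; clamp into (0, 1].
  p <- min(max(p, .Machine$double.xmin), 1)
  r2 <- sm$r.squared
  direction <- if (p < 0.05 && slope < 0) "inverse"
               else if (p < 0.05 && slope > 0) "positive" else "none"
  data.frame(gene_id = gene_id,
             slope = slope,
             intercept = unname(stats::coef(fit)[1L]),
             r2 = r2,
             p = p,
             n = n,
             direction = direction,
             significant = p < 0.05,
             stringsAsFactors = FALSE)
}

#' Screen a panel of candidate targets against the composite miRNA score
#'
#' Builds the composite score once from `records`, regresses every panel
#' gene's fold change on it, flags whether the fitted direction matches the
#' expected one, and sorts by p-value. A Benjamini-Hochberg `bh_q` column is
#' added as a supplementary annotation; the `significant` flag uses the raw
#' per-target p < 0.05 rule.
#'
#' @param records data.frame with columns `sample_id`, `group`, `mir_a`,
#'   `mir_b` and one numeric column per target gene.
#' @param target_panel data.frame with columns `gene_id` and
#'   `expected_direction` (`inverse` / `positive` / `none`), or a character
#'   vector of gene ids (expected direction then defaults to `inverse`).
#' @param scale `"linear"` (default) regresses raw fold changes; `"log2"`
#'   regresses log2 fold changes on the composite.
#' @return data.frame of per-target regression results with `concordant` and
#'   `bh_q` columns, sorted by `p`.
#' @export
screen_targets <- function(records, target_panel, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.character(target_panel)) {
    target_panel <- data.frame(gene_id = target_panel,
                               expected_direction = "inverse",
                               stringsAsFactors = FALSE)
  }
  missing <- setdiff(target_panel$gene_id, names(records))
  if (length(missing) > 0L) {
    stop("target gene(s) missing from records: ",
         paste(missing, collapse = ", "))
  }
  comp <- composite_score(records)
  rows <- lapply(seq_len(nrow(target_panel)), function(i) {
    g <- target_panel$gene_id[i]
    y <- records[[g]]
    if (scale == "log2") y <- log2(y)
    res <- regress_target(comp, y, gene_id = g)
    res$concordant <- res$direction == target_panel$expected_direction[i]
    res
  })
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write the per-sample miRNA/target table
#'
#' TSV with columns `sample_id`, `group`, `mir_a`, `mir_b`, then one numeric
#' column per target gene (all fold changes vs the sham mean).
#'
#' @param records data.frame of sample records.
#' @param path File path.
#' @export
write_mirna_targets <- function(records, path) {
  utils::write.table(format_num_df(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mirna_targets
#' @export
read_mirna_targets <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
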