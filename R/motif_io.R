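#' Read transcription factor motifs from a JASPAR-style PFM file
#'
#' Parses the plain-text JASPAR format: each record is a `>ID NAME` header
#' followed by four rows `A [ counts... ]`, `C [...]`, `G [...]`, `T [...]`.
#' Brackets are optional; rows must appear in A, C, G, T order.
#'
#' @param path Path to the motif file.
#' @return A named list of `pfm` objects (see [pfm()]); names are the motif
#'   IDs. An empty file yields an empty list with a warning.
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) {
    stop("motif file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("motif file is empty: ", path)
    return(structure(list(), names = character(0)))
  }
  headers <- grep("^>", lines)
  if (length(headers) == 0L || headers[1] != 1L) {
    stop("not a JASPAR PFM file (no '>' header on first line): ", path)
  }
  bounds <- c(headers, length(lines) + 1L)
  out <- vector("list", length(headers))
  ids <- character(length(headers))
  for (k in seq_along(headers)) {
    block <- lines[headers[k]:(bounds[k + 1L] - 1L)]
    header <- sub("^>\\s*", "", block[1])
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1L) paste(toks[-1], collapse = " ") else id
    body <- block[-1]
    if (length(body) != 4L) {
      stop("record '", id, "': expected 4 count rows, found ", length(body))
    }
    counts <- matrix(NA_real_, nrow = 4L, ncol = 0L,
                     dimnames = list(DNA_BASES, NULL))
    rows <- lapply(seq_len(4L), function(i) {
      row <- body[i]
      base <- sub("^\\s*([ACGTacgt]).*$", "\\1", row)
      if (!toupper(base) %in% DNA_BASES || toupper(base) != DNA_BASES[i]) {
        stop("record '", id, "': count rows must be labelled A, C, G, T ",
             "in order; got '", row, "'")
      }
      nums <- sub("^\\s*[ACGTacgt]\\s*", "", row)
      nums <- gsub("\\[|\\]", " ", nums)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) {
        stop("record '", id, "': unparseable counts in row '", row, "'")
      }
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop("record '", id, "': count rows have unequal lengths")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- DNA_BASES
    if (any(counts < 0)) {
      stop("record '", id, "': negative count")
    }
    out[[k]] <- pfm(id, counts, name = name)
    ids[k] <- id
  }
  if (anyDuplicated(ids)) {
    stop("duplicate motif id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(out) <- ids
  out
}

#' Write motifs to a JASPAR-style PFM file
#'
#' @param motifs A list of `pfm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$tf_id, m$name), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read promoter sequences from a FASTA file
#'
#' Record ids are taken as gene ids (first whitespace-delimited token of the
#' header). Sequences are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (a promoter set).
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate gene id(s) in FASTA: ", path)
  }
  if (any(nchar(seqs) < 1L)) stop("empty sequence in FASTA: ", path)
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Read a gene list (one id per line)
#' @param path Path to a text file, one gene id per line.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param ids Character vector of gene ids to write.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
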