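# CDS-annotated DNA sequence: the optimizer's immutable reference input.

#' Construct a CDS-annotated DNA sequence
#'
#' The reference object the optimizer redesigns: a DNA string plus the
#' coordinates of its protein-coding regions. Coordinates are 0-based,
#' half-open throughout the package; GenBank 1-based inclusive coordinates
#' are converted at the I/O boundary by [read_genbank()].
#'
#' @param seq A DNA string over A, C, G, T (ambiguity codes are rejected).
#' @param cds A data frame with columns `start` (0-based inclusive),
#'   `end` (exclusive) and `strand` (`"+"` or `"-"`). CDS intervals must be
#'   disjoint, lie within the sequence and have lengths that are multiples
#'   of 3. May have zero rows for a construct without annotated genes.
#' @return An `annotated_sequence` object.
#' @examples
#' annotated_sequence("ATGAAATAAGGGCCC",
#'   cds = data.frame(start = 0, end = 9, strand = "+")
#' )
#' @export
annotated_sequence <- function(seq, cds = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bases <- .seq_chars(seq)
  .check_alphabet(bases)
  if (is.null(cds)) {
    cds <- tibble(start = integer(), end = integer(), strand = character())
  }
  cds <- as_tibble(cds)
  stopifnot(all(c("start", "end", "strand") %in% names(cds)))
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  cds$strand <- as.character(cds$strand)
  if (nrow(cds) > 0L) {
    cds <- cds[order(cds$start), , drop = FALSE]
    if (any(cds$start < 0L) || any(cds$end > length(bases))) {
      stop("CDS interval outside the sequence", call. = FALSE)
    }
    len <- cds$end - cds$start
    if (any(len <= 0L) || any(len %% 3L != 0L)) {
      stop("every CDS length must be a positive multiple of 3", call. = FALSE)
    }
    if (!all(cds$strand %in% c("+", "-"))) {
      stop("CDS strand must be '+' or '-'", call. = FALSE)
    }
    if (nrow(cds) > 1L && any(cds$start[-1L] < cds$end[-nrow(cds)])) {
      stop("CDS intervals must be pairwise non-overlapping", call. = FALSE)
    }
  }
  structure(
    list(seq = seq, cds = cds),
    class = "annotated_sequence"
  )
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf(
    "<annotated_sequence> %d bp, %d CDS feature(s), GC %.3f\n",
    nchar(x$seq), nrow(x$cds), gc_content(x$seq)
  ))
  invisible(x)
}

#' @export
length.annotated_sequence <- function(x) nchar(x$seq)

#' Extract the coding sequence of one CDS feature, 5'->3'
#'
#' Minus-strand features are reverse-complemented so that codon-level
#' operations are strand-agnostic.
#' @noRd
.cds_string <- function(bases, start, end, strand) {
  s <- paste(bases[(start + 1L):end], collapse = "")
  if (strand == "-") reverse_complement(s) else s
}
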