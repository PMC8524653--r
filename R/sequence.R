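# Sequence primitives shared by objectives, operators and the generator.

.valid_bases <- c("A", "C", "G", "T")

#' Split a DNA string into single bases
#' @noRd
.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Check a character vector of bases against the strict DNA alphabet
#' @noRd
.check_alphabet <- function(bases, what = "sequence") {
  bad <- !(bases %in% .valid_bases)
  if (any(bad)) {
    stop(sprintf(
      "%s contains %d character(s) outside the {A,C,G,T} alphabet (first: '%s')",
      what, sum(bad), bases[which(bad)[1L]]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' GC content of a DNA sequence
#'
#' Fraction of bases that are G or C. The construct-level objectives are all
#' expressed in terms of this primitive evaluated on blocks or coding
#' sequences.
#'
#' @param seq A single DNA string over the alphabet A, C, G, T.
#' @return A fraction in \[0, 1\].
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) {
    stop("cannot compute GC content of an empty sequence", call. = FALSE)
  }
  bases <- .seq_chars(seq)
  .check_alphabet(bases)
  sum(bases %in% c("G", "C")) / length(bases)
}

#' Translate a coding sequence
#'
#' Standard genetic code translation; stop codons are rendered as `"*"`.
#' Used to assert that recoding operators only ever make silent edits.
#'
#' @param cds A DNA string whose length is a multiple of 3.
#' @return An amino-acid string (one letter per codon).
#' @examples
#' translate_cds("ATGAAATAA")
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3", call. = FALSE)
  }
  bases <- .seq_chars(cds)
  .check_alphabet(bases, "CDS")
  codons <- .codons_from_bases(bases)
  paste(.codon_aa[codons], collapse = "")
}

#' @noRd
.codons_from_bases <- function(bases) {
  n <- length(bases)
  paste0(
    bases[seq(1L, n, by = 3L)],
    bases[seq(2L, n, by = 3L)],
    bases[seq(3L, n, by = 3L)]
  )
}

#' Synonymous codons of a sense codon
#'
#' All codons (including the input) encoding the same amino acid under the
#' standard genetic code. Stop codons are never recoded and are rejected.
#'
#' @param codon A 3-mer over A, C, G, T encoding an amino acid.
#' @return Character vector of synonymous codons.
#' @examples
#' synonymous_codons("GCT")
#' @export
synonymous_codons <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  if (!codon %in% names(.codon_aa)) {
    stop(sprintf("'%s' is not a codon over {A,C,G,T}", codon), call. = FALSE)
  }
  if (codon %in% .stop_codons) {
    stop(sprintf("'%s' is a stop codon; stop codons are never recoded", codon),
      call. = FALSE
    )
  }
  unname(.syn_families[[.codon_aa[[codon]]]])
}

#' Reverse complement of a DNA string
#' @param seq A DNA string over A, C, G, T.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  bases <- .seq_chars(seq)
  .check_alphabet(bases)
  paste(rev(.complement_map[bases]), collapse = "")
}
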