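# Codon usage tables: per-codon relative frequencies grouped by amino acid.

#' Construct a codon usage table
#'
#' A codon usage table gives, for each amino acid, the relative frequency of
#' each synonymous codon in a target organism. The codon-usage objective
#' compares each codon used in a design against the most frequent (modal)
#' synonym, and the codon operator recodes toward the modal synonym.
#'
#' @param freqs Either a named numeric vector (names are the 61 sense
#'   codons, values their relative frequencies) or a data frame with columns
#'   `codon` and `frequency`.
#' @return A `codon_table` object: the frequency vector plus cached modal /
#'   rarest synonym lookups.
#' @details Frequencies within each amino-acid family must sum to 1
#'   (tolerance 1e-6). All 61 sense codons must be present.
#' @seealso [read_codon_table()], [random_codon_table()]
#' @export
codon_table <- function(freqs) {
  if (is.data.frame(freqs)) {
    stopifnot(all(c("codon", "frequency") %in% names(freqs)))
    freqs <- setNames(as.numeric(freqs$frequency), toupper(freqs$codon))
  }
  stopifnot(is.numeric(freqs), !is.null(names(freqs)))
  names(freqs) <- toupper(names(freqs))
  missing <- setdiff(.sense_codons, names(freqs))
  if (length(missing) > 0L) {
    stop(sprintf(
      "codon table is missing %d sense codon(s), e.g. %s",
      length(missing), missing[1L]
    ), call. = FALSE)
  }
  freqs <- freqs[.sense_codons]
  if (any(freqs < 0 | freqs > 1)) {
    stop("codon frequencies must lie in [0, 1]", call. = FALSE)
  }
  for (aa in names(.syn_families)) {
    s <- sum(freqs[.syn_families[[aa]]])
    if (abs(s - 1) > 1e-6) {
      stop(sprintf(
        "frequencies for amino acid '%s' sum to %.8f, not 1", aa, s
      ), call. = FALSE)
    }
  }
  # modal synonym per codon (ties broken alphabetically, reproducible)
  modal <- character(length(.sense_codons))
  names(modal) <- .sense_codons
  q_max <- q_min <- numeric(length(.sense_codons))
  names(q_max) <- names(q_min) <- .sense_codons
  for (fam in .syn_families) {
    f <- freqs[fam]
    modal[fam] <- fam[order(-f, fam)][1L]
    q_max[fam] <- max(f)
    q_min[fam] <- min(f)
  }
  structure(
    list(freq = freqs, modal = modal, q_max = q_max, q_min = q_min),
    class = "codon_table"
  )
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf(
    "<codon_table> 61 sense codons, %d modal codons GC-rich\n",
    sum(.codon_gc_n[unique(x$modal)] >= 2)
  ))
  invisible(x)
}

#' Read a codon usage table from a two-column text file
#'
#' The file format is whitespace- or tab-separated with two columns,
#' codon and relative frequency; lines starting with `#` are ignored.
#'
#' @param path Path to the table file.
#' @return A [codon_table()] object.
#' @export
read_codon_table <- function(path) {
  df <- utils::read.table(path,
    header = FALSE, comment.char = "#",
    col.names = c("codon", "frequency"),
    colClasses = c("character", "numeric")
  )
  codon_table(df)
}

#' Write a codon usage table to a two-column text file
#'
#' @param table A [codon_table()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_table <- function(table, path) {
  stopifnot(inherits(table, "codon_table"))
  utils::write.table(
    data.frame(codon = names(table$freq), frequency = unname(table$freq)),
    path,
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(path)
}

#' Random codon usage table
#'
#' Draws uniform weights per synonymous family and normalizes them to
#' relative frequencies. Used by the synthetic benchmark, where codon
#' frequencies are generated at random rather than taken from an organism.
#'
#' @param seed Optional integer seed for reproducibility.
#' @return A [codon_table()] object.
#' @export
random_codon_table <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- numeric(length(.sense_codons))
  names(freqs) <- .sense_codons
  for (fam in .syn_families) {
    w <- runif(length(fam))
    freqs[fam] <- w / sum(w)
  }
  codon_table(freqs)
}

#' Tidy a codon usage table into a tibble
#'
#' @param x A [codon_table()] object.
#' @param ... Unused.
#' @return A tibble with one row per sense codon: `codon`, `amino_acid`,
#'   `frequency`, `modal` (logical).
#' @export
tidy.codon_table <- function(x, ...) {
  tibble(
    codon = names(x$freq),
    amino_acid = unname(.codon_aa[names(x$freq)]),
    frequency = unname(x$freq),
    modal = names(x$freq) == unname(x$modal[names(x$freq)])
  )
}
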