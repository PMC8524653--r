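# The candidate-design data structure: a construct sequence plus an ordered
# block partition, with cached per-base GC and per-CDS codon scores so that
# objective evaluation after a single edit is O(blocks + CDSs).

#' Create a candidate design from a reference construct
#'
#' A solution pairs a (possibly recoded) construct sequence with an ordered
#' block partition describing how the construct will be synthesized and
#' assembled. Blocks exactly partition the sequence: they are contiguous,
#' the first starts at 0 and the last ends at the sequence length.
#'
#' @param ref An [annotated_sequence()].
#' @param blocks Block partition: either `NULL` (a single full-length
#'   block), an integer vector of block end positions (ascending, last equal
#'   to the sequence length), or a data frame with `start`/`end` columns.
#' @return A `design_solution` object.
#' @export
new_solution <- function(ref, blocks = NULL) {
  stopifnot(inherits(ref, "annotated_sequence"))
  bases <- .seq_chars(ref$seq)
  L <- length(bases)
  if (is.null(blocks)) {
    bounds <- L
  } else if (is.data.frame(blocks)) {
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    bounds <- as.integer(blocks$end)
    if (nrow(blocks) == 0L || blocks$start[1L] != 0L ||
      !all(blocks$start[-1L] == blocks$end[-nrow(blocks)])) {
      stop("blocks must contiguously cover the sequence from position 0", call. = FALSE)
    }
  } else {
    bounds <- as.integer(blocks)
  }
  .new_solution(bases, bounds, ref$cds)
}

#' @noRd
.new_solution <- function(bases, bounds, cds, codon_score = NULL,
                          objectives = NULL) {
  structure(
    list(
      bases = bases,
      bounds = as.integer(bounds),
      cds = cds,
      is_gc = as.integer(bases %in% c("G", "C")),
      codon_score = codon_score,
      objectives = objectives
    ),
    class = "design_solution"
  )
}

#' @export
print.design_solution <- function(x, ...) {
  cat(sprintf(
    "<design_solution> %d bp, %d block(s), %d CDS feature(s)\n",
    length(x$bases), length(x$bounds), nrow(x$cds)
  ))
  if (!is.null(x$objectives)) {
    cat("  objectives:",
      paste(sprintf("%s=%.4g", names(x$objectives), x$objectives), collapse = " "),
      "\n"
    )
  }
  invisible(x)
}

#' Block partition of a design as a tibble
#'
#' @param z A `design_solution`.
#' @return A tibble with columns `start` (0-based), `end` (exclusive),
#'   `length` and the block's GC fraction.
#' @export
solution_blocks <- function(z) {
  stopifnot(inherits(z, "design_solution"))
  starts <- c(0L, z$bounds[-length(z$bounds)])
  cum <- cumsum(z$is_gc)
  gc_counts <- cum[z$bounds] - c(0, cum[starts[-1L]])
  tibble(
    start = starts,
    end = z$bounds,
    length = z$bounds - starts,
    gc = gc_counts / (z$bounds - starts)
  )
}

#' Construct sequence of a design as a string
#'
#' @param z A `design_solution`.
#' @return A single DNA string.
#' @export
solution_sequence <- function(z) {
  stopifnot(inherits(z, "design_solution"))
  paste(z$bases, collapse = "")
}

#' Codon vector of one CDS of a design (5'->3')
#' @noRd
.solution_cds_codons <- function(z, i) {
  s <- .cds_string(z$bases, z$cds$start[i], z$cds$end[i], z$cds$strand[i])
  .codons_from_bases(.seq_chars(s))
}

#' Write a codon vector back into one CDS of a design, updating caches
#' @noRd
.solution_set_cds <- function(z, i, codons, table = NULL) {
  s <- paste(codons, collapse = "")
  if (z$cds$strand[i] == "-") s <- reverse_complement(s)
  idx <- (z$cds$start[i] + 1L):z$cds$end[i]
  z$bases[idx] <- .seq_chars(s)
  z$is_gc[idx] <- as.integer(z$bases[idx] %in% c("G", "C"))
  if (!is.null(z$codon_score) && !is.null(table)) {
    z$codon_score[i] <- .cds_codon_score(codons, table)
  }
  z$objectives <- NULL
  z
}

#' Per-CDS codon-usage score: sum over sense codons of Q(aa) - q(codon)
#' @noRd
.cds_codon_score <- function(codons, table) {
  sense <- codons[!(codons %in% .stop_codons)]
  if (length(sense) == 0L) return(0)
  miss <- !(sense %in% names(table$freq))
  if (any(miss)) {
    stop(sprintf("codon '%s' absent from the usage table", sense[miss][1L]),
      call. = FALSE
    )
  }
  sum(table$q_max[sense] - table$freq[sense])
}

#' @noRd
.ensure_codon_scores <- function(z, table) {
  if (is.null(z$codon_score) && nrow(z$cds) > 0L) {
    z$codon_score <- vapply(
      seq_len(nrow(z$cds)),
      function(i) .cds_codon_score(.solution_cds_codons(z, i), table),
      numeric(1)
    )
  } else if (is.null(z$codon_score)) {
    z$codon_score <- numeric(0)
  }
  z
}

#' Validate a candidate design against its reference construct
#'
#' Checks every structural invariant of a design: the blocks exactly
#' partition the sequence, all block lengths respect the synthesis limits,
#' the sequence length is unchanged, and every CDS still translates to the
#' reference protein (all edits silent).
#'
#' @param z A `design_solution`.
#' @param ref The [annotated_sequence()] the design was derived from.
#' @param cfg A [design_config()] supplying `l_min` / `l_max`.
#' @return A list with elements `valid` (logical) and `reasons`
#'   (character vector of failed checks, empty when valid).
#' @export
validate_solution <- function(z, ref, cfg) {
  stopifnot(inherits(z, "design_solution"), inherits(ref, "annotated_sequence"),
    inherits(cfg, "design_config")
  )
  reasons <- character()
  L <- length(z$bases)
  if (L != nchar(ref$seq)) {
    reasons <- c(reasons, "sequence length differs from reference")
  }
  b <- z$bounds
  if (length(b) == 0L || b[length(b)] != L || any(diff(c(0L, b)) <= 0L)) {
    reasons <- c(reasons, "blocks do not contiguously partition the sequence")
  } else {
    len <- diff(c(0L, b))
    if (any(len < cfg$l_min) || any(len > cfg$l_max)) {
      reasons <- c(reasons, "block length outside [l_min, l_max]")
    }
  }
  if (!all(z$bases %in% .valid_bases)) {
    reasons <- c(reasons, "sequence contains non-ACGT characters")
  }
  if (L == nchar(ref$seq) && nrow(z$cds) > 0L) {
    ref_bases <- .seq_chars(ref$seq)
    for (i in seq_len(nrow(z$cds))) {
      got <- translate_cds(.cds_string(
        z$bases, z$cds$start[i], z$cds$end[i], z$cds$strand[i]
      ))
      want <- translate_cds(.cds_string(
        ref_bases, ref$cds$start[i], ref$cds$end[i], ref$cds$strand[i]
      ))
      if (!identical(got, want)) {
        reasons <- c(reasons, sprintf("CDS %d translation changed (non-silent edit)", i))
      }
    }
  }
  list(valid = length(reasons) == 0L, reasons = reasons)
}
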