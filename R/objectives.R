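# The four design/manufacturing objectives, all minimized, and their
# ideal/nadir bound estimation.

#' GC-content objective
#'
#' Sum over blocks of the absolute deviation between the block's GC fraction
#' and the target `t_gc`. Zero exactly when every block sits at the target.
#'
#' @param z A `design_solution`.
#' @param t_gc Target GC fraction.
#' @return Nonnegative objective value.
#' @export
obj_gc <- function(z, t_gc) {
  stopifnot(inherits(z, "design_solution"))
  b <- z$bounds
  starts <- c(0L, b[-length(b)])
  cum <- c(0, cumsum(z$is_gc))
  gc <- (cum[b + 1L] - cum[starts + 1L]) / (b - starts)
  sum(abs(t_gc - gc))
}

#' Codon-usage objective
#'
#' Sum over all CDS codons of `Q(aa) - q(codon)`, where `Q(aa)` is the
#' usage-table frequency of the amino acid's most frequent codon and
#' `q(codon)` the table frequency of the codon actually used. Zero exactly
#' when every codon is its amino acid's modal codon. Stop codons (absent
#' from the 61-sense-codon table) do not contribute.
#'
#' @param z A `design_solution`.
#' @param table A [codon_table()].
#' @return Nonnegative objective value.
#' @export
obj_codon_usage <- function(z, table) {
  stopifnot(inherits(z, "design_solution"), inherits(table, "codon_table"))
  z <- .ensure_codon_scores(z, table)
  sum(z$codon_score)
}

#' Block-length-variance objective
#'
#' Population variance of the block lengths: homogeneous fragments assemble
#' more reliably. Zero when all blocks have the same length.
#'
#' @param z A `design_solution`.
#' @return Nonnegative objective value.
#' @export
obj_block_variance <- function(z) {
  stopifnot(inherits(z, "design_solution"))
  len <- diff(c(0L, z$bounds))
  mean((len - mean(len))^2)
}

#' Block-count objective
#'
#' Number of blocks (fragments to synthesize and assemble).
#'
#' @param z A `design_solution`.
#' @return Positive integer.
#' @export
obj_block_count <- function(z) {
  stopifnot(inherits(z, "design_solution"))
  length(z$bounds)
}

#' Evaluate the configured objectives on a design
#'
#' @param z A `design_solution`.
#' @param cfg A [design_config()].
#' @return `z` with its `objectives` field set to a named numeric vector in
#'   the order of `cfg$objectives`.
#' @export
evaluate_solution <- function(z, cfg) {
  vals <- vapply(cfg$objectives, function(id) {
    switch(id,
      gc = obj_gc(z, cfg$t_gc),
      codon_usage = obj_codon_usage(z, cfg$codon_table),
      block_variance = obj_block_variance(z),
      block_count = as.numeric(obj_block_count(z))
    )
  }, numeric(1))
  z$objectives <- vals
  z
}

#' Ideal and nadir bounds of the configured objectives
#'
#' Analytic bounds where available, a heuristic for the GC nadir: each CDS
#' codon is replaced by the synonym whose GC fraction is furthest from the
#' target, the sequence is partitioned into the maximum admissible number of
#' blocks, and the GC objective of that worst-case design is evaluated.
#' Because the GC nadir is heuristic it is an estimate, not a proven bound.
#'
#' The analytic bounds: codon usage has ideal 0 and nadir equal to the sum
#' over CDS codons of the modal-minus-rarest frequency gap; block variance
#' has ideal 0 and nadir `(l_max - l_min)^2 / 4`; block count has ideal
#' `ceiling(L / l_max)` and nadir `floor(L / l_min)`.
#'
#' @param ref An [annotated_sequence()].
#' @param cfg A [design_config()].
#' @return A tibble with columns `objective`, `ideal`, `nadir`.
#' @export
estimate_bounds <- function(ref, cfg) {
  stopifnot(inherits(ref, "annotated_sequence"), inherits(cfg, "design_config"))
  L <- nchar(ref$seq)
  if (L < cfg$l_min) {
    stop("sequence shorter than the minimum block length", call. = FALSE)
  }
  rows <- lapply(cfg$objectives, function(id) {
    switch(id,
      gc = tibble(objective = "gc", ideal = 0, nadir = .gc_nadir(ref, cfg)),
      codon_usage = tibble(
        objective = "codon_usage", ideal = 0,
        nadir = .codon_nadir(ref, cfg$codon_table)
      ),
      block_variance = tibble(
        objective = "block_variance", ideal = 0,
        nadir = (cfg$l_max - cfg$l_min)^2 / 4
      ),
      block_count = tibble(
        objective = "block_count",
        ideal = ceiling(L / cfg$l_max),
        nadir = floor(L / cfg$l_min)
      )
    )
  })
  dplyr::bind_rows(rows)
}

# Worst-case GC design: every CDS codon recoded to the synonym with GC
# fraction furthest from t_gc, then split into the max admissible number of
# (near-even) blocks.
#' @noRd
.gc_nadir <- function(ref, cfg) {
  z <- new_solution(ref)
  if (nrow(z$cds) > 0L) {
    for (i in seq_len(nrow(z$cds))) {
      codons <- .solution_cds_codons(z, i)
      sense <- !(codons %in% .stop_codons)
      lo <- .syn_min_gc[codons[sense]]
      hi <- .syn_max_gc[codons[sense]]
      d_lo <- abs(.codon_gc_n[lo] / 3 - cfg$t_gc)
      d_hi <- abs(.codon_gc_n[hi] / 3 - cfg$t_gc)
      codons[sense] <- ifelse(d_lo >= d_hi, lo, hi)
      z <- .solution_set_cds(z, i, codons)
    }
  }
  L <- length(z$bases)
  nb <- max(1L, L %/% cfg$l_min)
  z$bounds <- unique(as.integer(round(seq_len(nb) * (L / nb))))
  obj_gc(z, cfg$t_gc)
}

#' @noRd
.codon_nadir <- function(ref, table) {
  if (is.null(table)) {
    stop("codon_usage bounds require a codon_table", call. = FALSE)
  }
  z <- new_solution(ref)
  if (nrow(z$cds) == 0L) return(0)
  total <- 0
  for (i in seq_len(nrow(z$cds))) {
    codons <- .solution_cds_codons(z, i)
    sense <- codons[!(codons %in% .stop_codons)]
    total <- total + sum(table$q_max[sense] - table$q_min[sense])
  }
  total
}
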