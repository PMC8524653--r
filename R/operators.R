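# Stochastic edit operators: local search moves mapping a valid design to a
# new valid design. Sequence operators touch one random CDS and only make
# silent (synonymous) edits; block operators touch one block or block pair
# and never change the sequence.

#' @noRd
.sample1 <- function(v) v[sample.int(length(v), 1L)]

#' GC recoding operator
#'
#' Recodes one randomly chosen CDS by iterated single-codon synonymous
#' substitutions toward the target GC fraction `t_gc`. Each move swaps a
#' random improvable codon for its highest-GC synonym (when below target)
#' or lowest-GC synonym (when above). Moves continue while the accumulated
#' GC change on the CDS stays within `sigma_gc`, so a single move may
#' overshoot the budget by at most one codon (3 / CDS length). The walk also
#' stops when the CDS GC is within half a codon (1.5 nt) of the target or
#' when no synonym improves.
#'
#' @param z A `design_solution`.
#' @param cfg A [design_config()] (uses `t_gc`, `sigma_gc`, `codon_table`
#'   to refresh codon-score caches).
#' @return A new `design_solution`; the input is never modified. Designs
#'   without CDS features are returned unchanged.
#' @export
edit_gc <- function(z, cfg) {
  stopifnot(inherits(z, "design_solution"), inherits(cfg, "design_config"))
  if (nrow(z$cds) == 0L) return(z)
  i <- .sample1(seq_len(nrow(z$cds)))
  codons <- .solution_cds_codons(z, i)
  nc <- length(codons)
  len <- 3 * nc
  editable <- !(codons %in% .stop_codons)
  if (length(editable) > 0L && codons[1L] == "ATG") editable[1L] <- FALSE
  gcn <- .codon_gc_n[codons]
  start_cnt <- sum(gcn)
  cur_cnt <- start_cnt
  target_cnt <- cfg$t_gc * len
  max_delta <- cfg$sigma_gc * len
  changed <- FALSE
  for (iter in seq_len(10L * nc)) {
    if (abs(cur_cnt - start_cnt) > max_delta) break
    if (abs(target_cnt - cur_cnt) <= 1.5) break
    if (target_cnt > cur_cnt) {
      cand <- which(editable & .syn_max_gc_n[codons] > gcn)
      repl <- .syn_max_gc
    } else {
      cand <- which(editable & .syn_min_gc_n[codons] < gcn)
      repl <- .syn_min_gc
    }
    if (length(cand) == 0L) break
    j <- .sample1(cand)
    new_codon <- repl[[codons[j]]]
    cur_cnt <- cur_cnt - gcn[j] + .codon_gc_n[[new_codon]]
    codons[j] <- new_codon
    gcn[j] <- .codon_gc_n[[new_codon]]
    changed <- TRUE
  }
  if (!changed) return(z)
  .solution_set_cds(z, i, codons, cfg$codon_table)
}

#' Codon-usage recoding operator
#'
#' Independently replaces each codon of one randomly chosen CDS, with
#' probability `sigma_c`, by the most frequent synonymous codon of the
#' usage table. Stop codons and a leading ATG are left untouched; the
#' translation is preserved by construction.
#'
#' @param z A `design_solution`.
#' @param cfg A [design_config()] (uses `sigma_c`).
#' @param table A [codon_table()]; defaults to `cfg$codon_table`.
#' @return A new `design_solution`; unchanged if no CDS is present.
#' @export
edit_codon <- function(z, cfg, table = cfg$codon_table) {
  stopifnot(inherits(z, "design_solution"), inherits(cfg, "design_config"))
  if (is.null(table)) stop("edit_codon requires a codon_table", call. = FALSE)
  if (nrow(z$cds) == 0L) return(z)
  i <- .sample1(seq_len(nrow(z$cds)))
  codons <- .solution_cds_codons(z, i)
  editable <- !(codons %in% .stop_codons)
  if (length(editable) > 0L && codons[1L] == "ATG") editable[1L] <- FALSE
  sel <- editable & (runif(length(codons)) < cfg$sigma_c)
  if (!any(sel)) return(z)
  codons[sel] <- table$modal[codons[sel]]
  .solution_set_cds(z, i, codons, table)
}

#' @noRd
.admissible_left_lengths <- function(total, cfg) {
  j_lo <- ceiling(max(cfg$l_min, total - cfg$l_max) / cfg$sigma_b)
  j_hi <- floor(min(cfg$l_max, total - cfg$l_min) / cfg$sigma_b)
  if (j_hi < j_lo || j_hi < 1L) return(integer(0))
  seq.int(max(1L, j_lo), j_hi) * cfg$sigma_b
}

#' Block split operator
#'
#' Splits one randomly chosen block (of length at least `2 * l_min`) into
#' two at a cut point whose left length is a uniformly chosen multiple of
#' `sigma_b`, with both parts inside `[l_min, l_max]`. When no block is
#' splittable or no admissible cut exists the design is returned unchanged.
#'
#' @param z A `design_solution`.
#' @param cfg A [design_config()].
#' @return A new `design_solution` with one more block on success.
#' @export
edit_block_split <- function(z, cfg) {
  stopifnot(inherits(z, "design_solution"), inherits(cfg, "design_config"))
  len <- diff(c(0L, z$bounds))
  splittable <- which(len >= 2L * cfg$l_min)
  if (length(splittable) == 0L) return(z)
  i <- .sample1(splittable)
  lefts <- .admissible_left_lengths(len[i], cfg)
  if (length(lefts) == 0L) return(z)
  cut <- c(0L, z$bounds)[i] + .sample1(lefts)
  z$bounds <- sort(c(z$bounds, as.integer(cut)))
  z$objectives <- NULL
  z
}

#' Block join operator
#'
#' Merges one randomly chosen pair of adjacent blocks. If the merged block
#' exceeds `l_max` it is re-split into two blocks whose left length is a
#' multiple of `sigma_b` with both parts inside `[l_min, l_max]` (the block
#' count is unchanged but the boundary moves). Single-block designs are
#' returned unchanged.
#'
#' @param z A `design_solution`.
#' @param cfg A [design_config()].
#' @return A new `design_solution`.
#' @export
edit_block_join <- function(z, cfg) {
  stopifnot(inherits(z, "design_solution"), inherits(cfg, "design_config"))
  nb <- length(z$bounds)
  if (nb < 2L) return(z)
  i <- .sample1(seq_len(nb - 1L)) # boundary between block i and i+1
  starts <- c(0L, z$bounds)
  merged <- z$bounds[i + 1L] - starts[i]
  if (merged <= cfg$l_max) {
    z$bounds <- z$bounds[-i]
  } else {
    lefts <- .admissible_left_lengths(merged, cfg)
    if (length(lefts) == 0L) return(z)
    z$bounds[i] <- starts[i] + .sample1(lefts)
  }
  z$objectives <- NULL
  z
}

#' Apply one random edit operator
#'
#' Draws uniformly among the operators relevant to the configured
#' objectives: `edit_gc` when the GC objective is active, `edit_codon` when
#' the codon-usage objective is active, and the two block operators always.
#'
#' @param z A `design_solution`.
#' @param cfg A [design_config()].
#' @return A new `design_solution`.
#' @export
random_edit <- function(z, cfg) {
  ops <- .dispatch_set(cfg)
  switch(.sample1(ops),
    gc = edit_gc(z, cfg),
    codon = edit_codon(z, cfg),
    split = edit_block_split(z, cfg),
    join = edit_block_join(z, cfg)
  )
}

#' @noRd
.dispatch_set <- function(cfg) {
  c(
    if ("gc" %in% cfg$objectives) "gc",
    if ("codon_usage" %in% cfg$objectives) "codon",
    "split", "join"
  )
}
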