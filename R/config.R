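# Optimizer run configuration and the canned design problems.

.known_objectives <- c("gc", "codon_usage", "block_variance", "block_count")

#' Optimizer configuration
#'
#' Bundles the evolutionary-search parameters, the synthesis constraints and
#' the active objective set. All length parameters are in nucleotides; GC
#' parameters are fractions.
#'
#' @param objectives Character vector of objective identifiers, drawn from
#'   `"gc"`, `"codon_usage"`, `"block_variance"`, `"block_count"`, or a
#'   design-problem id (`"P1"`..`"P4"`, see [design_problem()]).
#' @param n Pool size (solutions kept per iteration).
#' @param t_max Iteration budget.
#' @param m Archive capacity (must be `>= n`).
#' @param l_min,l_max Minimum / maximum synthesizable block length (nt).
#' @param sigma_gc Maximum GC-fraction change allowed per GC-operator
#'   application (absolute difference, e.g. 0.05 = 5 percentage points).
#' @param sigma_c Per-codon recoding probability of the codon operator.
#' @param sigma_b Block boundary step size (nt): split/join cut points land
#'   on multiples of this grid.
#' @param t_gc Target GC fraction for blocks and for the GC operator.
#' @param overlap Gibson-assembly overlap length (nt) used when exporting
#'   manufacturable fragments.
#' @param codon_table A [codon_table()] object; required when the
#'   `codon_usage` objective is active.
#' @param seed Optional integer RNG seed; runs are bit-reproducible given
#'   the same seed.
#' @return A `design_config` object (a validated list).
#' @export
design_config <- function(objectives = c("gc", "block_count"),
                          n = 100L, t_max = 200L, m = 100L,
                          l_min = 500L, l_max = 3000L,
                          sigma_gc = 0.05, sigma_c = 0.25, sigma_b = 100L,
                          t_gc = 0.55, overlap = 40L,
                          codon_table = NULL, seed = NULL) {
  if (length(objectives) == 1L && objectives %in% c("P1", "P2", "P3", "P4")) {
    objectives <- design_problem(objectives)
  }
  objectives <- as.character(objectives)
  unknown <- setdiff(objectives, .known_objectives)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown objective id(s): %s", paste(unknown, collapse = ", ")),
      call. = FALSE
    )
  }
  if (length(objectives) == 0L) stop("at least one objective is required", call. = FALSE)
  if (anyDuplicated(objectives)) stop("duplicated objective id", call. = FALSE)
  n <- as.integer(n); t_max <- as.integer(t_max); m <- as.integer(m)
  l_min <- as.integer(l_min); l_max <- as.integer(l_max)
  sigma_b <- as.integer(sigma_b); overlap <- as.integer(overlap)
  stopifnot(
    n >= 1L, t_max >= 0L, m >= n,
    l_min > 0L, l_min <= l_max, sigma_b > 0L,
    sigma_gc >= 0, sigma_c >= 0, sigma_c <= 1,
    t_gc >= 0, t_gc <= 1, overlap >= 0L
  )
  if (!is.null(codon_table)) stopifnot(inherits(codon_table, "codon_table"))
  if ("codon_usage" %in% objectives && is.null(codon_table)) {
    stop("the codon_usage objective requires a codon_table", call. = FALSE)
  }
  structure(
    list(
      objectives = objectives, n = n, t_max = t_max, m = m,
      l_min = l_min, l_max = l_max,
      sigma_gc = sigma_gc, sigma_c = sigma_c, sigma_b = sigma_b,
      t_gc = t_gc, overlap = overlap,
      codon_table = codon_table, seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat(sprintf(
    "<design_config> objectives: %s\n  n=%d t_max=%d m=%d | blocks [%d, %d] nt, step %d\n  sigma_gc=%.3f sigma_c=%.2f t_gc=%.2f overlap=%d\n",
    paste(x$objectives, collapse = ", "),
    x$n, x$t_max, x$m, x$l_min, x$l_max, x$sigma_b,
    x$sigma_gc, x$sigma_c, x$t_gc, x$overlap
  ))
  invisible(x)
}

#' Canned design problems
#'
#' Four benchmark objective combinations covering the common DNA
#' design-for-manufacturing scenarios: `P1` = GC content + block count,
#' `P2` = GC content + block length variance, `P3` = GC content + block
#' variance + block count, `P4` = GC content + codon usage + block count.
#'
#' @param id One of `"P1"`, `"P2"`, `"P3"`, `"P4"`.
#' @return Character vector of objective identifiers.
#' @export
design_problem <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  switch(id,
    P1 = c("gc", "block_count"),
    P2 = c("gc", "block_variance"),
    P3 = c("gc", "block_variance", "block_count"),
    P4 = c("gc", "codon_usage", "block_count"),
    stop(sprintf("unknown design problem '%s' (use P1..P4)", id), call. = FALSE)
  )
}
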