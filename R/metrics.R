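# Front quality metrics: non-dominated filtering, hypervolume, normalized
# hypervolume, cross-run global Pareto union and the optimality share.

#' Maximal non-dominated subset of a set of objective vectors
#'
#' Duplicate vectors collapse to a single representative.
#'
#' @param M Numeric matrix or data frame, one row per solution, one column
#'   per objective (all minimized).
#' @return A numeric matrix: the mutually non-dominated rows of `M`.
#' @export
non_dominated_filter <- function(M) {
  M <- .as_obj_matrix(M)
  if (nrow(M) == 0L) return(M)
  M <- M[!duplicated(.vec_keys(M)), , drop = FALSE]
  M[domination_rank(M) == 0L, , drop = FALSE]
}

#' Hypervolume dominated by a front inside the ideal-nadir box
#'
#' The Lebesgue measure of the set of points in the box `[ideal, nadir]`
#' weakly dominated by at least one front member, i.e. the region between
#' the front and the nadir. Front points are clipped into the box. The
#' computation is an exact sweep for two objectives and exact recursive
#' slicing along the last objective for three or more (practical for the
#' small fronts a bounded archive produces).
#'
#' @param front Numeric matrix (rows = solutions, columns = objectives).
#' @param ideal,nadir Numeric vectors bounding the box, `ideal <= nadir`
#'   componentwise.
#' @return Nonnegative hypervolume.
#' @export
hypervolume <- function(front, ideal, nadir) {
  front <- .as_obj_matrix(front)
  k <- ncol(front)
  stopifnot(length(ideal) == k, length(nadir) == k)
  if (any(ideal > nadir)) {
    stop("ideal must be <= nadir in every coordinate", call. = FALSE)
  }
  if (nrow(front) == 0L) return(0)
  for (j in seq_len(k)) {
    front[, j] <- pmin(pmax(front[, j], ideal[j]), nadir[j])
  }
  front <- non_dominated_filter(front)
  .hv(front, nadir)
}

#' @noRd
.hv <- function(M, nadir) {
  k <- ncol(M)
  if (nrow(M) == 0L) return(0)
  if (k == 1L) return(nadir[1L] - min(M[, 1L]))
  if (k == 2L) {
    # rows are mutually non-dominated: sorted by f1 ascending, f2 is
    # strictly decreasing
    M <- M[order(M[, 1L]), , drop = FALSE]
    prev2 <- c(nadir[2L], M[-nrow(M), 2L])
    return(sum((nadir[1L] - M[, 1L]) * (prev2 - M[, 2L])))
  }
  # slice along the last objective
  zs <- sort(unique(M[, k]))
  uppers <- c(zs[-1L], nadir[k])
  total <- 0
  for (i in seq_along(zs)) {
    depth <- uppers[i] - zs[i]
    if (depth <= 0) next
    slab <- M[M[, k] <= zs[i], -k, drop = FALSE]
    slab <- non_dominated_filter(slab)
    total <- total + depth * .hv(slab, nadir[-k])
  }
  total
}

#' Normalized hypervolume
#'
#' Hypervolume of the front divided by the volume of the ideal-nadir box;
#' 1 for a front sitting at the ideal point, 0 at the nadir.
#'
#' @inheritParams hypervolume
#' @return A value in \[0, 1\].
#' @export
normalized_hypervolume <- function(front, ideal, nadir) {
  vol <- prod(nadir - ideal)
  if (vol <= 0) {
    stop("degenerate box: every objective must have nadir > ideal", call. = FALSE)
  }
  hypervolume(front, ideal, nadir) / vol
}

#' Approximate global Pareto front across runs
#'
#' The non-dominated subset of the union of the fronts found by several
#' independent runs or parameter settings.
#'
#' @param fronts A list of numeric matrices (uniform column count).
#' @return A numeric matrix, the non-dominated union.
#' @export
global_pareto_union <- function(fronts) {
  stopifnot(is.list(fronts), length(fronts) > 0L)
  non_dominated_filter(do.call(rbind, lapply(fronts, .as_obj_matrix)))
}

#' Share of the global Pareto front recovered by one setting
#'
#' The fraction of the approximate global Pareto set that one parameter
#' setting found, normalized by the pool size: the count of the setting's
#' solutions that are members of the global set (exact objective-vector
#' equality) divided by `min(|global set|, pool_size)`.
#'
#' @param setting_front Numeric matrix: the front found by one setting.
#' @param global_front Numeric matrix: the global Pareto union (non-empty).
#' @param pool_size Pool size used by the setting.
#' @return A value in \[0, 1\].
#' @export
r_theta <- function(setting_front, global_front, pool_size) {
  setting_front <- .as_obj_matrix(setting_front)
  global_front <- .as_obj_matrix(global_front)
  if (nrow(global_front) == 0L) {
    stop("the global Pareto set must be non-empty", call. = FALSE)
  }
  setting_front <- setting_front[!duplicated(.vec_keys(setting_front)), ,
    drop = FALSE
  ]
  found <- sum(.vec_keys(setting_front) %in% .vec_keys(global_front))
  found / min(nrow(global_front), pool_size)
}

#' Extract the archive front of a run as a matrix
#'
#' @param run A `design_run`.
#' @return Numeric matrix of archived objective vectors (columns named by
#'   objective).
#' @export
pareto_front <- function(run) {
  stopifnot(inherits(run, "design_run"))
  M <- .obj_matrix_of(run$archive)
  colnames(M) <- run$config$objectives
  M
}

#' Normalized hypervolume of a run's archive front
#'
#' Convenience wrapper computing the normalized hypervolume of the archive
#' front against the run's estimated ideal-nadir bounds.
#'
#' @param run A `design_run`.
#' @return A value in \[0, 1\].
#' @export
run_nv <- function(run) {
  stopifnot(inherits(run, "design_run"))
  normalized_hypervolume(pareto_front(run), run$bounds$ideal, run$bounds$nadir)
}
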