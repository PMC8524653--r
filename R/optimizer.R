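# The evolutionary main loop: clone-edit-evaluate cycles with
# domination-count ranking, crowding-distance selection and a bounded
# non-dominated archive.

#' Pareto dominance between two objective vectors
#'
#' All objectives are minimized: `u` dominates `v` when `u` is no worse in
#' every component and strictly better in at least one.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(u, v) {
  if (length(u) != length(v)) {
    stop("objective vectors must have equal length", call. = FALSE)
  }
  all(u <= v) && any(u < v)
}

#' Domination count of each member of a set of objective vectors
#'
#' `rank[i]` is the number of other members that dominate member `i`;
#' non-dominated members have rank 0.
#'
#' @param M A numeric matrix, one row per solution, one column per
#'   objective (minimized).
#' @return Integer vector of domination counts.
#' @export
domination_rank <- function(M) {
  M <- .as_obj_matrix(M)
  n <- nrow(M)
  if (n == 0L) return(integer(0))
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(M))) {
    cj <- M[, j]
    le <- le & outer(cj, cj, "<=")
    lt <- lt | outer(cj, cj, "<")
  }
  as.integer(colSums(le & lt))
}

#' @noRd
.as_obj_matrix <- function(M) {
  if (is.data.frame(M)) M <- as.matrix(M)
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  storage.mode(M) <- "double"
  M
}

#' Crowding distance of each member of a set of objective vectors
#'
#' Per objective, members are sorted and each interior member is credited
#' the normalized gap between its two neighbours,
#' `(f(next) - f(prev)) / (f_max - f_min)`; the two extreme members per
#' objective receive infinite distance. The total distance is the sum over
#' objectives. Degenerate objectives (`f_max == f_min`) contribute 0.
#'
#' @param M Numeric matrix of objective vectors (rows = solutions).
#' @param f_min,f_max Per-objective normalization bounds (defaults: the
#'   column ranges of `M`; the optimizer passes its running extremes).
#' @return Numeric vector of crowding distances (may be `Inf`).
#' @export
crowding_distance <- function(M, f_min = NULL, f_max = NULL) {
  M <- .as_obj_matrix(M)
  n <- nrow(M)
  k <- ncol(M)
  if (n == 0L) return(numeric(0))
  if (is.null(f_min)) f_min <- apply(M, 2, min)
  if (is.null(f_max)) f_max <- apply(M, 2, max)
  stopifnot(length(f_min) == k, length(f_max) == k, all(f_max >= f_min))
  d <- numeric(n)
  for (i in seq_len(k)) {
    ord <- order(M[, i])
    d[ord[1L]] <- Inf
    d[ord[n]] <- Inf
    if (n > 2L) {
      span <- f_max[i] - f_min[i]
      if (span > 0) {
        mid <- ord[2:(n - 1L)]
        d[mid] <- d[mid] + (M[ord[3:n], i] - M[ord[1:(n - 2L)], i]) / span
      }
    }
  }
  d
}

#' @noRd
.obj_matrix_of <- function(solutions) {
  do.call(rbind, lapply(solutions, function(z) z$objectives))
}

#' Environmental selection: keep the best n of parents plus offspring
#'
#' The union is sorted by domination count (ascending) and then crowding
#' distance (descending, ties broken by insertion order) and the top `n`
#' are retained.
#'
#' @param parents,offspring Lists of evaluated `design_solution`s.
#' @param n Number of solutions to keep.
#' @param f_min,f_max Optional per-objective normalization bounds for the
#'   crowding distance (the optimizer passes its running extremes).
#' @return A list of `n` solutions.
#' @export
select_pool <- function(parents, offspring, n, f_min = NULL, f_max = NULL) {
  union <- c(parents, offspring)
  M <- .obj_matrix_of(union)
  rank <- domination_rank(M)
  crowd <- crowding_distance(M, f_min, f_max)
  keep <- order(rank, -crowd, seq_along(union))[seq_len(n)]
  union[keep]
}

#' Initialize a pool of n designs with diverse random partitions
#'
#' Each pool member is a clone of the input construct with an independent
#' random partition: a target mean block length is drawn uniformly in
#' `[l_min, l_max]`, the sequence is cut into that many near-equal blocks,
#' and interior boundaries are jittered on the `sigma_b` grid while keeping
#' every block inside the synthesis limits.
#'
#' @param ref An [annotated_sequence()] of length at least `l_min`.
#' @param cfg A [design_config()].
#' @return A list of `cfg$n` unevaluated `design_solution`s.
#' @export
initialize_pool <- function(ref, cfg) {
  stopifnot(inherits(ref, "annotated_sequence"), inherits(cfg, "design_config"))
  L <- nchar(ref$seq)
  if (L < cfg$l_min) {
    stop("sequence shorter than the minimum block length", call. = FALSE)
  }
  base <- new_solution(ref)
  if ("codon_usage" %in% cfg$objectives) {
    base <- .ensure_codon_scores(base, cfg$codon_table)
  }
  nb_min <- max(1L, as.integer(ceiling(L / cfg$l_max)))
  nb_max <- max(nb_min, as.integer(L %/% cfg$l_min))
  lapply(seq_len(cfg$n), function(dummy) {
    target_len <- runif(1L, cfg$l_min, cfg$l_max)
    nb <- min(max(as.integer(round(L / target_len)), nb_min), nb_max)
    z <- base
    z$bounds <- .random_partition(L, nb, cfg)
    z
  })
}

# Near-even partition of [0, L) into nb blocks, boundaries jittered on the
# sigma_b grid subject to the block length limits.
#' @noRd
.random_partition <- function(L, nb, cfg) {
  base_len <- L %/% nb
  rem <- L %% nb
  len <- rep.int(base_len, nb) + c(rep.int(1L, rem), rep.int(0L, nb - rem))
  bounds <- cumsum(len)
  if (nb > 1L) {
    for (i in seq_len(nb - 1L)) {
      shift <- .sample1(c(-1L, 0L, 1L)) * cfg$sigma_b
      if (shift == 0L) next
      cand <- bounds[i] + shift
      left <- cand - if (i == 1L) 0L else bounds[i - 1L]
      right <- bounds[i + 1L] - cand
      if (left >= cfg$l_min && left <= cfg$l_max &&
        right >= cfg$l_min && right <= cfg$l_max) {
        bounds[i] <- cand
      }
    }
  }
  as.integer(bounds)
}

#' Update the bounded non-dominated archive
#'
#' Merges candidate designs into the archive, drops every dominated member
#' and collapses duplicate objective vectors. If the archive then exceeds
#' its capacity `m`, the members with the smallest crowding distance are
#' discarded until the size is `m`.
#'
#' @param archive List of evaluated `design_solution`s (mutually
#'   non-dominated).
#' @param candidates List of evaluated `design_solution`s to merge.
#' @param m Archive capacity.
#' @param f_min,f_max Optional crowding-distance normalization bounds.
#' @return The updated archive (a list).
#' @export
archive_update <- function(archive, candidates, m, f_min = NULL, f_max = NULL) {
  all_sol <- c(archive, candidates)
  if (length(all_sol) == 0L) return(all_sol)
  M <- .obj_matrix_of(all_sol)
  keep <- !duplicated(.vec_keys(M))
  all_sol <- all_sol[keep]
  M <- M[keep, , drop = FALSE]
  nd <- domination_rank(M) == 0L
  all_sol <- all_sol[nd]
  M <- M[nd, , drop = FALSE]
  if (length(all_sol) > m) {
    crowd <- crowding_distance(M, f_min, f_max)
    keep <- order(-crowd, seq_along(all_sol))[seq_len(m)]
    all_sol <- all_sol[sort(keep)]
  }
  all_sol
}

#' @noRd
.vec_keys <- function(M) {
  apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = "|"))
}

#' @noRd
.evaluate_all <- function(solutions, cfg) {
  lapply(solutions, function(z) {
    if (is.null(z$objectives)) evaluate_solution(z, cfg) else z
  })
}

#' Redesign a construct by multi-objective evolutionary search
#'
#' Runs the full optimization loop: an initial pool of `n` randomly
#' partitioned clones of the input is evolved for `t_max` iterations. Each
#' iteration clones the pool, applies one random edit operator to every
#' clone, evaluates the configured objectives, selects the best `n` of the
#' `2n` by domination count and crowding distance, and updates the bounded
#' non-dominated archive with all evaluated solutions. Runs are
#' bit-reproducible given `cfg$seed`.
#'
#' @param ref An [annotated_sequence()].
#' @param cfg A [design_config()].
#' @param keep_log Keep the objective vectors of every solution ever
#'   evaluated (for auditing the archive against a full re-scan).
#' @return A `design_run` object with elements `pool`, `archive` (lists of
#'   evaluated `design_solution`s), `history` (tibble: iteration,
#'   objective, min/mean/max over the pool), `bounds` (ideal/nadir tibble),
#'   `config`, `ref`, and `eval_log` (matrix or `NULL`).
#' @seealso [tidy.design_run()], [glance.design_run()],
#'   [autoplot.design_run()], [export_design()]
#' @export
optimize_design <- function(ref, cfg, keep_log = FALSE) {
  stopifnot(inherits(ref, "annotated_sequence"), inherits(cfg, "design_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bounds <- estimate_bounds(ref, cfg)
  pool <- .evaluate_all(initialize_pool(ref, cfg), cfg)
  M <- .obj_matrix_of(pool)
  f_min <- apply(M, 2, min)
  f_max <- apply(M, 2, max)
  eval_log <- if (keep_log) M else NULL
  archive <- archive_update(list(), pool, cfg$m, f_min, f_max)
  history <- list(.history_row(0L, M, cfg$objectives))
  t <- 1L
  while (t <= cfg$t_max) {
    offspring <- .evaluate_all(lapply(pool, random_edit, cfg = cfg), cfg)
    Mo <- .obj_matrix_of(offspring)
    f_min <- pmin(f_min, apply(Mo, 2, min))
    f_max <- pmax(f_max, apply(Mo, 2, max))
    if (keep_log) eval_log <- rbind(eval_log, Mo)
    archive <- archive_update(archive, c(pool, offspring), cfg$m, f_min, f_max)
    pool <- select_pool(pool, offspring, cfg$n, f_min, f_max)
    history[[t + 1L]] <- .history_row(t, .obj_matrix_of(pool), cfg$objectives)
    t <- t + 1L
  }
  structure(
    list(
      pool = pool, archive = archive,
      history = dplyr::bind_rows(history),
      bounds = bounds, config = cfg, ref = ref,
      f_min = setNames(f_min, cfg$objectives),
      f_max = setNames(f_max, cfg$objectives),
      eval_log = eval_log
    ),
    class = "design_run"
  )
}

#' @noRd
.history_row <- function(t, M, objectives) {
  tibble(
    iteration = t,
    objective = objectives,
    min = apply(M, 2, min),
    mean = apply(M, 2, mean),
    max = apply(M, 2, max)
  )
}

#' @export
print.design_run <- function(x, ...) {
  cat(sprintf(
    "<design_run> %d iteration(s), pool %d, archive %d design(s)\n",
    max(x$history$iteration), length(x$pool), length(x$archive)
  ))
  cat("  objectives:", paste(x$config$objectives, collapse = ", "), "\n")
  invisible(x)
}
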