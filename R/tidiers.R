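# Broom-style tidiers and ggplot2 autoplot methods for run objects.

#' Tidy the archive front of a run
#'
#' @param x A `design_run`.
#' @param ... Unused.
#' @return A tibble with one row per archived design: `design` id, one
#'   column per objective, `n_blocks`, and the block end positions as a
#'   comma-separated string.
#' @export
tidy.design_run <- function(x, ...) {
  M <- pareto_front(x)
  out <- as_tibble(M)
  dplyr::bind_cols(
    tibble(design = seq_len(nrow(M))),
    out,
    tibble(
      n_blocks = vapply(x$archive, function(z) length(z$bounds), integer(1)),
      block_ends = vapply(
        x$archive,
        function(z) paste(z$bounds, collapse = ","), character(1)
      )
    )
  )
}

#' One-row summary of a run
#'
#' @param x A `design_run`.
#' @param ... Unused.
#' @return A tibble with the iteration count, pool and archive sizes, the
#'   number of objectives and the normalized hypervolume of the archive
#'   front against the run's ideal-nadir bounds.
#' @export
glance.design_run <- function(x, ...) {
  tibble(
    iterations = max(x$history$iteration),
    pool_size = x$config$n,
    archive_size = length(x$archive),
    n_objectives = length(x$config$objectives),
    nv = run_nv(x)
  )
}

#' Plot a run: archive front or convergence history
#'
#' `type = "front"` draws the archived trade-off designs in objective
#' space (first two objectives; a third, if present, maps to colour).
#' `type = "history"` draws the per-iteration minimum and mean of each
#' objective over the pool.
#'
#' @param object A `design_run`.
#' @param type `"front"` or `"history"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.design_run <- function(object, type = c("front", "history"), ...) {
  type <- match.arg(type)
  if (type == "front") {
    df <- tidy(object)
    objs <- object$config$objectives
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data[[objs[1L]]],
      y = .data[[objs[min(2L, length(objs))]]]
    )) +
      ggplot2::labs(
        title = "Archived trade-off designs",
        x = objs[1L], y = objs[min(2L, length(objs))]
      ) +
      ggplot2::theme_minimal()
    if (length(objs) >= 3L) {
      p + ggplot2::geom_point(ggplot2::aes(colour = .data[[objs[3L]]]))
    } else {
      p + ggplot2::geom_point()
    }
  } else {
    df <- tidyr::pivot_longer(object$history, c("min", "mean"),
      names_to = "statistic", values_to = "value"
    )
    ggplot2::ggplot(df, ggplot2::aes(
      x = .data$iteration, y = .data$value, colour = .data$statistic
    )) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~objective, scales = "free_y") +
      ggplot2::labs(title = "Objective convergence", y = "objective value") +
      ggplot2::theme_minimal()
  }
}
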