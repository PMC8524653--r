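# Shared fixtures and independent oracles, all built in code.

# a small construct with one CDS (Met-Lys-stop) and known composition
tiny_ref <- function() {
  annotated_sequence(
    paste0("ATGAAATAA", strrep("GATC", 10)),
    cds = data.frame(start = 0, end = 9, strand = "+")
  )
}

# a config permissive enough for small test sequences
small_cfg <- function(...) {
  design_config(
    objectives = c("gc", "block_count"),
    n = 5L, t_max = 5L, m = 10L,
    l_min = 3L, l_max = 10000L, sigma_b = 3L, ...
  )
}

# deterministic sequence with an exact GC fraction: num GC bases out of den
seq_with_gc <- function(num, den) {
  paste0(strrep("G", num), strrep("A", den - num))
}

# brute-force pairwise domination oracle (independent of domination_rank)
oracle_rank <- function(M) {
  n <- nrow(M)
  vapply(seq_len(n), function(j) {
    sum(vapply(seq_len(n), function(i) {
      i != j && all(M[i, ] <= M[j, ]) && any(M[i, ] < M[j, ])
    }, logical(1)))
  }, integer(1))
}

oracle_non_dominated <- function(M) {
  M <- M[!duplicated(M), , drop = FALSE]
  M[oracle_rank(M) == 0L, , drop = FALSE]
}

# Monte-Carlo dominated-volume oracle: fraction of uniform samples in the
# ideal-nadir box weakly dominated by >= 1 front point
mc_hypervolume <- function(front, ideal, nadir, n_samples = 20000L) {
  k <- length(ideal)
  pts <- matrix(runif(n_samples * k), ncol = k)
  pts <- sweep(pts, 2L, nadir - ideal, "*")
  pts <- sweep(pts, 2L, ideal, "+")
  dominated <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(front))) {
    ok <- rep(TRUE, n_samples)
    for (j in seq_len(k)) ok <- ok & (front[i, j] <= pts[, j])
    dominated <- dominated | ok
  }
  frac <- mean(dominated)
  list(
    volume = frac * prod(nadir - ideal),
    se = sqrt(frac * (1 - frac) / n_samples) * prod(nadir - ideal)
  )
}

# random mutually non-dominated front of n points in k dims inside [0,1]^k
random_front <- function(n, k) {
  M <- matrix(runif(3 * n * k), ncol = k)
  M <- M[!duplicated(M), , drop = FALSE]
  nd <- M[oracle_rank(M) == 0L, , drop = FALSE]
  nd[seq_len(min(n, nrow(nd))), , drop = FALSE]
}
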