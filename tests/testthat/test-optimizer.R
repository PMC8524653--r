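# Selection machinery and the main loop.

test_that("dominance follows the componentwise definition", {
  expect_true(dominates(c(1, 2), c(2, 3)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("domination counts match the brute-force oracle", {
  expect_equal(domination_rank(rbind(c(0, 0), c(1, 1), c(2, 2))), c(0L, 1L, 2L))
  expect_equal(domination_rank(rbind(c(0, 1), c(1, 0))), c(0L, 0L))
  expect_equal(domination_rank(matrix(c(3, 1), nrow = 1)), 0L)
  set.seed(13)
  for (k in 2:3) {
    for (rep in 1:10) {
      M <- matrix(sample(0:4, 30 * k, replace = TRUE), ncol = k)
      expect_equal(domination_rank(M), oracle_rank(M))
    }
  }
})

test_that("crowding distance credits interior gaps and infinite extremes", {
  d <- crowding_distance(matrix(c(0, 4, 10), ncol = 1), f_min = 0, f_max = 10)
  expect_equal(d, c(Inf, 1.0, Inf))
  expect_equal(crowding_distance(matrix(c(1, 2), ncol = 1)), c(Inf, Inf))
  # degenerate objective contributes 0
  M <- cbind(c(0, 4, 10), c(5, 5, 5))
  d <- crowding_distance(M, f_min = c(0, 5), f_max = c(10, 5))
  expect_equal(d[2], 1.0)
})

test_that("selection keeps exactly n, preferring rank then spread", {
  ref <- generate_construct(benchmark_spec(2, seed = 14))
  cfg <- design_config("P1", n = 10, t_max = 2, seed = 14)
  run <- optimize_design(ref, cfg)
  expect_length(run$pool, 10L)
  # a dominating solution is always retained
  mk <- function(v) {
    z <- new_solution(annotated_sequence("ACGTACGT"))
    z$objectives <- v
    z
  }
  parents <- lapply(list(c(0, 0), c(5, 1)), mk)
  offspring <- lapply(list(c(1, 5), c(4, 4)), mk)
  kept <- select_pool(parents, offspring, 2L)
  expect_true(any(vapply(kept, function(z) all(z$objectives == c(0, 0)), logical(1))))
})

test_that("initial pools are feasible and diverse", {
  ref <- generate_construct(benchmark_spec(2, seed = 15)) # ~3.5 kb
  cfg <- design_config("P1", n = 10, t_max = 0, l_min = 500, l_max = 3000, seed = 15)
  pool <- initialize_pool(ref, cfg)
  expect_length(pool, 10L)
  L <- length(ref)
  for (z in pool) {
    v <- validate_solution(z, ref, cfg)
    expect_true(v$valid)
    nb <- length(z$bounds)
    expect_gte(nb, ceiling(L / 3000))
    expect_lte(nb, floor(L / 500))
  }
  expect_error(
    initialize_pool(annotated_sequence("ACGT"), cfg),
    "shorter"
  )
})

test_that("archive keeps the non-dominated set and evicts by crowding", {
  mk <- function(v) {
    z <- new_solution(annotated_sequence("ACGTACGT"))
    z$objectives <- v
    z
  }
  arch <- lapply(list(c(0, 2), c(2, 0)), mk)
  # dominated candidate: no change
  a2 <- archive_update(arch, list(mk(c(3, 3))), m = 10)
  expect_equal(sort(vapply(a2, function(z) z$objectives[1], numeric(1))), c(0, 2))
  # dominating candidate replaces a member
  a3 <- archive_update(arch, list(mk(c(0, 1))), m = 10)
  M <- do.call(rbind, lapply(a3, function(z) z$objectives))
  expect_true(any(apply(M, 1, identical, y = c(0, 1))))
  expect_false(any(apply(M, 1, identical, y = c(0, 2))))
  # crowded middle point evicted at capacity (extremes have infinite distance)
  line <- lapply(list(c(0, 10), c(1, 9), c(10, 0)), mk)
  a4 <- archive_update(list(), line, m = 2)
  M4 <- do.call(rbind, lapply(a4, function(z) z$objectives))
  expect_equal(nrow(M4), 2L)
  expect_false(any(apply(M4, 1, identical, y = c(1, 9))))
})

test_that("a zero-iteration run returns the evaluated initial pool", {
  ref <- generate_construct(benchmark_spec(2, seed = 16))
  cfg <- design_config("P1", n = 8, t_max = 0, m = 50, seed = 16)
  run <- optimize_design(ref, cfg, keep_log = TRUE)
  expect_length(run$pool, 8L)
  expect_equal(nrow(run$eval_log), 8L)
  arch <- unname(dnaforge:::.obj_matrix_of(run$archive))
  nd <- unname(non_dominated_filter(run$eval_log))
  expect_equal(
    arch[order(arch[, 1]), , drop = FALSE],
    nd[order(nd[, 1]), , drop = FALSE]
  )
})

test_that("identical seeds give bit-identical runs", {
  ref <- generate_construct(benchmark_spec(2, seed = 17))
  cfg <- design_config("P1", n = 10, t_max = 10, seed = 99)
  r1 <- optimize_design(ref, cfg)
  r2 <- optimize_design(ref, cfg)
  expect_identical(dnaforge:::.obj_matrix_of(r1$pool), dnaforge:::.obj_matrix_of(r2$pool))
  expect_identical(dnaforge:::.obj_matrix_of(r1$archive), dnaforge:::.obj_matrix_of(r2$archive))
  expect_identical(r1$history, r2$history)
  expect_identical(
    solution_sequence(r1$archive[[1]]),
    solution_sequence(r2$archive[[1]])
  )
})

test_that("elitist selection makes the best single objective non-increasing", {
  ref <- generate_construct(benchmark_spec(2, seed = 18))
  cfg <- design_config("gc", n = 15, t_max = 40, seed = 18)
  run <- optimize_design(ref, cfg)
  best <- run$history$min[run$history$objective == "gc"]
  expect_true(all(diff(best) <= 1e-12))
})

test_that("the archive matches a brute-force rescan of the evaluation log", {
  ref <- generate_construct(benchmark_spec(2, seed = 19))
  cfg <- design_config("P1", n = 10, t_max = 20, m = 1000, seed = 19)
  run <- optimize_design(ref, cfg, keep_log = TRUE)
  expect_equal(nrow(run$eval_log), 10 * 21)
  want <- oracle_non_dominated(run$eval_log)
  got <- dnaforge:::.obj_matrix_of(run$archive)
  key <- function(M) sort(apply(M, 1, paste, collapse = "|"))
  expect_equal(key(got), key(want))
  # with a tight capacity the archive is a size-m non-dominated subset
  cfg_small <- design_config("P1", n = 10, t_max = 20, m = 10, seed = 19)
  run_s <- optimize_design(ref, cfg_small, keep_log = TRUE)
  got_s <- dnaforge:::.obj_matrix_of(run_s$archive)
  expect_lte(nrow(got_s), 10)
  expect_true(all(domination_rank(got_s) == 0))
})
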