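# Edit operators: silentness, bounded GC drift, admissible cuts, dispatch.

leu_ref <- function(n = 3) {
  annotated_sequence(strrep("TTA", n),
    cds = data.frame(start = 0, end = 3 * n, strand = "+")
  )
}

test_that("GC operator walks toward the target within its budget", {
  cfg <- small_cfg(t_gc = 0.5, sigma_gc = 0.12)
  # CDS already at target: no move
  at_target <- annotated_sequence("ATGTTAGGGTAA", # GC = 5/12 -> target set there
    cds = data.frame(start = 0, end = 12, strand = "+")
  )
  cfg_at <- small_cfg(t_gc = gc_content("ATGTTAGGGTAA"), sigma_gc = 0.2)
  set.seed(1)
  z <- edit_gc(new_solution(at_target), cfg_at)
  expect_equal(solution_sequence(z), at_target$seq)

  # single-codon families only: nothing can move
  mw <- annotated_sequence("ATGTGGATGTGG",
    cds = data.frame(start = 0, end = 12, strand = "+")
  )
  set.seed(2)
  z <- edit_gc(new_solution(mw), small_cfg(t_gc = 0.9, sigma_gc = 0.5))
  expect_equal(solution_sequence(z), mw$seq)

  # Leu-only CDS far below target: one extreme-synonym move (+2 GC) fits the
  # budget, the next would not, so the walk stops at GC = 2/9
  ref <- leu_ref(3)
  for (s in 1:25) {
    set.seed(s)
    z <- edit_gc(new_solution(ref), cfg)
    gc_new <- gc_content(solution_sequence(z))
    expect_equal(gc_new, 2 / 9)
    expect_lte(abs(gc_new - 0), 0.12 + 3 / 9 + 1e-12)
    expect_equal(translate_cds(solution_sequence(z)), "LLL")
  }
})

test_that("GC operator drift is bounded by sigma_gc plus one codon", {
  ref <- generate_construct(benchmark_spec(2, seed = 21))
  cfg <- design_config("P1", n = 2, t_max = 0, sigma_gc = 0.05)
  base <- new_solution(ref)
  cds_gc <- function(z, i) {
    gc_content(substr(solution_sequence(z), z$cds$start[i] + 1, z$cds$end[i]))
  }
  set.seed(77)
  for (rep in 1:100) {
    z <- edit_gc(base, cfg)
    for (i in seq_len(nrow(ref$cds))) {
      len <- ref$cds$end[i] - ref$cds$start[i]
      expect_lte(
        abs(cds_gc(z, i) - cds_gc(base, i)),
        0.05 + 3 / len + 1e-12
      )
    }
  }
})

test_that("codon operator recodes toward modal with probability sigma_c", {
  tab <- local({
    f <- tidy(random_codon_table(seed = 1))
    v <- setNames(f$frequency, f$codon)
    v[c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")] <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.5)
    codon_table(v)
  })
  ref <- leu_ref(300)
  # sigma_c = 0: identity
  set.seed(3)
  z <- edit_codon(new_solution(ref), small_cfg(sigma_c = 0), tab)
  expect_equal(solution_sequence(z), ref$seq)
  # sigma_c = 1: fully modal, objective contribution zero
  set.seed(4)
  z <- edit_codon(new_solution(ref), small_cfg(sigma_c = 1), tab)
  expect_equal(solution_sequence(z), strrep("CTG", 300))
  expect_equal(obj_codon_usage(z, tab), 0)
  # sigma_c = 0.5: binomial recoding count
  set.seed(5)
  counts <- replicate(100, {
    z <- edit_codon(new_solution(ref), small_cfg(sigma_c = 0.5), tab)
    sum(strsplit(solution_sequence(z), "(?<=.{3})", perl = TRUE)[[1]] == "CTG")
  })
  expect_gt(mean(counts), 150 - 3 * sqrt(300 * 0.25))
  expect_lt(mean(counts), 150 + 3 * sqrt(300 * 0.25))
})

test_that("block split cuts on the sigma_b grid within length limits", {
  seq <- strrep("ACGT", 500) # 2000 nt
  ref <- annotated_sequence(seq)
  cfg <- design_config("P1", l_min = 500, l_max = 3000, sigma_b = 500, n = 2, t_max = 0)
  cuts <- integer(0)
  for (s in 1:60) {
    set.seed(s)
    z <- edit_block_split(new_solution(ref), cfg)
    expect_equal(length(z$bounds), 2L)
    cuts <- c(cuts, z$bounds[1])
    len <- diff(c(0L, z$bounds))
    expect_true(all(len >= 500 & len <= 3000))
  }
  expect_setequal(unique(cuts), c(500L, 1000L, 1500L))

  # unsplittable: single block of length l_min
  tiny <- annotated_sequence(strrep("ACGT", 125)) # 500 nt
  set.seed(1)
  z <- edit_block_split(new_solution(tiny), cfg)
  expect_equal(z$bounds, 500L)
})

test_that("block join merges when it fits and re-splits when too long", {
  seq <- strrep("ACGT", 500)
  ref <- annotated_sequence(seq)
  cfg <- design_config("P1", l_min = 500, l_max = 3000, sigma_b = 500, n = 2, t_max = 0)
  set.seed(6)
  z <- edit_block_join(new_solution(ref, blocks = c(1000L, 2000L)), cfg)
  expect_equal(z$bounds, 2000L)
  # one-block design unchanged
  z1 <- edit_block_join(new_solution(ref), cfg)
  expect_equal(z1$bounds, 2000L)

  big <- annotated_sequence(strrep("ACGT", 1250)) # 5000 nt
  lefts <- integer(0)
  for (s in 1:60) {
    set.seed(s)
    z <- edit_block_join(new_solution(big, blocks = c(2500L, 5000L)), cfg)
    expect_equal(length(z$bounds), 2L)
    lefts <- c(lefts, z$bounds[1])
    len <- diff(c(0L, z$bounds))
    expect_true(all(len >= 500 & len <= 3000))
  }
  expect_setequal(unique(lefts), c(2000L, 2500L, 3000L))
})

test_that("random_edit dispatches uniformly over the relevant operators", {
  cfg <- design_config(c("gc", "block_count"), n = 2, t_max = 0)
  expect_setequal(dnaforge:::.dispatch_set(cfg), c("gc", "split", "join"))
  cfg4 <- design_config("P4", codon_table = random_codon_table(seed = 1), n = 2, t_max = 0)
  expect_setequal(dnaforge:::.dispatch_set(cfg4), c("gc", "codon", "split", "join"))
  set.seed(8)
  draws <- replicate(9999, dnaforge:::.sample1(dnaforge:::.dispatch_set(cfg)))
  freq <- table(draws) / length(draws)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("operators preserve the sequence/partition separation", {
  ref <- generate_construct(benchmark_spec(2, seed = 9))
  cfg <- design_config("P4",
    codon_table = random_codon_table(seed = 9),
    n = 2, t_max = 0
  )
  set.seed(10)
  z0 <- initialize_pool(ref, cfg)[[1]]
  for (s in 1:30) {
    set.seed(s)
    zg <- edit_gc(z0, cfg)
    expect_identical(zg$bounds, z0$bounds)
    zc <- edit_codon(z0, cfg)
    expect_identical(zc$bounds, z0$bounds)
    zs <- edit_block_split(z0, cfg)
    expect_identical(zs$bases, z0$bases)
    zj <- edit_block_join(z0, cfg)
    expect_identical(zj$bases, z0$bases)
  }
})
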