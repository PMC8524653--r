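# GenBank I/O, YAML run configuration, fragment export.

test_that("GenBank coordinates convert between 1-based and half-open", {
  dir <- withr::local_tempdir()
  seq <- paste0(strrep("A", 10), "ATGAAATAA", strrep("C", 10))
  ref <- annotated_sequence(seq, cds = data.frame(start = 10, end = 19, strand = "+"))
  path <- file.path(dir, "x.gb")
  write_genbank(ref, path, name = "x")
  gb <- readLines(path)
  expect_true(any(grepl("CDS             11..19", gb, fixed = TRUE)))
  back <- read_genbank(path)
  expect_identical(back$seq, seq)
  expect_equal(back$cds$start, 10L)
  expect_equal(back$cds$end, 19L)
})

test_that("minus-strand and CDS-free records are handled", {
  dir <- withr::local_tempdir()
  gene <- "ATGAAATGGTAA"
  seq <- paste0("TTTT", reverse_complement(gene), "GGGG")
  ref <- annotated_sequence(seq, cds = data.frame(start = 4, end = 16, strand = "-"))
  path <- file.path(dir, "minus.gb")
  write_genbank(ref, path)
  back <- read_genbank(path)
  expect_equal(back$cds$strand, "-")
  expect_equal(back$cds$start, 4L)
  expect_equal(back$cds$end, 16L)

  bare <- annotated_sequence(strrep("ACGT", 30))
  path2 <- file.path(dir, "bare.gb")
  write_genbank(bare, path2)
  expect_warning(read_genbank(path2), "no CDS")
})

test_that("the GenBank writer round-trips through an independent parser", {
  dir <- withr::local_tempdir()
  con <- generate_construct(benchmark_spec(2, seed = 41))
  path <- file.path(dir, "con.gb")
  write_genbank(con, path, name = "con")
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys",
    "from Bio import SeqIO",
    "rec = SeqIO.read(sys.argv[1], 'genbank')",
    "cds = [f for f in rec.features if f.type == 'CDS']",
    "print(len(rec.seq), len(cds))",
    "for f in cds:",
    "    print(int(f.location.start), int(f.location.end))"
  ), script)
  out <- system2("python", c(script, path), stdout = TRUE)
  expect_equal(out[1], paste(length(con), nrow(con$cds)))
  coords <- do.call(rbind, strsplit(out[-1], " "))
  expect_equal(as.integer(coords[, 1]), con$cds$start)
  expect_equal(as.integer(coords[, 2]), con$cds$end)
})

test_that("fragment export produces Gibson-compatible overlaps that reassemble", {
  dir <- withr::local_tempdir()
  seq <- strrep("ACGT", 500) # 2000 nt
  ref <- annotated_sequence(seq)
  cfg <- design_config("P1", l_min = 500, l_max = 3000, overlap = 40, n = 2, t_max = 0)
  z <- new_solution(ref, blocks = c(1000L, 2000L))
  frags <- export_design(z, cfg, dir, name = "demo")
  expect_equal(frags$length, c(1040L, 1000L))
  fa <- Biostrings::readDNAStringSet(frags$file[1])
  expect_length(fa, 2L)
  s1 <- as.character(fa[[1]])
  s2 <- as.character(fa[[2]])
  expect_equal(substr(s1, 1001, 1040), substr(s2, 1, 40))
  # overlap-merge reconstructs the design exactly
  expect_equal(paste0(substr(s1, 1, 1000), s2), seq)
  # single block: fragment is the whole sequence
  f1 <- export_design(new_solution(ref), cfg, dir, name = "one")
  expect_equal(f1$length, 2000L)
  # overlap must be shorter than the smallest block
  cfg_big <- design_config("P1", l_min = 30, l_max = 3000, overlap = 1500, n = 2, t_max = 0)
  zs <- new_solution(ref, blocks = c(1000L, 2000L))
  expect_error(export_design(zs, cfg_big, dir), "overlap")
})

test_that("YAML run configurations load into a design_config", {
  dir <- withr::local_tempdir()
  con <- generate_construct(benchmark_spec(2, seed = 42))
  gb <- file.path(dir, "in.gb")
  write_genbank(con, gb)
  tabf <- file.path(dir, "usage.tsv")
  write_codon_table(random_codon_table(seed = 42), tabf)
  yml <- file.path(dir, "run.yaml")
  writeLines(c(
    sprintf("input: %s", gb),
    "problem: P4",
    sprintf("codon_table: %s", tabf),
    "t_gc: 0.5",
    "optimizer: {n: 10, t_max: 5, m: 20, seed: 3}",
    "operators: {sigma_gc: 0.1, sigma_c: 0.9, sigma_b: 250}",
    "blocks: {l_min: 400, l_max: 2500, overlap: 30}"
  ), yml)
  rc <- read_run_config(yml)
  expect_equal(rc$config$objectives, c("gc", "codon_usage", "block_count"))
  expect_equal(rc$config$n, 10L)
  expect_equal(rc$config$sigma_c, 0.9)
  expect_equal(rc$config$l_max, 2500L)
  expect_equal(rc$config$t_gc, 0.5)
  expect_s3_class(rc$config$codon_table, "codon_table")
  expect_error(suppressWarnings(read_run_config(file.path(dir, "absent.yaml"))))
  writeLines("input: /no/such/file.gb", file.path(dir, "bad.yaml"))
  expect_error(read_run_config(file.path(dir, "bad.yaml")), "does not exist")
})

test_that("codon tables round-trip through their text format", {
  dir <- withr::local_tempdir()
  tab <- random_codon_table(seed = 43)
  path <- file.path(dir, "t.tsv")
  write_codon_table(tab, path)
  back <- read_codon_table(path)
  expect_equal(back$freq, tab$freq, tolerance = 1e-12)
  expect_identical(back$modal, tab$modal)
  # a broken table is rejected
  bad <- tab$freq
  bad["GCT"] <- bad["GCT"] + 0.1
  expect_error(codon_table(bad), "sum to")
})
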