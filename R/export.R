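# Design export (GenBank + Gibson-ready FASTA fragments) and the YAML run
# configuration.

#' Export a redesigned construct and its manufacturable fragments
#'
#' Writes (a) the full redesigned sequence as a GenBank file with CDS and
#' block features, and (b) one FASTA record per manufacturable fragment.
#' Fragment `i` is its block extended by `cfg$overlap` nt into the next
#' block (the last block is unextended), so adjacent fragments share an
#' exact terminal overlap compatible with Gibson assembly; overlap-merging
#' the fragments reconstructs the design sequence exactly.
#'
#' @param z An evaluated `design_solution`.
#' @param cfg A [design_config()] (supplies `overlap`).
#' @param out_dir Output directory (created if missing).
#' @param name Base name for the output files.
#' @return Invisibly, a tibble describing the fragments (name, start, end,
#'   length, file).
#' @export
export_design <- function(z, cfg, out_dir, name = "design") {
  stopifnot(inherits(z, "design_solution"), inherits(cfg, "design_config"))
  blocks <- solution_blocks(z)
  if (cfg$overlap >= min(blocks$length)) {
    stop("Gibson overlap must be shorter than the smallest block", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gb_path <- file.path(out_dir, paste0(name, ".gb"))
  write_genbank(z, gb_path, name = name)

  seq <- solution_sequence(z)
  nb <- nrow(blocks)
  frag_end <- pmin(blocks$end + cfg$overlap, nchar(seq))
  frag_end[nb] <- blocks$end[nb]
  frags <- substring(seq, blocks$start + 1L, frag_end)
  names(frags) <- sprintf("%s_fragment_%02d", name, seq_len(nb))
  fa_path <- file.path(out_dir, paste0(name, "_fragments.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(frags), fa_path)
  invisible(tibble(
    fragment = names(frags),
    start = blocks$start, end = frag_end,
    length = frag_end - blocks$start,
    file = fa_path
  ))
}

#' Read a YAML run configuration
#'
#' The schema mirrors [design_config()]:
#' \preformatted{
#' input: construct.gb          # GenBank input path
#' output: results              # output directory
#' problem: P1                  # or objectives: [gc, block_count]
#' codon_table: usage.tsv       # optional two-column table
#' t_gc: 0.55
#' optimizer: {n: 100, t_max: 200, m: 100, seed: 42}
#' operators: {sigma_gc: 0.05, sigma_c: 0.25, sigma_b: 100}
#' blocks: {l_min: 500, l_max: 3000, overlap: 40}
#' }
#'
#' @param path Path to a YAML file.
#' @return A list with `input`, `output` and `config` (a
#'   [design_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$input) && !file.exists(y$input)) {
    stop(sprintf("input file '%s' does not exist", y$input), call. = FALSE)
  }
  objectives <- if (!is.null(y$problem)) design_problem(y$problem) else y$objectives
  if (is.null(objectives)) {
    stop("configuration must give either 'problem' or 'objectives'", call. = FALSE)
  }
  table <- NULL
  if (!is.null(y$codon_table)) {
    if (!file.exists(y$codon_table)) {
      stop(sprintf("codon table '%s' does not exist", y$codon_table), call. = FALSE)
    }
    table <- read_codon_table(y$codon_table)
  }
  opt <- y$optimizer %||% list()
  # YAML 1.1 treats a bare `n` key as a boolean; map it back to the pool size
  names(opt)[names(opt) %in% c("FALSE", "no")] <- "n"
  ops <- y$operators %||% list()
  blk <- y$blocks %||% list()
  cfg <- design_config(
    objectives = objectives,
    n = opt$n %||% 100L, t_max = opt$t_max %||% 200L, m = opt$m %||% 100L,
    seed = opt$seed,
    sigma_gc = ops$sigma_gc %||% 0.05, sigma_c = ops$sigma_c %||% 0.25,
    sigma_b = ops$sigma_b %||% 100L,
    l_min = blk$l_min %||% 500L, l_max = blk$l_max %||% 3000L,
    overlap = blk$overlap %||% 40L,
    t_gc = y$t_gc %||% 0.55,
    codon_table = table
  )
  list(input = y$input, output = y$output %||% ".", config = cfg)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the fronts table of a run as TSV
#'
#' One row per archived design: its objective values, block count and block
#' boundaries (comma-separated end positions), for diffable reporting.
#'
#' @param run A `design_run`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_front_tsv <- function(run, path) {
  df <- tidy(run)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
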