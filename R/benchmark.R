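# Synthetic benchmark generator: CDS-annotated constructs assembled from
# transcription units (promoter + CDS + terminator) with Poisson-distributed
# component lengths and Beta-distributed per-component GC targets.

#' Benchmark generator settings
#'
#' The defaults emulate bacterial-scale constructs: CDS lengths are drawn
#' as Poisson(`lambda_codons` = 250) codons (roughly the mean gene length
#' in *E. coli*), regulatory components (promoter, terminator) as
#' Poisson(`lambda_regulatory` = 500) bp, and every component's GC target
#' from a Beta distribution with shape `beta_k * beta_t` and
#' `beta_k * (1 - beta_t)` (`k` = 150, `t` = 0.55), giving components of
#' ~55% GC on average with ~4% spread.
#'
#' @param num_tus Number of transcription units in the construct.
#' @param lambda_codons Poisson mean of the CDS codon count (including the
#'   start and stop codons).
#' @param lambda_regulatory Poisson mean of promoter/terminator lengths (bp).
#' @param beta_k,beta_t Beta concentration and mean of per-component GC
#'   targets.
#' @param seed Optional integer RNG seed.
#' @return A `benchmark_spec` object.
#' @export
benchmark_spec <- function(num_tus, lambda_codons = 250,
                           lambda_regulatory = 500,
                           beta_k = 150, beta_t = 0.55, seed = NULL) {
  num_tus <- as.integer(num_tus)
  stopifnot(num_tus >= 1L, lambda_codons > 0, lambda_regulatory > 0,
    beta_k > 0, beta_t > 0, beta_t < 1
  )
  structure(
    list(
      num_tus = num_tus, lambda_codons = lambda_codons,
      lambda_regulatory = lambda_regulatory,
      beta_k = beta_k, beta_t = beta_t,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "benchmark_spec"
  )
}

#' Random DNA with a target GC fraction
#'
#' Each base is G or C with probability `gc_target` (uniform within
#' \{G, C\} and \{A, T\}).
#'
#' @param length Sequence length (>= 1).
#' @param gc_target GC probability per base.
#' @return A DNA string.
#' @export
random_dna_with_gc <- function(length, gc_target) {
  length <- as.integer(length)
  stopifnot(length >= 1L, gc_target >= 0, gc_target <= 1)
  is_gc <- runif(length) < gc_target
  bases <- ifelse(is_gc,
    c("G", "C")[sample.int(2L, length, replace = TRUE)],
    c("A", "T")[sample.int(2L, length, replace = TRUE)]
  )
  paste(bases, collapse = "")
}

# Synonym tilt strength: weights are exp(-.gc_tilt * |GC(codon) - target|),
# strong enough that realized CDS GC tracks the target within the limits
# the genetic code allows.
.gc_tilt <- 12

#' Random coding sequence with a target GC fraction
#'
#' Starts with ATG and ends with a random stop codon; interior amino acids
#' are uniform over the 20, and for each amino acid the synonymous codon is
#' drawn with probability proportional to an exponential tilt toward the GC
#' target, so the realized CDS GC approaches the target as far as the code
#' allows.
#'
#' @param n_codons Total codon count including start and stop (>= 3).
#' @param gc_target Target GC fraction.
#' @return A DNA string of length `3 * n_codons` translating with no
#'   internal stop.
#' @export
random_cds <- function(n_codons, gc_target) {
  n_codons <- as.integer(n_codons)
  stopifnot(n_codons >= 3L, gc_target >= 0, gc_target <= 1)
  aas <- setdiff(names(.syn_families), "M") # interior aa, Met only at start
  interior <- sample(aas, n_codons - 2L, replace = TRUE)
  codons <- vapply(interior, function(aa) {
    fam <- .syn_families[[aa]]
    w <- exp(-.gc_tilt * abs(.codon_gc_n[fam] / 3 - gc_target))
    .sample_prob(fam, w)
  }, character(1))
  stop_codon <- .sample1(.stop_codons)
  paste(c("ATG", codons, stop_codon), collapse = "")
}

#' @noRd
.sample_prob <- function(v, w) v[sample.int(length(v), 1L, prob = w)]

#' Generate a synthetic annotated construct
#'
#' Concatenates `num_tus` transcription units, each a promoter, a CDS and a
#' terminator, with lengths and per-component GC targets drawn from the
#' spec's distributions. CDS features are annotated at their construct
#' coordinates (plus strand).
#'
#' @param spec A [benchmark_spec()].
#' @return An [annotated_sequence()] carrying a `components` attribute: a
#'   tibble of per-component coordinates and GC targets for provenance.
#' @export
generate_construct <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  parts <- character(0)
  comp_rows <- list()
  cds_rows <- list()
  pos <- 0L
  for (tu in seq_len(spec$num_tus)) {
    for (role in c("promoter", "cds", "terminator")) {
      gc_target <- rbeta(1L, spec$beta_k * spec$beta_t,
        spec$beta_k * (1 - spec$beta_t)
      )
      if (role == "cds") {
        n_codons <- max(3L, rpois(1L, spec$lambda_codons))
        s <- random_cds(n_codons, gc_target)
      } else {
        len <- max(1L, rpois(1L, spec$lambda_regulatory))
        s <- random_dna_with_gc(len, gc_target)
      }
      n <- nchar(s)
      comp_rows[[length(comp_rows) + 1L]] <- tibble(
        tu = tu, role = role, start = pos, end = pos + n,
        length = n, gc_target = gc_target
      )
      if (role == "cds") {
        cds_rows[[length(cds_rows) + 1L]] <- tibble(
          start = pos, end = pos + n, strand = "+"
        )
      }
      parts <- c(parts, s)
      pos <- pos + n
    }
  }
  out <- annotated_sequence(
    paste(parts, collapse = ""),
    cds = dplyr::bind_rows(cds_rows)
  )
  attr(out, "components") <- dplyr::bind_rows(comp_rows)
  out
}

#' Generate a benchmark dataset of synthetic constructs
#'
#' Produces `per_count` constructs for each transcription-unit count,
#' reproducibly from `seed`, optionally writing each construct as a GenBank
#' file.
#'
#' @param tu_counts Integer vector of TU counts.
#' @param per_count Constructs per TU count.
#' @param seed Optional integer seed.
#' @param out_dir Optional directory to write GenBank files into (created
#'   if missing).
#' @param ... Passed on to [benchmark_spec()] (e.g. `lambda_codons`).
#' @return A list with `constructs` (named list of
#'   [annotated_sequence()]s) and `manifest` (tibble: name, file, TU count,
#'   length, CDS count, GC fraction).
#' @export
generate_dataset <- function(tu_counts = c(5L, 10L, 20L), per_count = 10L,
                             seed = NULL, out_dir = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  constructs <- list()
  rows <- list()
  for (tu in as.integer(tu_counts)) {
    for (rep in seq_len(per_count)) {
      name <- sprintf("tu%02d_rep%02d", tu, rep)
      con <- generate_construct(benchmark_spec(tu, ...))
      constructs[[name]] <- con
      file <- NA_character_
      if (!is.null(out_dir)) {
        file <- file.path(out_dir, paste0(name, ".gb"))
        write_genbank(con, file, name = name)
      }
      rows[[length(rows) + 1L]] <- tibble(
        name = name, file = file, tu_count = tu,
        length = nchar(con$seq), n_cds = nrow(con$cds),
        gc = gc_content(con$seq)
      )
    }
  }
  list(constructs = constructs, manifest = dplyr::bind_rows(rows))
}
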