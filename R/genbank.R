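# Minimal GenBank flat-file reader/writer for CDS-annotated constructs.
# Only the subset of the format the package emits and consumes is handled:
# LOCUS, single-interval CDS features (with complement()), ORIGIN.

#' Read a CDS-annotated construct from a GenBank file
#'
#' The sequence is upper-cased and CDS features are extracted with strand,
#' converting GenBank 1-based inclusive coordinates to the package's
#' 0-based half-open convention. Records without CDS features load with a
#' warning (block-only objectives remain usable); ambiguity codes in the
#' sequence are an error. Multi-segment `join()` locations are not
#' supported.
#'
#' @param path Path to a GenBank file.
#' @return An [annotated_sequence()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  origin <- grep("^ORIGIN", lines)
  if (length(origin) == 0L) stop("no ORIGIN section in GenBank file", call. = FALSE)
  origin <- origin[1L]
  seq_lines <- lines[(origin + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  cds <- list()
  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 1L && feat_start < origin) {
    block <- lines[(feat_start + 1L):(origin - 1L)]
    # feature header lines: 5 spaces, key, spaces, location
    hdr <- grep("^ {5}\\S", block)
    for (i in hdr) {
      m <- regmatches(block[i], regexec("^ {5}(\\S+)\\s+(\\S+)", block[i]))[[1L]]
      if (length(m) < 3L || m[2L] != "CDS") next
      loc <- m[3L]
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("^join\\(", loc)) {
        loc <- sub("^join\\((.*)\\)$", "\\1", loc)
        if (grepl(",", loc, fixed = TRUE)) {
          stop("multi-segment join() CDS locations are not supported", call. = FALSE)
        }
      }
      if (!grepl("^<?\\d+\\.\\.>?\\d+$", loc)) {
        stop(sprintf("unsupported CDS location '%s'", m[3L]), call. = FALSE)
      }
      ends <- as.integer(regmatches(loc, gregexpr("\\d+", loc))[[1L]])
      cds[[length(cds) + 1L]] <- tibble(
        start = ends[1L] - 1L, end = ends[2L], strand = strand
      )
    }
  }
  if (length(cds) == 0L) {
    warning("GenBank record has no CDS features; only block objectives are usable",
      call. = FALSE
    )
    return(annotated_sequence(seq))
  }
  annotated_sequence(seq, cds = dplyr::bind_rows(cds))
}

#' Write a construct (or redesigned solution) as a GenBank file
#'
#' @param x An [annotated_sequence()] or `design_solution`.
#' @param path Output path.
#' @param name Locus name.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path, name = "construct") {
  if (inherits(x, "design_solution")) {
    seq <- solution_sequence(x)
    cds <- x$cds
    blocks <- solution_blocks(x)
  } else if (inherits(x, "annotated_sequence")) {
    seq <- x$seq
    cds <- x$cds
    blocks <- NULL
  } else {
    stop("x must be an annotated_sequence or design_solution", call. = FALSE)
  }
  n <- nchar(seq)
  out <- c(
    sprintf(
      "LOCUS       %-16s%12d bp    DNA     linear   SYN %s",
      name, n, toupper(format(Sys.Date(), "%d-%b-%Y"))
    ),
    "DEFINITION  synthetic construct.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  if (nrow(cds) > 0L) {
    for (i in seq_len(nrow(cds))) {
      loc <- sprintf("%d..%d", cds$start[i] + 1L, cds$end[i])
      if (cds$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out,
        sprintf("     CDS             %s", loc),
        sprintf("                     /label=\"cds_%d\"", i)
      )
    }
  }
  if (!is.null(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      out <- c(out,
        sprintf(
          "     misc_feature    %d..%d", blocks$start[i] + 1L, blocks$end[i]
        ),
        sprintf("                     /label=\"block_%d\"", i)
      )
    }
  }
  out <- c(out, "ORIGIN")
  lower <- tolower(seq)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    from <- seq(s, min(s + 59L, n), by = 10L)
    chunk <- substring(lower, from, pmin(from + 9L, n))
    out <- c(out, sprintf("%9d %s", s, paste(chunk, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
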