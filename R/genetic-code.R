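# Standard genetic code tables, derived once from Biostrings::GENETIC_CODE.
# All lookups are named vectors so operator inner loops stay vectorized.

.codon_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

.stop_codons <- names(.codon_aa)[.codon_aa == "*"]
.sense_codons <- names(.codon_aa)[.codon_aa != "*"]

# codon -> synonymous family (sense codons only)
.syn_families <- split(.sense_codons, .codon_aa[.sense_codons])

# codon -> number of G/C bases (0..3)
.codon_gc_n <- vapply(
  strsplit(names(.codon_aa), ""),
  function(b) sum(b %in% c("G", "C")),
  integer(1)
)
names(.codon_gc_n) <- names(.codon_aa)

# codon -> synonym with the most / fewest G+C bases (ties broken
# alphabetically for reproducibility)
.extreme_syn <- function(which_max) {
  out <- character(length(.sense_codons))
  names(out) <- .sense_codons
  for (fam in .syn_families) {
    gcn <- .codon_gc_n[fam]
    pick <- if (which_max) fam[order(-gcn, fam)][1L] else fam[order(gcn, fam)][1L]
    out[fam] <- pick
  }
  out
}
.syn_max_gc <- .extreme_syn(TRUE)
.syn_min_gc <- .extreme_syn(FALSE)
.syn_max_gc_n <- .codon_gc_n[.syn_max_gc]
names(.syn_max_gc_n) <- names(.syn_max_gc)
.syn_min_gc_n <- .codon_gc_n[.syn_min_gc]
names(.syn_min_gc_n) <- names(.syn_min_gc)

.complement_map <- c(A = "T", C = "G", G = "C", T = "A")
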