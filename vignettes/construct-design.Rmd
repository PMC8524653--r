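---
title: "Multi-objective design of synthesizable DNA constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective design of synthesizable DNA constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaforge)
```

## The problem

A DNA construct designed on a screen still has to be manufactured: chemical
synthesis limits both the length and the base composition of each fragment,
so a long construct must be split into blocks, recoded where its composition
is hostile to synthesis, and then reassembled (here, by Gibson assembly,
which requires adjacent fragments to share terminal homology). Recoding and
partitioning interact — fixing GC content can spoil codon usage, splitting
relaxes composition constraints but multiplies assembly cost — so there is
rarely a single best design. dnaforge treats the task as a multi-objective
optimization problem over candidate designs $z = (s, b)$, a construct
sequence $s$ plus an ordered block partition $b$, and returns a *set* of
Pareto-optimal trade-offs rather than one answer.

All objectives are minimized. A design $z_1$ dominates $z_2$ when it is no
worse in every objective and strictly better in at least one; the archive
returned by a run contains mutually non-dominated designs only.

## Objectives

Four interpretable objectives cover the common design-for-manufacturing
requirements:

* **GC content** — $\sum_{b \in B(z)} |T_{GC} - GC(b)|$, the summed absolute
  deviation of each block's GC fraction from the target $T_{GC}$
  (default 0.55). Zero when every block sits at the target.
* **Codon usage** — $\sum_{c \in C(z)} (Q(aa(c)) - q(c))$ over all CDS
  codons, where $Q$ is the usage-table frequency of the amino acid's most
  frequent codon and $q$ the frequency of the codon actually used. We read
  $q$ as the *table* frequency of the chosen codon (not its empirical
  frequency within the design); this is the only reading under which the
  stated bounds hold — the objective is zero exactly when every codon is
  modal, and maximal when every codon is the rarest synonym.
* **Block length variance** — the population variance of block lengths;
  homogeneous fragments assemble more reliably.
* **Block count** — the number of fragments to synthesize.

Each objective carries an ideal and a nadir estimate
(`estimate_bounds()`). Variance and count have closed forms
($(l_{max}-l_{min})^2/4$; $\lceil L/l_{max}\rceil$ and
$\lfloor L/l_{min}\rfloor$ — the count bounds are integer-rounded because
block counts are integers). The GC nadir is heuristic: every CDS codon is
swapped to the synonym whose GC is furthest from the target and the
sequence is cut into the maximum admissible number of blocks. Because it is
heuristic, a run may occasionally exceed it; it is treated as a
normalization reference, not a proven bound.

## Edit operators

Candidate designs evolve by four local moves, each applied to a single
random CDS or block (one edit per clone per iteration, operators drawn
uniformly among those relevant to the active objectives):

* **GC recoding** (`edit_gc`): iterated single-codon synonymous swaps
  toward $T_{GC}$ on one random CDS. Moves continue while the accumulated
  GC change stays within `sigma_gc` (an absolute GC fraction, default
  0.05), so one move may overshoot by at most one codon (3 nt / CDS
  length); the walk also stops within half a codon of the target or when no
  synonym improves. We note the direction of each swap follows the
  operator's purpose — raise GC when below target, lower when above.
* **Codon recoding** (`edit_codon`): each codon of one random CDS is
  replaced by the modal synonym with probability `sigma_c` (default 0.25).
* **Block split / join** (`edit_block_split`, `edit_block_join`): cut
  points land on a `sigma_b` grid (default 100 nt) and both parts must
  respect the synthesis limits `l_min`/`l_max` (defaults 500 and 3000 nt);
  a join that would exceed `l_max` moves the boundary instead of merging.

Stop codons and a leading ATG are never recoded, so the silent-edit
invariant holds trivially at the boundaries; minus-strand CDS features are
reverse-complemented before codon-level work and written back in place.
The operator defaults above are package defaults chosen to be reasonable
for bacterial-scale constructs; all are configurable.

## The optimizer

`optimize_design()` runs an elitist evolutionary loop: an initial pool of
`n` clones of the input with diverse random partitions (target mean block
length uniform in $[l_{min}, l_{max}]$, boundaries jittered on the
`sigma_b` grid); each iteration clones the pool, edits every clone once,
evaluates, and keeps the best `n` of `2n` by domination count and crowding
distance. The crowding distance normalizes neighbour gaps by the running
extremes of each objective observed so far in the run; the two extreme
designs per objective get infinite distance (the standard convention —
the boundary members are otherwise undefined), and ties break by insertion
order so runs are bit-reproducible given a seed.

Every evaluated solution also feeds a bounded **archive** of capacity `m`
that retains non-dominated designs that selection would discard. Two
pragmatic choices: the archive collapses duplicate objective vectors
(duplicates add no trade-off information to a bounded store), and capacity
pruning drops the `size − m` smallest-crowding members in one pass rather
than re-ranking after each single eviction. With ample capacity the archive
provably equals the non-dominated subset of the full evaluation log (a
property the tests audit by brute-force rescan).

## Quality metrics

`hypervolume()` measures the region of the ideal–nadir box weakly
dominated by a front — an exact sweep in 2-D and exact recursive slicing
along the last objective for three or more dimensions, which is practical
for the small fronts a bounded archive produces (a general exact
high-dimensional algorithm is out of scope). The normalized hypervolume
NV divides by the box volume, so NV is 1 for a front at the ideal point and
0 at the nadir. The box orientation matters: the published description of
the reference point admits two readings, and only measuring the region
*between the front and the nadir* makes NV → 1 for good fronts, so that
orientation is implemented.

`global_pareto_union()` pools fronts from independent runs into an
approximate global Pareto set, and `r_theta()` reports the share of that
set one setting recovered, divided by `min(|global set|, pool size)` —
a normalization chosen so the share is 1 when a setting finds everything
the pool could possibly hold; membership is exact objective-vector
equality.

## The synthetic benchmark

`generate_construct()` emulates modular bacterial constructs: each
transcription unit is promoter + CDS + terminator, with promoter and
terminator lengths Poisson(500) bp, CDS lengths Poisson(250) codons
(including start and stop — roughly the mean *E. coli* gene length), and
every component's GC target drawn from Beta(150·0.55, 150·0.45), i.e.
55% ± 4% GC. Regulatory sequence is per-base Bernoulli at the component's
GC target; CDS synonyms are drawn with an exponential tilt toward the
target (weight $e^{-12\,|GC(codon)-t|}$, a one-time calibration giving
realized CDS GC within ±0.05 of a 55% target), since the genetic code
bounds what CDS GC can reach. Codon-usage tables for benchmark runs draw
uniform weights per synonymous family and normalize.

What the generator does *not* emulate: real promoter/terminator motifs,
repeats, restriction sites, homopolymers, secondary structure, or
organism-specific codon bias. Passing benchmarks therefore demonstrate the
optimizer's search behaviour on realistic length/composition statistics,
not performance on any particular genome's sequence features.

Canned problems P1–P4 pair the GC objective with block count (P1), block
variance (P2), variance + count (P3) and codon usage + count (P4).

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GenBank's 1-based
  inclusive coordinates convert at the I/O boundary.
* Ambiguity codes are rejected at load: objectives and operators are
  defined over {A, C, G, T} only. Circular sequences and non-standard
  genetic codes are unsupported.
* A degenerate objective (equal running min and max) contributes zero
  crowding distance; a zero-volume normalization box is an error rather
  than a silent NaN.
* Sequences shorter than `l_min` cannot be partitioned and are rejected.
* The GC walk has a hard cap of 10× the CDS codon count non-improving
  draws, guaranteeing termination even on pathological inputs.

## Problem sizes used in the test-suite

The packaged checks run at desk scale, chosen so the full suite completes
in minutes on one core: operator fuzzing uses 10^4 applications on 3-TU
constructs; optimizer audits use pools of 10–20 over 20–60 iterations; the
design-quality reproduction uses three 5-TU constructs × three seeds per
problem with `n = 100`, `t_max = 200`, `m = 100`. Larger constructs
(10–20 TUs) are generated by the same code paths and differ only in cost.

## Known limitations

* The GC nadir is heuristic (above), so NV is computed against an
  estimate; all NV values in a comparison should use the same bounds.
* With a randomly generated codon-usage table, modal codons average
  near 50% GC, so the codon-usage and GC objectives conflict only weakly
  on ~55%-GC constructs; fronts for P4 can then collapse toward the ideal
  corner. Against a strongly biased organism table the conflict — and a
  broad front — reappears.
* Exact objective-vector equality in `r_theta()` is brittle under
  floating-point noise if fronts from different software are mixed; within
  this package all values derive from integer counts and exact sums, so
  equality is well defined.
* The evolutionary search carries no convergence guarantee; seeds and
  iteration budgets are part of any reproducible protocol.
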