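# dnaforge

Multi-objective design of synthesizable DNA constructs.

## What it does, and for whom

Synthetic biologists who design constructs of many kilobases face a gap
between *design* and *build*: chemical synthesis limits fragment length and
base composition, so a construct must be partitioned into blocks, recoded
where composition is hostile, and reassembled (e.g. by Gibson assembly).
Those requirements conflict — recoding for GC spoils codon usage, splitting
eases composition limits but multiplies assembly cost — so dnaforge treats
construct engineering as a multi-objective optimization problem and returns
a set of Pareto-optimal trade-off designs instead of a single answer.

A candidate design is $z = (s, b)$: a construct sequence $s$ (only silent,
synonymous edits of annotated CDSs are allowed) plus an ordered block
partition $b$ with every block length in $[l_{min}, l_{max}]$. Designs are
compared by Pareto dominance over $k$ minimized objectives
$F = (f_1, \dots, f_k)$:

* GC content: $f_1(z) = \sum_{b \in B(z)} |T_{GC} - GC(b)|$
* codon usage: $f_2(z) = \sum_{c \in C(z)} \big(Q(aa(c)) - q(c)\big)$
* block length variance: $f_3(z) = \frac{1}{|B(z)|}\sum_{b}(l(b)-\bar l)^2$
* block count: $f_4(z) = |B(z)|$

An elitist evolutionary loop (pool of $n$ clones, one random edit per clone
per iteration, selection by domination count then crowding distance,
$T_{max}$ iterations) maintains a bounded archive of every non-dominated
design encountered. Front quality is scored by the hypervolume indicator
normalized to the ideal–nadir box ($NV \in [0,1]$, 1 = front at the ideal
point), and cross-run optimality by $R_\theta$, the recovered share of the
pooled global Pareto set. A synthetic benchmark generator builds
CDS-annotated constructs from transcription units (promoter + CDS +
terminator) with Poisson-distributed component lengths and Beta-distributed
GC targets.

See `vignettes/construct-design.Rmd` for the model, parameter meanings and
design choices.

## Worked example

```r
library(dnaforge)

# a synthetic 5-transcription-unit construct, ~9 kb, annotated CDSs
con <- generate_construct(benchmark_spec(5, seed = 11))
con
#> <annotated_sequence> 8958 bp, 5 CDS feature(s), GC 0.531

# redesign for GC 0.55, homogeneous blocks, few fragments (problem P3)
cfg <- design_config("P3", n = 50, t_max = 100, seed = 42)
run <- optimize_design(con, cfg)
glance(run)
#> # A tibble: 1 × 5
#>   iterations pool_size archive_size n_objectives    nv
#> 1        100        50            3            3 0.993

tidy(run)
#> # A tibble: 3 × 6
#>   design      gc block_variance block_count n_blocks block_ends
#> 1      1 0.0105              0            3        3 2986,5972,8958
#> 2      2 0.00975           392            3        3 3000,6000,8958
#> 3      3 0.0105            131.           3        3 3000,5972,8958
```

The archive holds three trade-off designs, all meeting the synthesis limits
with 3 blocks: design 1 has perfectly equal block lengths (variance 0) at a
summed GC deviation of 0.0105 (~0.35 GC percentage points per block from
the 55% target); design 2 trades a little variance for slightly better GC.
`nv = 0.993` says the front dominates 99.3% of the estimated
ideal–nadir box. Export a chosen design as a GenBank file plus
Gibson-ready fragments (40 nt terminal overlaps by default):

```r
export_design(run$archive[[1]], cfg, "out", name = "demo")
#>   fragment         start   end length
#> 1 demo_fragment_01     0  3026   3026
#> 2 demo_fragment_02  2986  6012   3026
#> 3 demo_fragment_03  5972  8958   2986
```

`autoplot(run, "front")` and `autoplot(run, "history")` draw the archived
front and the convergence of each objective. A thin command-line wrapper
(`inst/cli/dnaforge.R`) exposes `design` (GenBank + YAML config in,
fronts/history/designs out), `benchmark` (dataset generation) and
`evaluate` (NV and $R_\theta$ from front tables).

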