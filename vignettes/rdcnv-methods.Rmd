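---
title: "Read-depth CNV detection: model, normalization and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV detection: model, normalization and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rdcnv` detects copy number variants (CNVs) from the read depth of a single
whole-genome sequencing sample, without a matched control. This vignette
describes the statistical model, every tunable parameter with its default,
the choices made where the design was genuinely open, and the limits of what
the synthetic fixtures can demonstrate.

## The signal and its biases

Per-base read depth `r_i` counts the retained reads whose aligned span
covers base `i` (pileup convention; unmapped, secondary, supplementary,
duplicate and QC-fail records are dropped, MAPQ 0 reads are kept). A
deletion depresses depth, a duplication elevates it, but two sequencing
biases distort the signal:

* **GC bias.** PCR acts on the whole sequenced fragment, so coverage at a
  base depends on the G+C content of every fragment that can cover it.
  Rather than a fixed window, each base receives an insert-weighted GC
  content `h_i = sum_j w_j a_j / sum_j w_j`, where `a_j` indicates G/C and
  `w_j` counts the distinct placements of a mean-insert-length fragment that
  cover both `i` and `j` (`L - |i - j|` in the chromosome interior,
  truncated near the ends so only placements that fit the sequence count).
  N bases contribute to neither sum.
* **Dinucleotide repeat bias.** Tandem two-base motifs as short as 20 bases
  can show motif-specific coverage suppression or inflation that GC
  correction does not capture.

Classical per-bin mean scaling (`r_norm = r * m / m_GC`) equalizes bin means
but leaves the **variance** varying with GC, which inflates false positives
in high-variance bins and costs sensitivity in low-variance ones. The
`gc_mean_normalize_diagnostic()` function reproduces this phenomenon on
simulated data; it takes no part in calling.

## Quantile normalization to standard-deviation units

Bases are grouped into bins by discretized `h` (width 0.01, 101 levels) and
by the mapping-quality stratum of their 100-base window (low when the mean
MAPQ is below 5). Within each bin, bases are ranked by raw depth (ties
broken deterministically by genomic position) and the rank proportion

```
p = R / n        if 2R <= n
p = (n - R) / n  otherwise        (numerator floored at 0.5 when zero)
```

maps through the inverse standard-normal CDF, with the sign restored so the
result `x_i` is monotone in rank and the median rank maps to exactly 0.
Every bin then has mean ~0 and SD ~1 regardless of its raw dispersion —
both the mean and the variance of the GC bias are removed, and no
parametric assumption is made about the depth distribution.

Bins need at least 100 members; smaller GC levels are merged into the
nearest adjacent level of the same stratum. To stop coverage spikes from
dominating, members whose depth exceeds twice their chromosome's mean have
their rank averaged with the (interpolated) rank that a depth of exactly
twice the mean would take in the bin.

Motifs whose runs (maximal period-2 repeats of two distinct bases, length
at least 20, at least 50 occurrences genome-wide) have mean coverage more
than 1.5 genome depth standard deviations from the genome mean are flagged
biased. Bases within half an insert of a biased run are removed from their
GC bin and normalized in (motif, distance) bins instead, with distance
discretized in 10-base steps from the nearest run boundary (0 inside the
run); undersized distance bins merge toward larger distances. Each base is
normalized by exactly one bin.

## Excessive-coverage masking and the two pipelines

Complex regions produce stretches of extreme coverage that both generate
false calls and corrupt the sampled window distributions. The genome is cut
into 10,000-base blocks; a block is *high* when its mean depth (non-N
bases) strictly exceeds twice the chromosome average. A *cluster* is a
maximal interval that begins and ends on high blocks, has more than 25%
high blocks, and contains at least four of them. Maximality by interval
inclusion makes the definition symmetric under coordinate reversal; the
spanning-interval semantics follows from the two stated constraints.

Pipeline 1 excludes cluster bases from binning, window sampling and
scanning (the exclusion is dilated by one mean insert, because fragments
spanning a cluster edge leave an excess-coverage shoulder just outside the
block-aligned cluster); pipeline 2 runs unmasked so that CNVs inside
clusters remain discoverable. The final call set is the union, with
same-type overlapping calls merged into their spanning interval and tagged
`both`.

Bases within one mean insert of an N run are excluded from binning in both
pipelines: no fragment spans an N, so depth ramps to zero next to every gap
for purely structural reasons, and those bases would otherwise produce a
deterministic spurious deletion at each gap edge.

## The sliding-window search

For each window size `l` on a 20-point geometric grid between `w_min = 100`
and `w_max = 10000`, 1000 window positions free of excluded bases are
sampled and the mean and SD of the window-averaged `x` recorded; parameters
for intermediate sizes are interpolated on the log-size scale (the SD is
approximately a power law in `l`, and estimating all ~9900 sizes
individually adds nothing but cost).

A base `j` is a candidate breakpoint when its raw depth is at least 1.3
times (duplication) or at most 0.70 times (deletion) the mean raw depth of
its own bin — the stated diploid ratios, exposed as `dup_ratio`/`del_ratio`
— and at least half of `[j, j + w_min)` is abnormal in the same direction.
From each candidate the window grows in one-base steps while at least half
its bases stay abnormal; at each size the window mean of `x` is converted
to a z-statistic against the sampled distribution, and the call fires when
the one-sided normal tail probability in the candidate's direction is below
`alpha = 1e-6`. (Comparing a z-score itself to `1e-6` would be
dimensionally inconsistent; the tail-probability reading is the only
coherent one.) If the window reaches `w_max` while significant, a
`w_max`-sized window slides right while it stays significant and
half-abnormal.

**Breakpoint refinement.** The growth and extension rules above bound the
call, but both can overshoot: under the 0.70/1.3 screen roughly a fifth of
ordinary 10x bases are "abnormal" by chance, so the last abnormal base of a
window is nearly always a background base. The reported end breakpoint is
therefore the last maximizer of `(abnormal count) - (span / 2)` over the
call — the changepoint where local abnormal density crosses one half, so a
deviation costs in proportion to its distance from the event — and the
start is the mirrored leftmost maximizer. Both refined breakpoints are by
construction abnormal bases. The most extreme z over the sweep is reported;
scanning resumes after the call, so calls never nest.

## Synthetic fixtures

The generator builds references with a linear GC gradient (0.35-0.60 by
default, piecewise constant per kb), embedded dinucleotide runs, and one N
gap per chromosome; fragments are sampled with a unimodal fragment-GC
exposure curve, optional per-motif suppression, and optional hotspot
multipliers, the latter two adding or removing fragments relative to the
GC-only baseline so target coverage is preserved. Copy number thins or
replicates each read by `cn/2` at the read center, which keeps depth
transitions sharp at the read-length scale. Everything is deterministic
given the seed, down to the bytes of the FASTA/BAM written by
`write_fixture()`.

Defaults mirror a realistic benchmark design: two 2-Mb chromosomes, 10x
coverage from paired 100-base reads on 500-base fragments, ten heterozygous
deletions and ten duplications of 3-10 copies with lengths log-uniform
between 500 and 10,000 bases.

What the fixtures do **not** emulate: sequencing errors and base
qualities, alignment ambiguity (MAPQ is constant except in designated
regions), junction-spanning fragments at breakpoints, microhomology or
repeat-mediated breakpoint complexity, and chromosome-scale coverage waves.
Passing tests demonstrate the algorithmic properties of the method on
idealized data, not its field accuracy on real libraries.

## What recovery to expect at 10x

Power at these study conditions is limited by two quantities the tests make
visible. First, the normalized depth of a heterozygous deletion base at 10x
averages only about -1.6 to -1.7 SD units (the overlap between Poisson
depth at 5x and 10x), and rank capping saturates duplication bases near
+2 to +3. Second, paired 100-base reads from one fragment make window means
autocorrelated with an integrated correlation length of roughly 250 bases,
so a window of `l` bases contributes about `l/250` independent terms. At
`alpha = 1e-6` (|z| > 4.75) a heterozygous deletion therefore needs roughly
2 kb to be reliably callable, and sub-kilobase events of either type are
frequently missed; breakpoints of detected events are typically localized
to some tens of bases but occasionally attach to adjacent chance coverage
dips, which dominate the mean breakpoint error. The acceptance suite and
`scripts/acceptance.R` compute the realized sensitivity, FDR and breakpoint
error on the default fixture rather than assuming them.

## Numerical and convention notes

* Coordinates are 1-based closed internally (the R/Bioconductor
  convention); BED output is 0-based half-open.
* The inverse normal CDF is `qnorm`, not a precomputed table.
* Windows with no reads have undefined mapping quality and fall in the
  high-MQ stratum: treating them as MAPQ 0 would send homozygous deletions
  into their own low-MQ bins, where they would self-normalize to `x ~ 0`
  and become undetectable.
* `sigma_l = 0` (constant tracks) is floored at 1e-12 in the z computation;
  degenerate bins of constant depth produce `x = 0` rows rather than
  errors.
* Window-distribution sampling, fixture construction and reference
  generation all draw from seeded local RNG streams (`withr::with_seed`),
  so identical inputs and seeds give byte-identical call files.
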