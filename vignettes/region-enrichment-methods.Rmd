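---
title: "Width-matched permutation tests for region-set enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Width-matched permutation tests for region-set enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xregenrich)
```

## The scientific question

Association studies restricted to the X chromosome produce a set of loci with
suggestive disease signals. A natural follow-up question is whether the
genomic regions around those loci are unusually rich in regulatory non-coding
elements — long non-coding RNAs, circular RNAs, microRNAs, superenhancers —
compared to what equally sized stretches of the same chromosome would carry by
chance. `xregenrich` answers this with a permutation test whose null model is
*width- and count-matched random placement*: every randomized region set has
exactly the same number of regions and exactly the same region widths as the
query set, differing only in where those regions fall on the chromosome. This
controls for the single most important confounder of overlap counting — the
total amount and granularity of sequence interrogated — while leaving the
positions free.

A second, independent test asks whether the genes implicated by the
association signals are enriched in a curated list of differentially
methylated genes, using bootstrap resampling of candidate-sized gene draws
from a user-supplied universe.

## The permutation model

Let the query set be $R = \{r_1, \dots, r_m\}$, disjoint intervals on a
chromosome of length $L$, and let $T$ be an annotation track of elements. The
observed statistic is

$$ c_\mathrm{obs} = \#\{\, t \in T : t \text{ shares} \ge 1 \text{ base with some } r_i \,\}, $$

with each element counted at most once no matter how many regions it touches
(deduplication by element id, so two coordinate-identical elements with
distinct ids still count as two). Overlap requires a shared base: intervals
that merely touch end-to-start ("book-ended") do not overlap, although
`merge_intervals()` deliberately unions them when constructing regions.

For iterations $i = 1, \dots, n$ the sampler draws a random set $R_i$
preserving the width multiset of $R$, computes the count $c_i$ of the same
track against $R_i$ — all tracks in a run share the same $R_i$ per iteration —
and the empirical p-value is the *same-or-larger* fraction

$$ p = \frac{k}{n}, \qquad k = \#\{\, i : c_i \ge c_\mathrm{obs} \,\}. $$

Equality counts: an iteration tying the observed count is evidence against
enrichment. The reported two-decimal p-value is therefore the percent row of
the result table divided by 100 (24.5% of qualifying iterations prints as
0.25). Reproducing that correspondence requires rounding the exact rational
$k/n$ with ties away from zero — `format_p()` does this in integer
arithmetic, because binary floating point cannot represent 0.245 and
round-half-even would print 0.24. A conservative estimator $(k+1)/(n+1)$,
which can never return zero, is available behind `conservative = TRUE`; the
default is the plain fraction because that is what the percent-to-p
correspondence implies.

The null mean and SD reported per track use the sample (n−1) SD — a
convention choice recorded in the output rather than a modeling claim.

## The sampler

`sample_region_set()` places one interval per query width, uniformly over all
start positions that keep the interval fully on the chromosome, outside any
exclusion zones (e.g. assembly gaps, supplied as BED), and — by default —
disjoint from intervals already placed in the same set. Disjointness mirrors
the query (merged association regions are disjoint by construction) and
avoids double-covering bases; `allow_overlap = TRUE` relaxes it. Placement is
rejection sampling with a cap (`max_attempts`, default 10,000 per region):
at the densities this analysis targets (~9.3 Mb of regions on a ~155 Mb
chromosome, ~6% occupancy) rejections are rare, and a cap failure is an
explicit error naming the offending width, never a silent width change.
Widths are placed in decreasing order; the synthetic query generator uses
the same routine, so query and null placements follow one distribution —
the exchangeability that the calibration property below relies on.

Randomness is organized as one root seed with per-iteration substreams: the
seed of iteration $i$ is a pure arithmetic function of (root seed, $i$).
Consequences: reruns are bit-exact, and materializing iterations 5–9 yields
exactly the sets a full run would produce at those indices. All seeds stay
within 32-bit integer range.

## From SNPs to regions

`build_regions_from_snps()` selects SNPs with association $p <$ `p_max`
(strict inequality; default $5 \times 10^{-4}$, a conventional suggestive
threshold), expands each to a symmetric window of `flank` bases (default
75 kb, so a singleton SNP yields a ~150 kb region — the scale typical of
association follow-up regions), and merges windows closer than `merge_gap`
(default 0: merge only on overlap or book-end). SNP positions are 1-based on
input, the association-output convention. How real studies convert SNPs to
regions varies (LD blocks, fixed windows, recombination intervals); the
flank-and-merge construction is an explicit modeling choice, not a
reconstruction of any particular study's undisclosed algorithm, and all three
knobs are exposed.

## Coordinates

Internally everything is a `GRanges`, 1-based closed, the Bioconductor
convention. BED input and output are 0-based half-open, converted only at the
`read_bed()`/`write_bed()` boundary, so BED round-trips are bit-exact and
overlap semantics are identical under either convention ($[a,b)$ and $[c,d)$
overlap iff $a < d$ and $c < b$). Readers tolerate LF and CRLF, skip
`#`/`track`/`browser` lines, and fail on malformed lines with the line
number.

## The gene-set bootstrap

`geneset_bootstrap()` measures the overlap of a candidate gene list with a
curated list, then resamples candidate-set-sized draws from the universe
*without replacement* (default) and reports the same-or-larger overlap
fraction. Without replacement, the null is exactly hypergeometric and the
bootstrap p converges to the tail $P(X \ge \mathrm{obs})$ — asserted in the
test suite against exhaustive subset enumeration at small sizes. Drawing
*with* replacement is available behind `replace = TRUE` for users who prefer
a classical bootstrap; a gene drawn twice still counts once toward the
overlap. The universe is deliberately user-supplied: results are sensitive
to it, and no sensible default exists. The package ships a nine-gene curated
list of differentially methylated genes in primary biliary cholangitis
(`curated_dmg_genes()`) as a convenience fixture.

## The synthetic-data generator

Because the real inputs of such analyses (full association tables,
annotation database snapshots) are typically not redistributable, every
stage is testable against synthetic data with *exactly* planted truths:

* `make_chromosome()` — a chrX-scale chromosome (default 155 Mb), optionally
  with disjoint exclusion zones covering an exact fraction of it.
* `make_query_regions()` — exactly `n_query_regions` (default 62) disjoint
  regions summing *exactly* to `query_total_width` (default 9.3 Mb). Widths
  are gamma draws (shape 1.65, giving a width CV near 0.78 — broad,
  right-skewed, like real association regions) rescaled to the target total;
  only the final width absorbs the rounding residue, keeping the others
  distribution-faithful while making totals assertable with equality.
* `make_annotation_track()` — element midpoints from a two-component
  density: weight 1 outside the query, weight `enrichment_fold` inside, so
  the expected in-query midpoint fraction is
  $fW_q / (fW_q + (L - W_q))$ — closed-form, hence directly testable. At
  fold 1 this is exactly uniform; at fold 0 elements are additionally
  clipped to the inter-region gap holding their midpoint, making planted
  depletion exact. Widths are uniform per class: point-like for miRNAs
  (22–100 bp), broad for superenhancers (10–50 kb).
* `make_snp_table()` — uniform background p-values plus positionally tight
  signal clusters (50 kb windows, centers ≥ 1 Mb apart) with p-values below
  the nominal threshold.
* `make_gene_universe()` — synthetic symbols with the candidate/curated
  overlap planted exactly.

Default track densities (280 lncRNA, 2900 circRNA, 160 miRNA, 5100
superenhancer elements) were chosen analytically so the expected null
overlap count, $n_\mathrm{el}(W_q + m\bar{w})/L$, lands at the scale typical
of chrX non-coding annotation against a ~6% query: tens of lncRNAs,
hundreds of circRNAs and superenhancers, around ten miRNAs.

All generators are pure functions of the scenario seed, with per-generator
substreams offset far above the null-ensemble iteration counters so scenario
streams and permutation streams never collide even at equal root seeds.

What the generator does *not* emulate: the spatial clustering of real
annotation databases (real circRNAs pile up on host genes; uniform placement
underdisperses null counts relative to real tracks), LD structure among
SNPs, sequence content, or strand. Passing calibration and power tests on
synthetic data therefore demonstrate correctness of the machinery and of the
statistic's distribution under its own null — not that any particular real
annotation is or is not enriched.

## Calibration and power, as tested

Two properties anchor the test suite at the study geometry (62 regions,
9.3 Mb, 155 Mb chromosome):

* **Calibration.** When the query itself is drawn from the null
  (`enrichment_fold = 1`), the empirical p over 500 scenario replicates
  (200 iterations each, one 2900-element track) is consistent with
  uniformity (Kolmogorov–Smirnov, $\alpha = 0.01$). The track is kept dense
  so the null count distribution is wide and ties between observed and null
  counts — which make the same-or-larger p conservative for coarse discrete
  statistics — are negligible.
* **Power.** A 10-fold planted circRNA-class enrichment is reported at
  $p \le 0.01$ in at least 95 of 100 replicates at 1,000 iterations each.

These replicate counts and iteration depths are the package's chosen
trade-off between statistical resolution and a test suite that runs in
minutes on one core.

## Numerical and degenerate-input choices

* Empty query after thresholding: a warning and an empty `GRanges`, not an
  error — pipelines should be able to report "nothing suggestive".
* Empty track: observed 0, null mean 0, $p = 1$.
* A width equal to the chromosome length has a single admissible placement
  and is placed there deterministically.
* Region summaries print kb/Mb at one decimal, ties away from zero, to
  match the reporting convention of the p-values.
* Duplicate explicit element ids in a BED file are an error (ids must be
  unique within a track); synthesized ids for unnamed coordinate-identical
  lines are disambiguated with suffixes so the element multiset survives a
  round-trip.

## Known limitations

* The null is placement-uniform; it does not match GC content, gene
  density, or replication timing, and no circular-shift null is offered.
  Enrichments driven by large-scale covariates of element density will look
  significant under this null — as they do in the published analyses this
  class of test descends from.
* Single chromosome by design; no multi-chromosome sampling.
* Strand-blind; no minimum-overlap-fraction option (one shared base
  counts, matching the "partially or totally overlapping" convention).
* With `n` iterations the smallest nonzero p is $1/n$; at the default 1,000
  iterations, p-values below 0.001 are reported as 0 unless
  `conservative = TRUE`.
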