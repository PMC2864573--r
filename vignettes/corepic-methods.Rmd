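---
title: "Methods: core promoter scanning, PIC occupancy statistics, and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core promoter scanning, PIC occupancy statistics, and the synthetic cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corepic)
library(dplyr)
```

`corepic` analyses promoter-array ChIP data for two general transcription
factors — TFIIB, whose promoter occupancy proxies preinitiation complex (PIC)
levels, and NC2, the TBP-binding repressor that competes with PIC assembly —
and relates factor occupancy to core promoter sequence architecture and gene
expression. This vignette documents the models, the parameters that matter,
the numerical conventions, and what the synthetic data generator does and
does not emulate.

## Coordinates and sequence conventions

Core promoter sequences cover positions −50..+50 with the TSS at +1 and no
position 0, the standard promoter-biology numbering. A 100-base string maps
index 1..50 to −50..−1 and 51..100 to +1..+50; because the numbering only
skips the label 0, adjacency in positions equals adjacency in the string, and
all motif windows convert to contiguous index runs. Scanning always operates
on the transcribed strand; minus-strand records supplied in genomic
orientation are reverse-complemented first (`orientation = "genomic"`).

## Motif classes

Seven classes are scanned with IUPAC degenerate patterns and
presence/absence semantics (overlapping hits of one class count once; the
leftmost anchor is reported):

| class | pattern | rule | mismatches |
|---|---|---|---|
| TATA | `TATAW` | first T fixed at −31 | 0 |
| TATA-like | `WWWW` | fully inside [−40, −20] | 0 |
| BREu | `SRCGCC` | occupies [−37, −32] | 0 |
| BREu-like | `SRCGCC` | occupies [−37, −32] | ≤ 1 |
| BREd | `RTDKKKK` | occupies [−25, −19], TATA promoters only | 0 (relaxed mode exposed) |
| INR | `YYANWY` | central A anywhere in [−4, +5] | 0 |
| DPE | `RGWYVT` | starts in [+28, +32] | 0 |

Design choices made where the window definitions were genuinely open:

- **BREu anchoring.** BREu/BREu-like are anchored positionally at
  [−37, −32] — immediately upstream of the canonical TATA location — rather
  than conditioned on an actual TATA hit. Conditioning would cap BREu
  frequency at TATA frequency, which contradicts observed cohorts where
  relaxed BREu exceeds TATA; positional anchoring keeps the two classes
  independent.
- **BREd window.** With the consensus T of `RTDKKKK` (pattern position 2) at
  −24, the element occupies [−25, −19]. BREd is only *evaluated* in TATA
  promoters because the element is defined relative to a located TATA box;
  in TATA-less promoters its position is not interpretable.
- **DPE window.** The canonical placement is "around +30"; the Drosophila
  definition's start window [+28, +32] is adopted and configurable
  (`motif_defs()`).
- **TATA tolerance.** The anchor is fixed at −31; a `tata_tolerance`
  argument widens it to ±w for exploratory scans but defaults to 0.
- Mismatch matching is monotone by construction (a hit at m mismatches is a
  hit at m+1), and `TATAW` is itself a W-run inside [−40, −20], so
  TATA ⇒ TATA-like holds identically — these are tested as invariants.

Frequencies are reported as raw counts plus percentages, together with a
`tata_like_only` row (TATA-like carriers without a TATA consensus), because
published "TATA-like" tallies can be read as inclusive or exclusive of TATA.

## Probe-signal model and scaling

Each promoter is covered by 15 probes tiling 1.5 kb at 100-bp spacing.
Arrays are centered by subtracting the one-step Tukey biweight location of
all probe log2 ratios: with M the median and S the raw median absolute
deviation, `u = (x − M)/(c·S + ε)`, weights `(1 − u²)²` for |u| < 1 (else 0),
estimate `Σwx/Σw`, falling back to M when all weights vanish. The constants
`c = 5`, `ε = 1e-4` are the array-analysis convention. Scaling is idempotent
up to the near-zero biweight mean of already-centered data (tested to
|mean| < 1e-9). The probeset **median** of scaled ratios is the promoter
occupancy score; medians of 15 values are insensitive to single-probe
artifacts.

**Peak calling** uses a threshold-run rule: the cut-off is
`mean + k·sd` with the *population* standard deviation (n denominator, for
determinism), and a peak is a maximal run of at least `min_run = 2`
consecutive positions strictly above it; the apex is the run maximum,
leftmost on ties. Zero-variance series yield zero peaks, not an error.
Because the thresholds are nested in k, peak sets at larger k are contained
in peaks at smaller k — the stringency tiers k = 1, 2, 2.5 reproduce the
usual ordering of peak counts. Whether published peak counts used per-series
or per-region standard deviations is not documented anywhere we know of;
this caller computes the threshold over the series it is given (array-wide
in `call_promoter_peaks()`).

**Binding profiles** bin strand-oriented probe offsets to the nearest
multiple of 10 bp (ties toward 0, so −55 → −50 and +55 → +50) and divide the
high-score probe count per bin by the number of available probes there. The
availability correction removes positional bias from uneven probe coverage;
bins with no available probes are omitted. `max1` mode rescales to a maximum
of 1 for profile-shape comparisons.

**Concordance** between replicates is the Pearson correlation of paired
promoter scores plus an overlap fraction: the share of one replicate's upper
5th-percentile set recovered in the other's upper 10th percentile.
Percentile thresholds use `stats::quantile` type 7 and include boundary
ties, so the sets are deterministic.

## Occupancy–expression statistics

- **Sliding windows.** Genes sorted by occupancy are partitioned into
  consecutive intervals of width = step (default 0.1 log2 units,
  non-overlapping; the published procedure fixes the step but not the
  width, and equating them is the simplest deterministic choice). Windows
  with fewer than 10 genes merge into the following window (trailing
  remainder merges backward). The reported r is the Pearson correlation of
  the window curve.
- **Quantile tables.** Occupancy deciles × expression quantiles, rows
  normalized to 1, plus the fraction of genes above the overall expression
  median per decile. Records with an absent detection call are excluded
  from all occupancy–expression statistics.
- **Bootstrap KS.** `D = sup|ECDF_a − ECDF_b|`; the null distribution is
  obtained by resampling the pooled data with replacement into the original
  group sizes, and `p = (1 + #{D* ≥ D})/(n_boot + 1)` — the +1 correction
  avoids p = 0 and the resampling null stays valid under ties. D is
  cross-checked against `stats::ks.test` in the tests; the bootstrap loop is
  seeded. Note that D lives on a lattice of width ~1/n, so the p-value is
  discrete; near-uniformity under the null (and the nominal 5% type-I rate)
  is a large-sample property and is verified at n = 100 and n = 30 per group
  respectively.
- **Rank-sum on positions.** `stats::wilcox.test` with normal
  approximation, tie correction and continuity correction.

## TFIIB/NC2 ratios and dominated sets

Log2 enrichments are converted to the linear scale (2^x) *before* averaging
within expression-percentile bins, and the ratio of bin means is reported. A
ratio of mean log-ratios can be negative or undefined, whereas per-gene
linear ratios are strictly positive — consistent with how such ratios are
reported in practice; adding a common constant to both log2 tracks leaves
every ratio unchanged (tested).

Dominated sets restrict to "active" genes — at or above the 60th percentile
in TFIIB occupancy, NC2 occupancy and expression simultaneously — rank them
by per-gene linear ratio `2^(tfiib − nc2)`, and return the top and bottom
`top_n`. Ties at the boundary break lexicographically by promoter id, so
selection is deterministic; the two sets are disjoint whenever
`top_n ≤ eligible/2`.

## TSS shape classification

Per-promoter tag-count vectors are classified as `single` (all tags within a
4-bp span), `dominant` (one position holds a strict majority of tags),
`multimodal` (at least two peaks ≥ 25 bp apart, each holding ≥ 20% of tags,
found greedily from the strongest position), else `broad`; single/dominant
are focused, broad/multimodal dispersed. The external classification this
follows publishes no thresholds, so the four numbers (4 bp, 0.5, 25 bp, 20%)
are operational choices exposed in code; `dominant` requires a *strict*
majority so that two equal half-share peaks classify as multimodal. The
classification is invariant under common position shifts.

## The synthetic cohort generator

A `cohort_blueprint` fixes: the number of promoters; the background GC of
core sequences (i.i.d. bases with P(G) = P(C) = gc/2); a planting table of
(promoter, class, anchor) motifs; a bivariate log-normal occupancy model
(per-factor log2 location/spread, inter-factor correlation, default 0.8);
a linear expression link (`expression = coupling · log2-TFIIB + noise`);
a Gaussian PIC footprint (center −50, spread 150 bp) that multiplies each
promoter's occupancy into its probe signals plus probe- and replicate-level
Gaussian noise; TSS shape labels with a tag-depth mean; and a seed. All
randomness flows from the seed, and identical blueprints give byte-identical
cohorts.

**Fixture mode (plant-then-scrub).** Planted motifs are written into the
sequence by sampling each IUPAC position uniformly from its allowed set
("like-only" plantings carry exactly one mismatch at a uniformly chosen
position); planted bases are frozen. The scrubber then rescans all seven
classes and resamples, from the background distribution, the unfrozen
positions of any window where a *non-planted* class matches, iterating to a
fixed point (bounded at 200 rounds; non-convergence is an error, never a
silent partial fixture). Scrubbing touches only windows at legal scan
positions — sequence outside scan windows is unconstrained, which is
sufficient for exact scanner round-trips and cheap. Consequently scanner
counts equal planted counts exactly, which is what makes the preset
compositions exact at n = 100. Sampling mode plants without scrubbing,
leaving background hits at their natural rate.

**Background GC calibration.** Published promoter GC values describe whole
core regions *including* their (often AT-rich) elements. Presets therefore
solve, in closed form over the IUPAC allowed-set GC fractions of each
planting, for the background GC that makes the expected cohort-wide GC equal
the printed value. The GC recovery checks run in sampling mode, since
scrubbing (which removes AT-rich W-runs from background) slightly perturbs
base composition.

**CAGE-like tags.** Focused promoters put a Binomial(total, 0.85) share of
tags on one dominant start and scatter the rest within ±30 bp; dispersed
promoters spread tags over four modes at −60/−20/+20/+60 with weights
0.30/0.25/0.25/0.20, so no mode exceeds 40% and modes are ≥ 25 bp apart.
These operationalize the focused/dispersed dichotomy (≥ 80% on a dominant
site versus ≥ 3 separated modes, none above 40%).

**Presets.** Integer planting counts encode published cohort compositions
at n = 100. Two compositions required one-count adjustments because the
printed marginal frequencies and the printed combination-size fractions are
not simultaneously satisfiable by any 0/1 membership matrix (the membership
sum implied by the size histogram differs by one from the sum of the
marginals); the relaxed-BREu class absorbs the discrepancy (36 rather than
35 in the TFIIB-dominated preset, 12 rather than 13 in the NC2-dominated
preset) while every other marginal, the combination fractions, and all
co-occurrence percentages are exact. The dedicated co-occurrence presets
(`cooccur_inr`, `cooccur_dpe`) use n = 100 reference-motif promoters so the
printed pairwise percentages are exact integers.

**The `profile_minus50` preset** sets the footprint spread to 20 bp rather
than the signal-model default of 150 bp. The preset exists to demonstrate
modal-bin recovery from 5,000 sampled probe offsets at 10-bp resolution:
with a 150-bp spread, adjacent bins differ by under 0.3% in density —
far below sampling noise at that depth — so no finite experiment of this
size could identify the mode; a 20-bp spread separates the −50 bin from its
neighbours by several standard errors. The sampled high probes are laid over
a deterministic uniform grid (every integer offset × 35) and included in the
all-probe set, as on a real array; since the availability-corrected fraction
is a monotone function of the high count under uniform availability, the
modal bin equals the modal high-count bin.

### What the generator emulates, and what it does not

It emulates the *structure* of a promoter tiling-array study: TSS-anchored
core sequences with controlled composition, probeset signals with a
footprint and replicate noise, occupancy-coupled expression, and tag-count
vectors with focused/dispersed shapes. It does **not** emulate microarray
image artifacts, dye or probe-sequence effects, genomic background outside
the promoter windows, CpG-island structure, the correlated motif syntax of
real promoters beyond the planted marginals and pairwise co-occurrences, or
linkage between motif content and occupancy (presets couple them only
through their settings). Passing fixture round-trips therefore demonstrates
correctness of the *analysis* — scanner windows, counting rules, scaling,
binning — not biological realism of the sequences; stochastic checks (GC
recovery, footprint mode, replicate concordance trends, type-I error)
demonstrate the statistical behaviour of the methods under the stated
models.

## Numerical conventions and degenerate inputs

- Percentile thresholds: `stats::quantile` type 7; boundary ties included.
- Peak apex ties: leftmost. Dominated-set ties: lexicographic by id.
- Bin ties (offset exactly between two bin centers): toward 0.
- Zero-variance peak series: zero peaks. Empty tag maps, empty samples,
  empty regions, missing probes: errors naming the offending record.
- `dplyr::ntile` assigns rank ties by row order, so quantile binning is
  deterministic for a fixed input order.
- Problem sizes in the test suite are chosen to finish in minutes on one
  CPU: preset fixtures at n = 100, GC recovery at n = 1,000 promoters,
  profile recovery at 5,000 probes × 20 seeds, type-I error at 1,000
  replications of n = 30 with 199 bootstrap resamples, null-uniformity at
  200 replications of n = 100 with 500 resamples.

## Known limitations

- The threshold-run peak caller is a defined, deterministic replacement for
  model-based array peak callers; absolute peak counts from real arrays
  depend on the caller and are not comparable across implementations.
- Motif scanning is consensus-based (IUPAC + mismatch), not PWM-based; no
  de novo discovery is attempted.
- No multiple-testing correction is applied across genes, matching the
  analyses this package implements.
- Promoter-to-expression matching is assumed to be resolved upstream
  (tables join on `promoter_id`).
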