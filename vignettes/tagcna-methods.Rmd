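---
title: "Consensus copy-number events from tag markers: model and methods"
author: "tagcna package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus copy-number events from tag markers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagcna)
```

## The problem

Somatic copy-number alterations (CNAs) accumulate throughout tumour genomes.
Most are passengers — random gains and losses with no selective role — while
a minority recur across patients because they carry driver genes.  Given a
cohort of segmented log2-ratio profiles (an N-subject by L-marker matrix
`X`), the task is to find *significant consensus events* (SCEs): genomic
regions whose aberration across the cohort is statistically enriched over
the background of random CNAs, with family-wise control of false positives.

Two features of copy-number data make naive per-marker testing unattractive.
First, adjacent markers are strongly dependent (a CNA is a segment, not a
point), so L marker-level tests are massively redundant and any multiplicity
correction over them is far too conservative.  Second, the null distribution
should describe *background* CNAs only; if the very events one hopes to
detect dominate the permutation null, moderately recurrent events become
invisible.

This package addresses both with a two-stage design: (1) reduce the genome
to approximately independent *tag markers*, one per correlation block; (2)
assess tags with an iterative *peel-off* max-T permutation test whose null
converges toward a background-only distribution.

## Stage 1: correlation blocks and tag markers

Amplifications and deletions are analysed separately.  Thresholds
$\theta^{amp} > 0 > \theta^{del}$ split `X` into two call matrices in which
an aberrant cell keeps its log2-ratio and every other cell is exactly zero
(bounds inclusive).

For one chromosome and one polarity, the Pearson correlation $r_{ij}$
between marker columns $i$ and $j$ is computed across subjects (a
zero-variance column — no aberration anywhere — is assigned correlation 0;
such markers carry no consensus signal and must not seed spurious blocks).
Each marker $k$ then receives the windowed average

$$\bar r_k = \frac{1}{|W_k|}\sum_{j \in W_k} r_{kj}, \qquad
  W_k = \{\, j \ne k : |j - k| \le \lfloor w/2 \rfloor \,\},$$

with the neighbour set truncated (and the divisor shrunk) at chromosome
ends.  The window `w` is in markers; the default 20 follows the real-data
convention, and values between roughly 10 and 50 are reasonable — smaller
windows favour focal events, larger ones broad events.

The profile $\bar r$ is piecewise homogeneous: inside a region of shared
CNA structure it is elevated, in unstructured background it hovers near
zero.  A circular binary segmentation (CBS) changepoint engine partitions
it into blocks where the level changes.  Within each block the single
marker at the *middle site*, `start + floor((len - 1)/2)` (left of centre
for even lengths, a deterministic tie-break), becomes the block's tag.  The
N x M tag matrix `T` — M the number of blocks — is the object actually
tested; a tag's result stands for its whole block.

### The changepoint engine

`cbs_segment()` implements the classic recursion: find the pair of split
points maximising the circular two-sample t statistic between an arc and
its complement, accept the split if its permutation p-value is below
`alpha`, recurse.  Numerical specifics, all deterministic given the seed:

* ties in the maximising pair go to the leftmost candidate;
* segments shorter than `min_width` (default 2) are never created;
* a constant segment is never split (its statistic is defined as 0);
* a zero-within-group-variance split with distinct means (a noiseless
  step) gets an infinite statistic and is accepted;
* permutation sampling is *curtailed*: once the exceedance count reaches
  `ceil(alpha * n_perm)` the split can no longer attain `p < alpha`, so
  sampling stops — an exact early rejection, not an approximation;
* optionally (`fast_accept`, on by default) a split whose Bonferroni-bounded
  analytic p-value over all admissible split pairs is below `alpha/100` is
  accepted without permuting.  The bound only fires when the decision is
  unambiguous by two orders of magnitude; disable it to force pure
  permutation decisions.

Internally the scan uses the identity $t^2 = B\,(n-2)/(TSS - B)$ with
$B = n D^2 / (k(n-k))$, where $D$ is the centred arc sum: $TSS$ is
permutation-invariant, so a permuted segment exceeds the observed statistic
iff some arc's $D^2$ crosses a precomputed per-length threshold.  This makes
each permutation scan a subtract-multiply-compare per arc.

The same engine serves two roles: partitioning the correlation profile
(defaults `alpha = 0.01`, `min_width = 2`, `n_perm = 200`), and, in the
simulation pipeline, segmenting each subject's raw noisy profile before
thresholding (`segment_cohort()`; the simulation experiments use
`n_perm = 100` there — at `alpha = 0.01` a split is accepted only with zero
exceedances either way, so 100 draws resolve every decision).

## Stage 2: scoring and peel-off permutation

Each tag is scored by the summed aberration magnitude across subjects,
$S_m = \sum_n |t_{nm}|$ — zeros contribute nothing, so both the frequency
and the amplitude of aberration raise the score, in the spirit of the
G-score family of cohort statistics.

The null model holds that all tags are passengers, exchangeable across tag
locations within a subject.  One permutation draw independently and
uniformly permutes each subject's row of `T`; the draw's statistic is the
*maximum* tag score.  E draws form the max-T null `D_1`, and each tag gets
the right-tail p-value

$$p(m) = \frac{1}{E}\sum_{e=1}^{E} I\!\left(\max_{m'} S_{m'}(\delta^e(T))
  \ge S_m\right).$$

The `>=` in the indicator is the standard right-tail convention.  The
literal estimator can return 0; an add-one variant `(1 + count)/(1 + E)` is
available behind `add_one = TRUE` for users who prefer never-zero p-values.
Because the comparison is against one shared distribution, a higher score
never receives a higher p-value, and testing the maximum controls the
family-wise error rate.

If any tag achieves `p < alpha` (strictly; ties at `alpha` stay), all such
tags are deleted and the null is rebuilt from the remaining matrix — the
*peel-off*.  Each deletion removes a presumed consensus event from the
permutation pool, so the null mean drifts left, approaching the null that
background CNAs alone would generate.  The loop stops at the first
iteration that removes nothing, giving `D_H`; finally *all* original tags,
including those peeled en route, are re-assessed against `D_H`.  These
final p-values are the authoritative ones: the leftward drift can rescue
moderately recurrent events that the contaminated first-round null masked.
Two structural facts are worth knowing: H can never exceed M + 1, and the
minimum-score tag always has p = 1 (the permuted maximum is at least the
mean column score), so the matrix can never be peeled empty.

Significant tags map back to regions spanning their block's first-to-last
marker positions (`call_sces()`), reported with the tag's score, final
p-value and aberrant-subject count.

### Permutation scope

By default every chromosome is its own permutation family
(`scope = "chromosome"`), matching the view that chromosomes differ in
background CNA load; no cross-chromosome multiplicity scaling is applied,
since dividing `alpha` by the chromosome count is generally too
conservative for chromosome-specific events.  With `scope = "genome"` the
blocks are still built per chromosome (correlation windows never cross a
boundary) but all tags of a polarity are pooled into one family, which
favours broad events.

## Defaults and units

| parameter | default | units | role |
|---|---|---|---|
| `theta_amp` / `theta_del` | 0.848 / -0.737 | log2-ratio | call thresholds for real cohorts (3.6 and 1.2 copies); the simulation experiments use ±0.1 |
| `w` | 20 | markers | correlation window span |
| `E` | 1000 | draws | permutations per peel-off iteration |
| `alpha` | 0.05 | — | peel and reporting cutoff |
| `seg_alpha`, `seg_min_width`, `seg_n_perm` | 0.01, 2, 200 | — | changepoint engine settings |

All stochastic routines take an explicit integer seed and consume one RNG
stream in subject-major order; identical configuration and seed give
byte-identical output files.

## The cohort simulator

`simulate_cohort()` generates the synthetic data every result in this
package is demonstrated on.  Tumour copy number starts at 2 everywhere.  An
embedded consensus event of pure-tumour log2-ratio `r` sets carrier copy
number to $c_t = 2 \cdot 2^{r}$ over its interval (so 0.585 is 3 copies,
1.322 is 5); events are placed once per cohort at seeded-random offsets,
non-overlapping with a guard gap of 100 markers, and each draws its own
carriers, `round(f * N)` subjects.  Every subject also receives its own
passenger regions at independent uniform positions (rejection-sampled off
the consensus intervals so truth labels stay unambiguous), with lengths
U[50, 500] markers and ratios U[0.585, 1.322].  The observed signal mixes
tumour and normal cells: with normal fraction `p`,

$$x = \log_2\!\frac{(1-p)\,c_t + 2p}{2} + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

with `p` drawn per subject (uniform on [0.3, 0.7] by default; a truncated
Gaussian for contamination sweeps; or none) and the noise SD drawn per
subject from an interval — [0.1, 0.2], [0.2, 0.4] or [0.4, 0.6] in the
standard settings.  Gains are compressed toward diploid as `p` rises,
losses likewise; the mixture is strictly monotone in `p`.

Null cohorts (`simulate_null_cohort()`) simply omit the consensus events:
each subject keeps its own random passengers, so no locus is enriched
across subjects; aggregate per-marker coverage is flat in the genome
interior (it tapers within one passenger length of the ends, a geometric
edge effect of uniform placement).

The raw simulated profiles are noisy at marker level; the analysis pipeline
expects segmented input, so simulation experiments run
`segment_cohort()` on each subject before thresholding — the same
individual-sample step a real cohort would have undergone upstream.

What the simulator does *not* emulate: real marker spacing (markers are
equidistant), chromosome-arm-scale broad events, GC waves and other spatial
artefacts, heavy-tailed or correlated noise, and linkage between events
(carrier sets are drawn independently).  Passing the suite's checks
therefore demonstrates the statistical machinery under the stated
generative model, not robustness to every artefact of array or sequencing
data.

### The contamination experiment

The normal-cell contamination sweep (`simulate_contamination_sweep()`,
`contamination_power()`) inserts one amplified and one deleted event at
frequency 0.15 and draws `p` from N(0.6, sd), truncated to [0, 0.99],
across a grid of sd values.  The paper-level description of this experiment
fixes the mean, the sd range and the event frequency but not the event
sizes, the noise level or the background, so this package chooses once:
ratio +1 (4 copies) and -1 (1 copy), length 100 markers each, noise SD
U[0.2, 0.4] (the middle standard level), and — deliberately — *no*
passenger regions.  The background is marker noise alone.  With passenger
events included, an amplification compressed by 60% mean contamination has
the same amplitude as the compressed passengers and the max-T null
saturates: its detection probability is near zero at every feasible scale,
which would make the sweep measure background competition rather than the
contamination mechanism.  Against a noise-only background the sweep
isolates what it is meant to isolate: as the contamination spread grows,
more subjects sit near `p = 1`, their signal drops below the call
threshold, the effective carrier count falls, and power decays.

## Problem sizes used by the test suite

The full study conditions (100 subjects x 10000 markers, 600 null
replications, 1000 permutations) are what `sim_config()` defaults encode.
The package's own experiments run a reduced rendition chosen to keep the
whole suite within a desktop budget, via `sim_preset(scale = "desk")`:

* 50 subjects x 2000 markers, 200 permutations per iteration;
* passenger lengths scaled with the genome (U[10, 100] at L = 2000) so the
  per-subject background *coverage fraction* (~5.5%) matches the full
  scale; unscaled passengers would cover ~27% of a 2000-marker genome and
  half of it would sit in the placement edge zone, changing the
  generator's geometry rather than merely its size;
* consensus event lengths stay at {200, 100, 50} markers;
* type-I error: 100-150 null replications per noise level;
* detection: 20 replications per frequency/noise setting;
* contamination: 100 subjects (see above) x 2000 markers, 30 replications
  per sd.

The family-wise error of a permutation test does not depend on N or L, so
the type-I checks transfer directly; detection power does depend on the
absolute carrier count, which is why reduced-scale true-positive rates are
modest (the checks are ordinal: detection above background, more carriers
never worse, power decaying with contamination).

## Known limitations

* The correlation-block partition inherits CBS's behaviour on smooth
  profiles: the windowed profile is autocorrelated by construction, so the
  exchangeability null oversplits it and blocks are typically a few markers
  wide.  That costs nothing in error control (tags are still tested
  jointly) but means M grows with L.
* When one background CNA spans several adjacent blocks, its value enters a
  subject's row at a *run* of tags; permutation scatters the run, so
  permuted column maxima are stochastically larger than observed ones and
  the test is conservative — the family-wise error on simulated null
  cohorts lands below, not at, the nominal 0.05.  The finer the block
  partition relative to CNA lengths, the stronger this effect.
* Power is governed by the absolute carrier count against the permuted-max
  background; small cohorts (N below ~40) have little power at the study's
  event frequencies regardless of marker count.
* The literal p-value estimator can return exactly 0; use `add_one = TRUE`
  if downstream tooling dislikes that.
* No FDR machinery is provided (the method is max-T/FWER by design), and
  no broad-versus-focal dual thresholds.
* Missing cells are rejected, not imputed; upstream segmentation is
  expected to have produced complete matrices.
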