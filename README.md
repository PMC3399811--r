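# tagcna

Identify **significant consensus copy-number events (SCEs)** — recurrent
amplifications and deletions that may harbour cancer driver genes — in a
cohort of segmented tumour copy-number profiles.

Cohort-level CNA testing has to deal with two facts: adjacent markers are
strongly dependent (a CNA is a segment), and the permutation null is easily
contaminated by the very events being sought.  `tagcna` addresses both with
a two-stage design:

1. **Tag-marker selection.**  For each polarity (gains ≥ θ^amp, losses ≤
   θ^del analysed separately), every marker gets a windowed average
   correlation r̄_k with its neighbours (window `w` markers).  A circular
   binary segmentation (CBS) changepoint engine partitions the r̄ profile
   into *correlation blocks*; the middle marker of each block becomes its
   **tag**.  The N × M tag matrix T (M = number of blocks) is the object
   tested, so dependent markers are represented once.

2. **Peel-off max-T permutation.**  Each tag is scored by summed aberration
   magnitude, S_m = Σ_n |t_nm| (frequency and amplitude both count).  Each
   subject's row of T is permuted uniformly across tag locations; the
   maximum score over tags, collected across E permutations, forms the null
   D_1, and p(m) = (1/E) Σ_e I(max-score_e ≥ S_m).  Tags with p < α are
   **peeled off** and the null is rebuilt, shifting its mean left toward a
   background-only null; at convergence (D_H) all original tags are
   re-assessed.  Testing the maximum controls the family-wise error rate.

The package also ships the complete simulation framework used to
characterise the method — tumour/normal mixture cohorts with embedded
ground-truth events, background-only null cohorts, contamination sweeps —
and evaluation tools (marker-level ROC, empirical type-I error, detection
power versus contamination).

## Worked example

Simulate a 50 × 2000 cohort with three embedded amplifications (pure-tumour
log2-ratios 0.585/1/1.322, lengths 200/100/50 markers, 30% carrier
frequency), tumour/normal mixing and marker noise; segment each subject;
run the pipeline:

```r
library(tagcna)

cfg <- sim_preset("power", "desk", f = 0.3, noise_sd_range = c(0.1, 0.2),
                  seed = 2)
sim <- simulate_cohort(cfg)

seg <- segment_cohort(sim$data, n_perm = 100, seed = 3)   # per-subject CBS
fit <- tagcna_fit(seg, theta_amp = 0.1, theta_del = -0.1,
                  w = 20, E = 200, alpha = 0.05, seed = 4)
fit
```

```
tagcna_fit: 2 chromosome x polarity run(s), 11 significant region(s) at alpha = 0.05
  chr1 amp: 261 blocks, H = 2, null mean 6.44 -> 5.78
  chr1 del: 3 blocks, H = 1, null mean 0.467
```

The amplification run shows the peel-off at work: 261 correlation blocks,
two iterations, and a null mean drifting left (6.44 → 5.78) as significant
tags are removed.  The deletion run finds nothing (H = 1).  The significant
regions:

```r
head(fit$sces[, c("chrom", "start_pos", "end_pos", "score", "p_value")], 3)
```

```
  chrom start_pos end_pos    score p_value
1  chr1       416     422 12.59938       0
2  chr1       423     424 12.59938       0
3  chr1       425     456 12.59938       0
```

Each row is one correlation block whose tag reached final p < 0.05: its
marker-position span, its score (≈ carriers × mean |log2-ratio|) and its
permutation p-value.  Here the calls tile the embedded events (truth
intervals 416–465, 710–809 and 975–1174 at this seed):

```r
fit_marker_rates(fit, sim$truth, 0.05)
#>       tpr       fpr
#> 0.4057143 0.0000000
```

Forty percent of truth markers are recovered with no false marker calls.  For
real cohorts, use `read_ratio_matrix()` / `read_seg_segments()` for input,
the real-data thresholds (defaults 0.848/−0.737 ≈ 3.6 and 1.2 copies), and
`run_pipeline()` to write BED-detail region files, a per-tag statistics
table and a JSON run manifest.

## Command-line use

```sh
Rscript inst/cli/tagcna.R simulate --preset paper-power --scale desk \
    --freq 0.2 --noise 0.1,0.2 --seed 7 -o cohort/
Rscript inst/cli/tagcna.R run --matrix cohort/matrix.tsv \
    --markers cohort/markers.tsv --theta-amp 0.1 --theta-del -0.1 \
    -w 20 -E 1000 --alpha 0.05 --seed 7 -o out/
Rscript inst/cli/tagcna.R evaluate --mode type1 --reps 100 --noise 0.1,0.2 \
    --seed 7 -o type1.tsv
```
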