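# scanfuse

Microarray scanners observe fluorescence on a 16-bit scale: scan an array
at high photomultiplier (PMT) sensitivity and abundant transcripts saturate
at 65535 FLU; scan low and rare transcripts disappear into background. One
way out is to scan the *same* array several times at different PMT settings
and fuse the scans into a single per-probe intensity. `scanfuse` is an R
package for people who want to evaluate — or apply — that strategy: it
implements three fusion algorithms, the quality and reproducibility metrics
used to compare them on technical replicates, and a synthetic multi-scan
generator with known ground truth so the whole pipeline is testable end to
end.

## What is in the box

**Fusion algorithms** (probe `i`, scan `j`, ceiling `C = 65535`):

* `lyng_combine()` — windowed multiplicative rescaling. The gain `k`
  between low and high scan is the mean high/low ratio over probes with
  high-scan signal in 20000–30000 FLU; high-scan values above 50000 FLU are
  imputed as `k * low`.
* `csml_combine()` — clipping-saturation maximum likelihood. A least
  trimmed squares line `high = a*low + b` (via `MASS::lqs`), Gaussian noise
  scales from the robust residual spread, then a per-probe latent `t`
  minimising `(low-t)^2/sl^2 + (high-(a t+b))^2/sh^2`, with the high term
  replaced by the censored tail `-log P(a t + b + e >= C)` for saturated
  probes. Saturated probes are "de-censored": their fused values may exceed
  the ceiling.
* `khondoker_combine()` — Cauchy functional regression over all `m >= 2`
  scans: `y_ij = clip(beta_j x_i + e_ij, C)` with
  `e_ij ~ Cauchy(0, sigma * beta_j)` and `beta_1 = 1`, censored
  observations entering through the Cauchy tail probability. With only two
  scans the likelihood favours a degenerate `sigma -> 0` solution whenever
  saturated probes exist whose rescaled low-scan values exceed the ceiling;
  the fit lands on a configured floor and raises `degenerate_scale_flag` —
  the documented two-scan pathology of this model.

**Metrics**: cyclic lowess normalization (`cyclic_lowess`), negative-control
background bound (mean + 3 SD, `background_bound`), per-array SNR, dynamic
range (fraction of probes above background and below 10% of saturation,
with the low scan gating the upper end for fused data), pairwise paired
t-tests with Bonferroni correction, Spearman replicate correlations with
bootstrap percentile intervals, decile stratification and sliding-window
curves.

**Synthetic data**: `truth_model()` / `simulate_scanset()` /
`default_study_fixture()` generate multi-PMT scan sets (22575 probes, 40
arrays, 162 negative controls, 3 scan levels by default; a 2000 x 8 mini
variant for fast runs) with log-normal expression shared across technical
replicates, gain-amplified background, Gaussian or Cauchy noise, integer
rounding and 16-bit clipping — with the generating truth returned for
recovery tests.

**Orchestration**: `run_config()` + `run_pipeline()` run
simulate → combine (all methods) → normalize → QC → correlation and return
a report object; `write_report()` serializes it to JSON/TSV.

## A worked example

```r
library(scanfuse)
fx <- default_study_fixture(mini = TRUE)       # 2000 probes x 8 arrays x 3 scans
cfg <- run_config(scanset = fx$scanset, negcontrol = fx$truth$negcontrol,
                  B = 300, corr_window = 200, corr_stride = 50, seed = 1)
report <- run_pipeline(cfg)
print(report)
#> scanfuse_report: 7 approaches
#>    approach mean_corr               ci   snr negctrl_mean dynamic_range
#>         low    0.9215 [0.9030, 0.9325] 0.789        8.192         0.398
#>      medium    0.8924 [0.8716, 0.9078] 0.641       10.978         0.163
#>        high    0.8496 [0.8244, 0.8678] 0.515       13.772         0.000
#>        lyng    0.8505 [0.8250, 0.8688] 0.515       13.772         0.290
#>        csml    0.9140 [0.8967, 0.9262] 0.443       13.809         0.424
#>  khondoker2    0.8968 [0.8754, 0.9120] 0.725        8.272         0.347
#>  khondoker3    0.9222 [0.9039, 0.9339] 0.605        8.444         0.416
```

Reading the table: `mean_corr` is the average Spearman correlation between
replicate arrays (with its Bonferroni-adjusted bootstrap interval) — the
reproducibility of each acquisition strategy; `snr` is median signal minus
negative-control background in log2 units; `negctrl_mean` is the background
level itself; `dynamic_range` is the fraction of useable probes. The
patterns mirror what multi-scan studies report: background rises and SNR
falls as PMT increases; the three-scan Cauchy fit is the most reproducible
approach and keeps a low-scan-like background, while the same model on two
scans degenerates (check `report$approaches$khondoker2$fit[[a]]$degenerate_scale_flag`)
and loses reproducibility.

Per-approach detail lives in `report$approaches$<name>`: the normalized
matrix, quality report, correlation summaries, sliding-window curve and the
fit objects. `ratio_intensity_data()` and `density_with_corr_overlay()`
produce the corresponding plot data.

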