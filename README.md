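# sourcemvpa

Region-based multivariate pattern analysis of source-space MEG, built for
one scientific question: when training turns an unrecognizable two-tone
(Mooney) image into a recognized object, *where*, *when* and — above all —
*how* does the cortical response change? A region can gain response
**power** while keeping its spatial activity pattern (amplified
processing), it can **reorganize the pattern** at constant power (new
processing), or it can re-express a category-specific component at a
**later latency**. The package implements the full analysis chain that
separates these possibilities, plus a synthetic source-data generator that
emulates the pre/post training design so every stage is testable without
access to raw MEG recordings.

## What it computes

For each subject and cortical region (vertices × time × trials epochs per
condition; 2 object images × {pre, post} state and 2 nonsense images ×
{session 1, session 2} per category):

* **RB-MVPA decoding** — 10 ms binning, 10 pseudo-trial averages per
  condition (conditions under 50 trials are excluded), 3 principal
  components per region, pairwise LDA with all 100 leave-one-per-class-out
  folds (`compute_empirical_rdms()`).
* **RSA** — Spearman correlation of the 28 pairwise accuracies with a
  binary model RDM (high dissimilarity across the recognized/unrecognized
  boundary; 12 of 28 pairs), Fisher-z, one-sided group t-maps with
  BH-FDR over all region × timebin cells (`searchlight_effect_map()`),
  and the nine-component **RDM profile** with the canonical contrasts
  dR−dU, dNa−dN, sNa, RN−UN, sRU−sNa (`compute_profile()`,
  `profile_contrast()`).
* **Power vs pattern** — RMS power of the PC scores with a
  SESSION × GROUP repeated-measures ANOVA, the across-subject correlation
  of decoding gain with power change, and the **alpha angle** between the
  discriminant normals of the pre-vs-nonsense and post-vs-nonsense
  classifiers against its pre-stimulus baseline
  (`angle_timecourse_vs_baseline()`).
* **Temporal generalization** — train-time × test-time accuracy matrices
  with the shared-group image-exclusion rule, cross-exemplar transfer for
  isolating category-shared components, and cluster-based sign-flip
  permutation inference on the 2-D matrices (`generalization_matrix()`,
  `cross_exemplar_generalization()`, `cluster_permutation_2d()`).
* **Synthetic cohorts** — evoked gamma envelopes on region- and
  stimulus-specific spatial patterns in spatially and temporally smooth
  noise, with injectable `power_gain`, `pattern_rotation` and
  `delayed_shared_pattern` effects (`simulate_dataset()`,
  `effect_spec()`).

## Worked example

```r
library(sourcemvpa)

cfg <- sim_config(n_subjects = 16, regions = c("rIO", "ctrl"),
                  n_vertices = 30, rng_seed = 9,
                  effects = list(effect_spec("power_gain", "rIO",
                                             c(80, 160), 0.8)))
ds   <- simulate_dataset(cfg)
rdms <- compute_empirical_rdms(ds, pipeline_config(analysis_window_ms = c(0, 300),
                                                   rng_seed = 9))

prof <- window_profiles(rdms, "rIO", c(80, 160))
profile_contrast(prof, "RN-UN", alternative = "greater")$t$statistic
#> [1] 3.39        # recognition gain in decoding objects vs nonsense

decoding_power_association(
  recognition_decoding_gain(rdms, "rIO", c(80, 160)),
  recognition_power_delta(rdms$features, "rIO", c(80, 160)))$rho
#> [1] 0.59        # subjects with larger power gains decode better

ang <- angle_timecourse_vs_baseline(rdms$features, "rIO", c(80, 160))
round(c(window = mean(ang$window_alpha), baseline = mean(ang$baseline_alpha)))
#>   window baseline
#>       46       91  # discriminant direction preserved: a power effect
```

The injected gain is read out exactly as the method intends: decoding of
objects against nonsense improves after training (RN−UN, t ≈ 3.4), the
improvement tracks the power increase across subjects (ρ ≈ 0.59), and the
discriminant normal barely moves (alpha ≈ 46° in the window against a
~91° noise baseline) — amplification, not reorganization.

The `analysis/` directory runs the full study as numbered stages
(simulate → decode → RSA/profile → power/pattern → generalization),
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_decode.R
Rscript analysis/03_rsa_profile.R
Rscript analysis/04_power_pattern.R
Rscript analysis/05_generalization.R
```

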