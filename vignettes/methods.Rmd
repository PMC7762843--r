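---
title: "Region-based decoding of recognition effects: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based decoding of recognition effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When an observer learns to see the object hidden in a two-tone Mooney
image, the stimulus on the retina is unchanged but the cortical response
to it is not. `sourcemvpa` implements a source-space MEG analysis chain
that localizes such recognition-induced changes in space and time and —
its central methodological point — distinguishes *how* a region's
response changed: by gaining power while keeping its spatial activity
pattern (an amplification of processing that was already there), by
reorganizing the pattern at constant power (a new configuration of
processing), or by re-expressing a category-specific component at a later
latency.

The experimental design the package assumes, and which its simulator
emulates, is a per-category set of eight conditions: two object images,
each measured before training (naively unrecognizable, "pre") and after a
brief training procedure that induces recognition ("post"), and two
nonsense images measured in two sessions that bracket training. The
nonsense session split is the recognition-free control for anything that
merely changes between sessions.

# The analysis model

## Region-based MVPA

All decoding is pairwise linear discriminant analysis on a per-region
feature space:

1. **Downsampling.** Source epochs are reduced to a 10 ms grid by
   averaging consecutive samples (`downsample_epochs()`); averaging acts
   as a crude low-pass and is deterministic. The 0–500 ms analysis window
   yields 51 bins at full scale.
2. **Pseudo-trials.** The trials of each condition (75 by default, at
   least 50 or the condition — and with it the subject — is excluded) are
   randomly partitioned into 10 disjoint near-equal groups and averaged
   (`make_pseudotrials()`); with 50–80 trials the group sizes are 5–8. A
   random *partition* rather than resampling keeps cross-validation folds
   independent and reproduces those sizes exactly.
3. **Features.** One PCA per subject × region is fitted on the vertex
   dimension, pooling all conditions' pseudo-trials over all
   analysis-window bins, and the first 3 components are kept
   (`extract_region_features()`). A single shared basis per region is a
   deliberate interpretation: discriminant directions at different times
   and conditions then live in one 3-D space, which is what makes the
   discriminant-angle and temporal-generalization analyses meaningful.
   Scores are also computed for pre-stimulus bins (the basis is applied,
   not refitted) so that baseline quantities use the same geometry.
4. **Classification.** Fisher LDA with pooled within-class covariance and
   a relative ridge of `1e-6 * trace(S)/p` (18 samples in 3-D are almost
   always well-conditioned; the ridge guards degenerate draws). The
   boundary sits midway between projected class means; exact ties go to
   the first class so results are deterministic. Cross-validation holds
   out one pseudo-trial per class, enumerating all `10 × 10 = 100` folds
   (`cross_validated_accuracy()`).

## RSA and the RDM profile

The 28 pairwise accuracies per subject × region × bin form an empirical
RDM (accuracy as dissimilarity). The binary model RDM codes high
dissimilarity for the 12 pairs crossing the recognized/unrecognized
boundary — post-objects vs nonsense (RN, 8 pairs) and post- vs pre-state
objects (sRU, dRU, 2+2) — with pre-state objects grouped with nonsense.
Spearman correlation (average ranks; the binary model makes ties
structural) is Fisher-transformed, with `rho` clipped to `1 - 1e-6` so
structurally perfect correlations stay finite; a zero-variance empirical
RDM is flagged degenerate and excluded from group tests rather than
propagated as `NA`.

The RDM profile averages the 28 entries into nine components
(dU, dR, dN, dNa, sNa, UN, RN, sRU, dRU) with entry counts
(1, 1, 2, 2, 2, 8, 8, 2, 2); the weighted averages of the first six
(16 entries) and last three (12 entries) summarize the low- and
high-dissimilarity sides of the model. The canonical contrasts are
`dR-dU` (recognition-induced within-category differentiation), `dNa-dN`
and `sNa` (session controls; `sNa` is tested against chance 0.5),
`RN-UN` (recognition gain against nonsense) and `sRU-sNa` (same image
pre vs post, controlling session changes).

**Sidedness.** The effect map tests the Fisher-z correlations one-sided
(positive) by default. This is a deliberate choice: the model RDM is
directional — it predicts above-chance correlation where recognition
restructures responses — and under the simulated null the rank structure
of the model has a small *negative* bias (the low-dissimilarity group
contains proportionally more decodable different-stimulus pairs than the
high group), which a two-sided map would report as spurious "effects"
with inverted sign. Contrasts with a directional prediction (`RN-UN`,
`sRU-sNa`) are run one-sided where the analysis scripts say so; all
sidedness is an explicit argument.

**Multiplicity.** All region × timebin cells of one category analysis
form a single Benjamini–Hochberg family at `q = 0.05`. Window summaries
flag a region when at least half the window's bins are FDR-significant.

## Power versus pattern

Two observables dissociate amplification from reorganization:

* **RMS power** of the 3-PC scores, computed per pseudo-trial and then
  averaged (robust to pattern cancellation across pseudo-trials; the
  alternative order — RMS of the mean — is more susceptible to it). A
  recognition-specific gain appears as the SESSION × GROUP interaction of
  a repeated-measures ANOVA (first/second session × objects/nonsense),
  and as a positive across-subject Spearman correlation between the
  decoding gain (RN − UN) and the power change (post − pre RMS).
* **The alpha angle** between the discriminant normals of the
  pre-vs-nonsense and post-vs-nonsense classifiers (object class first in
  both, so orientation is preserved and alpha is not folded to ≤ 90°; the
  nonsense stimulus is session-matched to the object state). Preserved
  patterns give small alpha; reorganized patterns give large alpha. The
  chance level is estimated from classifiers trained on pre-stimulus
  baseline bins with the same condition pairs.

Two estimator properties are worth stating plainly, because they bound
what the alpha analysis can show. First, the normal `w ∝ S⁻¹(μ_obj −
μ_nonsense)` contains the nonsense reference, so a vertex-space rotation
of the object pattern by θ reads out compressed (for equal object and
nonsense amplitudes, roughly `acos((cos θ + 1)/2)` in the noise-free
limit). Second, with noise-driven normals the baseline alpha concentrates
near 90°, and no power-preserving rotation of magnitude ≤ 90° can push
the effect-window alpha *above* that baseline — an effect-window alpha
significantly *below* baseline is therefore evidence of a preserved
pattern (the power-gain signature), while pattern reorganization shows up
as alpha rising *toward* the baseline level and as the absence of the
power signatures. The validation suite asserts the stronger directional
reading as well, and documents where it is not attainable; effect-type
classification rests on the robust signatures (power interaction and
decoding–power correlation present vs absent, with the RSA/profile
detection).

## Temporal generalization

A classifier trained on a pair of image groups at train time `T1` is
tested on a (possibly different) pair at test time `T2`
(`generalization_matrix()`), giving a `T1 × T2` accuracy matrix per
subject. When a testing group coincides with a training group, all
combinations in which that group contributes the same image to training
and testing are excluded; with disjoint groups independence holds
automatically. The nonsense group spans both sessions, so session-stable
nonsense patterns can never masquerade as transfer.

The delayed-component analysis (`cross_exemplar_generalization()`)
trains on one object exemplar's pre-state vs nonsense and tests on the
*other* exemplar's post-state vs nonsense, averaging the two
assignments: stimulus-specific patterns cannot transfer across
exemplars, so above-chance off-diagonal accuracy isolates category-shared
components, and a component re-expressed `Δt` later in the post state
appears as a cluster whose test-time support is shifted by `Δt`.

Inference is a cluster-based sign-flip permutation test
(`cluster_permutation_2d()`): cell-wise one-sample t against chance,
two-sided pointwise threshold `p < 0.05` (the conventional
cluster-definition threshold; the quantity is configurable), 4-connected
same-sign clusters scored by size, and a null distribution of the maximal
cluster size from 10,000 random whole-subject sign flips (whole matrices
are flipped, preserving within-subject correlation structure). Clusters
beyond the 95th percentile are significant.

## Statistical kernel

`fisher_z()`, `fdr_bh()` (Benjamini–Hochberg step-up), `one_sample_t()`
/ `paired_t()` and `rm_anova()` (full-factorial within-subject ANOVA via
`aov` error strata, up to three factors, no sphericity correction — none
is reported in this family of designs; with two-level factors, where the
package's analyses live, sphericity is not at issue). Degenerate inputs
are flagged rather than silently propagated: zero-variance t-tests,
`rho = ±1`, and ANOVA strata with vanishing sums of squares.

# The synthetic cohort

`simulate_dataset()` generates per (subject, region, condition) trials

```
x(t) = a_c(t) · g(t) · p_c(t) + ε(t)
```

* `g` — gamma-shaped evoked envelope, unit peak at 120 ms, shape 3: the
  response rises from onset and decays through ~300 ms, so that
  mid-latency effect windows still carry signal, as sustained evoked
  fields do.
* `p_c` — unit-norm spatial pattern per subject × region × stimulus,
  drawn independently per subject: there is deliberately no
  vertex-to-vertex correspondence across subjects, since region-based
  decoding requires none. Object patterns are identical pre/post and
  nonsense patterns identical across sessions unless an effect or
  `session_drift` changes them.
* `ε` — Gaussian noise, correlated across vertices (random orthonormal
  mixing with a `k^(-1/2)` eigenvalue decay) and smoothed over time with
  a short variance-preserving kernel: white noise would make decoding
  unrealistically easy.
* `snr = 0.2` (default) — evoked per-vertex RMS at the envelope peak
  over noise RMS. Real-data SNR is not known at this level; the default
  was calibrated once so that pairwise decoding of distinct stimuli
  peaks at ~0.65–0.8 accuracy — the range typical of source-space MEG
  decoding — leaving headroom for gain effects to express themselves.

Injectable effects (`effect_spec()`):

* `power_gain` — post-state amplitude `(1+β)·a` inside the window,
  pattern untouched. The per-subject gain is `β · max(0, 1 + z)`,
  `z ~ N(0,1)` (`effect_sd = 1`): pronounced individual differences in
  training benefit. Without between-subject variance in the true effect
  the across-subject decoding–power correlation would be structurally
  zero; heterogeneous learning gains are also what training studies
  observe.
* `pattern_rotation` — exact Givens rotation of the pattern by θ degrees
  in the plane spanned by the pre pattern and a random direction
  orthogonal to all of the region's patterns; amplitude unchanged, so
  power is invariant by construction (θ = 90° makes pre/post
  condition-mean maps exactly orthogonal, which the tests verify).
* `delayed_shared_pattern` — one unit pattern shared by the category,
  amplitude 3 (a dominant component, as the face-specific N170m
  dominates the fusiform response), added to pre-state objects in the
  window and to post-state objects `Δt` later.

What the simulator does *not* emulate: realistic forward fields and
inverse-operator leakage between regions, physiological artifacts,
induced (non-phase-locked) oscillatory power, inter-subject amplitude
scaling, and trial-to-trial latency jitter. Passing tests on this cohort
therefore demonstrate that the analysis chain recovers the effects it is
designed for under realistic SNR and smooth correlated noise — not that
it is robust to every failure mode of real source reconstructions.

# Validation design and problem sizes

The test suite validates three layers:

1. **Exact structure** — the 28-pair enumeration against an independent
   rule table, model-RDM composition, fold enumeration against a
   brute-force double loop, BH against the step-up definition, `rm_anova`
   against both the paired-t identity and a hand-computed 2×2
   sums-of-squares decomposition, cluster labelling against a reference
   flood fill.
2. **Calibration under the null** — 200 effect-free replicates (6
   subjects, one region, 12 vertices, 0–50 ms window): exchangeable-pair
   decoding centred at 0.5, RSA group test and the FDR map at nominal
   false-positive rates; 200 pure-noise generalization matrices for the
   familywise rate of the cluster test.
3. **Effect recovery** — 20 replicates of the full 16-subject design (75
   trials, 30 vertices, three effect regions, windows restricted to
   0–220 / 0–300 ms): detection rates, dissociation signatures and
   effect-type classification accuracy. The cross-exemplar
   generalization test in this battery uses a cluster-forming threshold
   of pointwise `p < 0.01` (the map default is 0.05): on a 31 × 31
   correlated accuracy surface a 0.05 threshold produces null maximal
   clusters of ~30 cells, blinding the max-size statistic to the focal
   5 × 5-bin support a delayed component occupies.

Two recovery findings are documented rather than hidden: with three
retained PCs, the subject-specific fraction of a rotated pattern
captured by the PC basis couples the post-state in-subspace power to
post-state decodability, so the rotation's decoding–power correlation
sits slightly above zero (far below the power-gain association, and
never enough to classify the rotation as a power effect); and the
rotation's effect-window alpha cannot rise above the ~90° noise
baseline for the geometric reasons given earlier.

The replicate sizes are the package's chosen desk-scale study
conditions: large enough that the paper-scale statistics (paired t over
16 subjects, Spearman over 16 subjects, 1000–10,000-permutation cluster
tests) behave as in a real study, small enough that the whole battery is
a coffee-break computation. `scripts/acceptance.R` re-runs a condensed
version (100 null replicates, 10 recovery replicates) and writes the
headline numbers as JSON.

# Known limitations

* Three principal components cannot contain the full signal subspace of
  an eight-condition design (up to five distinct patterns plus injected
  directions); rotated or shared components are partially truncated,
  which compresses recovered discriminant angles and attenuates — but
  does not silence — their decoding signatures. This mirrors the
  trade-off of the 3-PC choice itself: location specificity over
  completeness.
* The discriminant-angle baseline sits near 90° by geometry; see the
  power-versus-pattern section for what directional claims that does and
  does not license.
* Accuracy-as-dissimilarity is bounded at 1, so strong effects can
  saturate and compress between-subject variance (the default SNR is
  calibrated to avoid the ceiling).
* `rm_anova` assumes complete balanced within-subject designs and
  applies no sphericity correction.
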