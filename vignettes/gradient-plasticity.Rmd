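---
title: "Linking gene expression to learning-dependent gradient plasticity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking gene expression to learning-dependent gradient plasticity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`gradlink` implements a node-level analysis pipeline connecting three layers
of observation in the adult human cortex: regional bulk gene expression,
learning-dependent changes in cortical microstructure and functional
connectivity summarized as low-dimensional *gradients*, and behavioral
learning. The pipeline has four analytic stages:

1. **Feature matrices.** Microstructure profile covariance (MPC) — the
   partial correlation between depth-wise myelin-sensitive (MT) intensity
   profiles of every node pair, controlling for the cortex-wide mean
   profile, Fisher r-to-z transformed with negative edges clipped to zero —
   and functional connectivity (FC), the Pearson correlation of node
   resting time series.
2. **Gradients and dispersion.** Each feature matrix is row-sparsified
   (top 10% of entries kept per row), converted to a normalized-angle
   affinity, and embedded by diffusion maps. Every subject/session
   embedding is aligned to a group template by orthogonal Procrustes
   rotation. Network *dispersion* is computed in the space of the first
   three gradients: within-network dispersion is the **sum** of squared
   Euclidean node-to-centroid distances; between-network dispersion is the
   Euclidean distance between network centroids.
3. **Behavior.** Learning rate is the slope `b` of the logarithmic fit
   `accuracy = a + b ln(t)` over training sessions. Post-minus-pre
   dispersion changes (visual-network within, fronto-parietal within,
   between) predict the learning rate in a standardized multiple
   regression, assessed by permutation of the outcome, leave-one-out
   cross-validation, and a specificity permutation that randomly re-pairs
   baseline and pre-training sessions.
4. **Transcriptomic association.** Partial least squares (PLS) regression
   of the nodes-by-genes expression matrix onto six response maps (the
   group-mean change in MPC G1–G3 and FC G1–G3). Component significance
   comes from permuting the response rows (jointly across columns) or,
   optionally, from spatially constrained surrogate responses.
   Gene-level stability comes from a node bootstrap with Procrustes
   rotation of the loading matrices, z-score-like weights, and the FDR
   inverse quantile transformation (FIQT) to counter winner's-curse bias;
   genes with adjusted |z| > 1.96 feed a hypergeometric gene-set
   enrichment with Benjamini–Hochberg correction.

All computation lives in the package (`R/`); the numbered scripts under
`analysis/` are thin narrative drivers that run each stage on the default
synthetic study and write tables under `results/`.

# The synthetic study

No subject-level imaging or donor expression data ship with the package.
Instead a first-class generator (`synth_config()`, `gen_geometry()`,
`gen_expression()`, `gen_profiles()`, `gen_timeseries()`, `gen_behavior()`)
produces inputs with the statistical structure the analysis assumes, plus
*planted* ground-truth effects so that recovery is testable:

* **Geometry.** Nodes are sampled on a smooth two-dimensional sheet
  embedded in 3-D (about 10 × 10 arbitrary units); seven spatially
  contiguous network patches are carved by k-means, with the visual (VN)
  and fronto-parietal (FPN) networks at opposite ends of the sheet's first
  axis.
* **Expression.** Each gene is an independent Gaussian field over the
  sheet with a squared-exponential kernel (`spatial_corr_length`, default
  1.5 units; neighboring nodes then correlate at roughly 0.9) and a 5%
  white nugget. Planted genes additionally carry
  `planted_effect_size` (default 1) times the standardized planted change
  pattern.
* **Profiles.** Depth profiles are a per-network smooth template times a
  node-specific deviation spanned by two depth basis functions. A rank-2
  deviation space is deliberate: with a single basis the within-network
  residual profiles are proportional and their correlations pin at ±1, so
  planted changes would be invisible to MPC. The planted microstructural
  change shifts each VN node's first deviation coefficient in a fixed
  per-node direction (±), in proportion to the subject's effect — a
  multiplicative shape change that survives covariance normalization and
  widens the VN covariance spread.
* **Time series.** Multivariate Gaussian draws from a block correlation
  matrix (within-network 0.35, between 0.10). The planted functional
  change adds a rank-one ± spread term to the FPN block post-training,
  splitting the network into subclusters and widening FPN dispersion.
* **Behavior.** `accuracy(t) = a_s + b_s ln t + noise`, clipped to
  [0, 100] after noise; `b_s = 10 + coupling × effect_s` with the
  dispersion–behavior coupling defaulting to 5 percent per log-session per
  unit effect. Subject effects are positive with mean 1 and SD 0.4.
* **Planted change pattern.** The spatial phenotype tracked by planted
  genes (`planted_change_pattern()`) is the deterministic per-node
  direction of the plants: the ± tilt direction over VN plus the ±
  subcluster sign over FPN, zero elsewhere, standardized. This is exactly
  the pattern that survives averaging change maps over subjects, so a real
  gene–map association exists by construction.

Effect-size scales (`mpc_change_scale = 0.25`, `fc_change_scale = 0.2`)
were chosen once so that the resulting dispersion-behavior regressions have
effect sizes comparable to published values in this literature
(R² around 0.5–0.6 with ~20 subjects); the source study reports no brain
effect magnitudes, so these are generator conventions, not claims about the
data. A deliberate asymmetry — microstructural plant in VN only, functional
plant in FPN only — keeps the "which measures should light up"
question well-posed in the end-to-end test.

What the generator does **not** emulate: vertex-level surfaces, donor
microarray noise and probe aggregation, head motion or physiological
confounds, hemodynamics (time series are white in time), site effects, or
missing data. Passing recovery tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to the
full messiness of empirical MRI/AHBA data.

# Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `sparsity` | 0.9 | fraction of each affinity row zeroed (keep top 10%) |
| `alpha` | 0.5 | diffusion-map density-normalization exponent |
| `t` | 0 | diffusion time; 0 = eigenvalue-scaled components |
| `k` | 5 | retained gradients (dispersion always uses G1–G3) |
| `n_perm` | 500 | permutations for PLS and regression tests |
| `n_boot` | 200 | bootstrap samples for gene z-weights |
| `z_threshold` | 1.96 | adjusted-|z| cutoff (two-sided p < 0.05) |
| `spatial_corr_length` | 1.5 | gene-map kernel length scale (sheet units) |

The affinity kernel (top-10% row retention, normalized-angle similarity,
symmetrization by averaging) and the embedding defaults follow the de-facto
standard of connectome-gradient toolboxes; none of these choices are pinned
by the source study, so all are exposed in the configuration and recorded
in output metadata.

# Numerical choices

* **PLS.** Components are covariance-maximizing latent directions with
  deflation of both blocks. Each component's weight vector is computed
  exactly from the small response-side eigenproblem of `(X'Y)'(X'Y)` —
  the same fixed point the classic NIPALS alternation converges to, but
  deterministic and fast when the response block is narrow. The test suite
  pins this equivalence against an independently coded NIPALS iteration.
  Component sign is fixed by making the largest-magnitude weight positive.
  `X = T P' + E` and `Y = U Q' + F` hold as identities of the fit.
* **Bootstrap z-scale.** Bootstrap z-weights are computed on the
  *covariance-loading* scale (unit response-side weight, no unit-norm
  constraint on the gene vector). Under node resampling the norm of the
  full weight vector is systematically inflated (resampling noise adds to
  realized noise), so unit-norm bootstrap weights are shrunk and their SD
  understates sampling variability — measured null z SDs near 1.2 and
  empirical false-discovery proportions near 0.33. On the covariance scale
  the null z SD is ~1.02 for spatially unstructured genes and the FDR
  calibrates. The z-scores are invariant to any *fixed* rescaling, so this
  is purely an identification choice.
* **Fisher z cap.** MPC correlations are capped at `1 - 1e-7` before
  `atanh` so perfectly collinear synthetic profiles stay finite.
* **Permutation p-values.** Always the add-one estimator
  `(1 + #{null ≥ observed}) / (1 + n)`; never exactly zero.
* **Degenerate inputs.** Constant profiles, zero-variance time series,
  disconnected affinity graphs, singular regression designs and hits
  outside the enrichment background all raise errors naming the offending
  units; bootstrap rank-deficiency is retried with a capped count.
* **Determinism.** Every stochastic stage draws its seed from the run seed
  through a fixed integer map (`derive_seed()`), so stages rerun
  independently and the whole pipeline is byte-reproducible.

# Design decisions on open points

* **Dispersion uses the sum (not mean) of squared distances**, exactly as
  defined; the value therefore scales with network size. This is
  documented rather than "corrected".
* **Group alignment topology.** One template per modality, embedded from
  the grand-average feature matrix across all subjects and sessions; every
  individual embedding aligns to it. Chained pairwise alignment would
  accumulate error and make sessions incomparable.
* **Response maps.** The PLS responses are group-mean change maps (200
  nodes), not concatenated subjects; with a 200-node predictor matrix this
  is the only shape consistent with the node count.
* **Permutation of responses** shuffles all six columns jointly,
  preserving inter-map correlation under the null.
* **Specificity convention.** The specificity permutation reports the
  fraction of random baseline/pre pairings giving a significant model and
  its complement as `p` (large = specific).
* **Report flags.** The end-to-end report flags a PLS component at a
  Bonferroni-corrected permutation threshold (0.05/3) and a dispersion
  measure when its modality's model is permutation-significant *and* its
  own correlation with the outcome passes 0.05/3. Per-measure correlations
  are used instead of multiple-regression coefficients because the planted
  VN-within and the induced VN-FPN-between changes are strongly collinear;
  coefficient tests under collinearity are unstable in either direction.
* **Enrichment statistic.** Plain one-sided hypergeometric
  over-representation by default, with an optional EASE-style
  overlap-minus-one variant and a choice of Benjamini–Hochberg, Bonferroni
  or no correction.
* **Surrogate maps.** Variogram matching on node coordinates: a random
  permutation of the map is smoothed with a Gaussian distance kernel plus
  a white-noise blend, parameters calibrated against the source variogram
  (15 trial surrogates per candidate), and ranks are remapped to the
  original values — preserving the value multiset exactly. A geometry-based
  spin test is not applicable because inputs are parcels, not spheres.

# Problem sizes

The default study is 200 nodes, 2,000 genes (50 planted), 20 subjects,
three imaging sessions, 500 permutations, 200 bootstrap samples; the full
multisession run takes well under a minute on a single core. The test
suite's calibration checks use 200 null simulations per permutation test,
50 simulations for gene-driver recovery (800 genes at the same 2.5%
planted fraction), and 100 simulations for coupling-sign recovery; these
sizes were chosen to keep each property estimable with useful Monte-Carlo
precision while the whole suite stays fast.

# Known limitations

* **Gene-level FDR under spatial autocorrelation.** The node bootstrap
  treats nodes as exchangeable; spatially smooth gene maps share a
  dataset-level variance component the bootstrap cannot see, leaving null
  bootstrap z-scores mildly overdispersed (SD ≈ 1.1–1.2 at the default
  smoothness). BH/FIQT then under-corrects slightly: the measured mean
  false-discovery proportion at the default settings sits at the 0.10
  boundary (≈ 0.100–0.13 depending on conditions) rather than the nominal
  0.05. The surrogate-map null corrects the *component-level* test for
  spatial autocorrelation but no analogous correction exists in this
  recipe at the per-gene level; a spatial block bootstrap would address it
  at the cost of changing the resampling unit.
* Dispersion statistics inherit embedding sign/rotation noise; alignment
  to a group template mitigates but does not remove it.
* The enrichment test assumes independent gene sampling; co-expression
  violates this, as it does for every hypergeometric screen.
* The generator's time series are temporally white; autocorrelated noise
  would widen FC sampling variability relative to what the tests exercise.
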