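# gradlink

Linking regional gene expression to learning-dependent changes in cortical
microstructure and functional-connectivity gradients.

## The problem

Perceptual training changes the adult cortex at (at least) two levels:
myelin-sensitive microstructure and resting-state functional connectivity.
A compact way to compare the two is *gradient* analysis: summarize each
node-by-node similarity matrix — microstructure profile covariance (MPC,
partial correlations between depth-wise MT intensity profiles controlling
for the cortex-wide mean profile) and functional connectivity (FC, Pearson
correlations of resting time series) — by a low-dimensional diffusion-map
embedding, and quantify network organization as *dispersion* in the space
of the first three gradients:

- within-network dispersion: sum of squared Euclidean distances of a
  network's nodes to the network centroid (higher = more segregated),
- between-network dispersion: Euclidean distance between two network
  centroids.

`gradlink` implements the full analysis chain for this design, for
node-parcellated inputs (no voxel or surface processing):

1. MPC/FC construction, affinity sparsification (top 10% per row,
   normalized-angle kernel), diffusion-map embedding, Procrustes alignment
   of every subject/session embedding to a group template, and dispersion
   statistics for the visual (VN) and fronto-parietal (FPN) networks;
2. logarithmic learning-curve fits (`accuracy = a + b ln t`), standardized
   multiple regressions of learning rate on dispersion changes, with
   permutation tests, leave-one-out cross-validation, and a baseline/pre
   specificity permutation;
3. PLS regression (X = nodes x genes expression, Y = six group-mean
   gradient-change maps; `X = TP' + E`, `Y = UQ' + F`) with per-component
   permutation p-values (row permutation or variogram-matched spatial
   surrogate maps), PCA-denoised expression variant, Procrustes-corrected
   bootstrap z-weights, FDR inverse quantile transformation (FIQT), and
   hypergeometric gene-set enrichment with Benjamini-Hochberg correction;
4. an intervention arm (active stimulation vs sham) with control-group
   normalization;
5. a first-class synthetic-data generator with planted effects (gene
   drivers, VN microstructural dispersion increase, FPN functional
   dispersion increase, dispersion-behavior coupling) so that every stage
   is testable against known ground truth.

## Worked example

```r
library(gradlink)

res <- run_multisession(default_run_config(seed = 1))

round(100 * res$pls$fit$var_explained, 2)   # % Y-variance per PLS component
#> [1] 11.28 10.63  3.62
res$pls$perm$p                              # permutation p per component
#> [1] 0.001996008 0.001996008 0.045908184
length(res$pls$significant$PLS1)            # genes with |z_adj| > 1.96
#> [1] 54
print(res$behavior_models$FC$regression)
#> F(3, 16) = 9.493, p = 0.0008, R2 = 0.640 (adj 0.573), n = 20
#>                   beta       t      p
#> VN-within      -0.0243 -0.1596 0.8752
#> FPN-within      0.8058  5.2619 0.0001
#> VN-FPN-between -0.0173 -0.1143 0.9104
res$flags$fc_measure
#>      VN-within     FPN-within VN-FPN-between
#>          FALSE           TRUE          FALSE
```

Reading: the three PLS components explain 11.3%, 10.6% and 3.6% of the
variance in the gradient-change maps; the first two (which carry the
planted gene association) are permutation-significant. Of 2,000 genes, 54
survive FIQT at |z| > 1.96, including all 50 planted drivers. Changes in
FC dispersion explain 64% of the variance in learning rate, driven by the
FPN within-network term (standardized beta 0.81) — exactly the planted
coupling, and nothing else, is flagged.

The numbered scripts in `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` ... `06_intervention.R`), writing tables under
`results/`.

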