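---
title: "Normative-model subtyping of regional gray matter volume: models, parameters and design choices"
author: "normsub package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative-model subtyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`normsub` implements a complete analysis chain for discovering patient
subtypes from individualized deviations of regional gray matter volume
(GMV) and for placing those subtypes in a molecular context:

1. **Harmonization** of multi-site data (parametric empirical-Bayes
   ComBat).
2. **Normative modeling** of regional GMV in healthy controls with
   Gaussian process regression on age and sex, cross-validated by
   repeated k-fold and leave-one-site-out (LOSO) schemes, and conversion
   of patients into deviation Z-scores with extreme-deviation overlap
   maps.
3. **Subtyping**: a SigClust test for the existence of cluster structure,
   correlation-distance K-means, ensemble voting over cluster validity
   indices for the number of clusters, and stability quantification by
   subsample and LOSO adjusted Rand indices (ARI).
4. **Contrasts**: covariate-adjusted regional t-maps per subtype, the
   between-subtype spatial correlation, and demographic comparisons.
5. **Molecular contextualization**: multilinear models of subtype t-maps
   on neurotransmitter receptor/transporter density maps with permutation
   inference, dominance analysis, and excitatory/inhibitory class
   contributions.
6. **Transcriptomic contextualization**: a correlated gene expression
   (CGE) connectome, neighbor-deviation coupling, Steiger Z comparison of
   dependent correlations, and disease-epicenter mapping by rank plus
   permutation.

A synthetic-data module generates multi-site cohorts, expression
matrices, receptor maps and epicenter-diffused deviation fields with
known ground truth, so every stage can be exercised and validated without
any external data. Consortium imaging archives, donor brain expression
atlases and PET receptor atlases are all access-restricted or too large
to bundle; the synthetic harness is therefore a first-class, tested
component, not a fixture.

# The models

## ComBat harmonization

Per region $g$ the observed value for subject $i$ at site $s$ is modeled
as
$$ y_{isg} = \alpha_g + X_i \beta_g + \gamma_{sg} + \delta_{sg}
\varepsilon_{isg}, $$
with protected covariates $X$ (age, sex and the patient/control
indicator by default — protecting the group indicator prevents the
harmonization from absorbing diagnosis signal). Standardized site
locations $\gamma$ and scales $\delta^2$ are shrunk toward a normal and
an inverse-gamma prior respectively by the standard iterative EB
update (tolerance `1e-4` on successive estimates, cap 500 iterations),
and the data are reconstructed without the site terms. Parametric priors
were chosen over nonparametric ones for determinism and speed. The
fitted `CombatModel` (grand effects, shrunk site parameters, pooled SDs,
prior hyperparameters) is returned and serializable to JSON, which is
why ComBat is implemented in the package rather than delegated: the
audit trail of the shrunk site parameters is part of the module
contract. The implementation is checked against an independent reference
implementation in the test suite.

Whether controls and patients should be harmonized jointly or separately
is genuinely open; the default harmonizes jointly with the group
indicator protected, which keeps the two groups on one scale while
shielding diagnosis-related variance.

## Gaussian process normative model

One GP per region with kernel
$$ k(x, x') = \sigma_f^2 \exp\!\Big(-\tfrac12 \sum_d
\frac{(x_d - x'_d)^2}{\ell_d^2}\Big) + \sigma_n^2 \,\delta_{x x'}, $$
fitted on healthy controls only, predictors age and sex standardized to
the training mean/SD, targets centered and scaled per region.
Hyperparameters maximize the marginal likelihood (L-BFGS-B on the log
scale with analytic gradients, box bounds $e^{\pm 8}$, multiple random
restarts; 2–3 restarts are ample for a 2-predictor kernel). A sum of a
smooth anisotropic term and white noise is the simplest kernel that can
express "smooth age trend plus sex offset plus noise"; nothing more
exotic is warranted by two predictors.

A subject's deviation is
$$ Z_{sg} = \frac{y_{sg} - \mu^*_{sg}}
{\sqrt{\sigma^{*2}_{sg} + \sigma_{n,g}^2}}, $$
with $\mu^*, \sigma^{*2}$ the predictive mean and latent variance at the
subject's covariates. Including the noise variance in the denominator is
the convention of normative modeling: it makes held-out healthy controls
approximately standard normal, so the $\pm 1.96$ rule (two-tailed 95%)
flags genuinely extreme individuals. Patients' Z-scores are computed
from the model trained on **all** controls; cross-validation serves only
to certify model validity beforehand.

Model validity is reported as the standardized mean squared error
$$ \mathrm{SMSE}_g = \frac{\sum_{\mathrm{test}} (y - \hat y)^2}
{\sum_{\mathrm{test}} (y - \bar y_{\mathrm{test}})^2}, $$
so predicting the held-out mean scores exactly 1 (the package exposes
this baseline through `predictor = "mean"` as a normalization anchor).
K-fold partitions are stratified by site and drawn independently on
every repeat. Note a small-sample property: because the denominator uses
the $n-1$ test variance, even a perfect model sits slightly above
$1 - R^2$ for small test folds; validation cohorts in the tests are
sized so this bias is minor.

## SigClust

The statistic is the 2-means cluster index — the within-cluster sum of
squares of the best bipartition divided by the total sum of squares.
The null hypothesis is a single Gaussian; null data are simulated with a
diagonal covariance whose entries are eigenvalue estimates floored at a
robust background noise variance $(\mathrm{MAD}/0.6745)^2$. One
numerical choice matters here: raw sample eigenvalues are themselves
spread by Wishart sampling noise, and simulating from them makes the
null *more* elongated than the data, which at moderate $p/n$ (e.g. 40
features, 150 subjects) collapses the rejection rate to zero. The
package therefore applies Ledoit–Wolf linear shrinkage of the covariance
toward the spherical target before taking eigenvalues. With that
correction the test holds its nominal level in the package's calibration
tests while retaining full power for separated clusters (the minimum
attainable p is reached at 10-SD separation). The p-value uses the
add-one rule $(1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(n_{sim}+1)$.

## Correlation-distance K-means and the validity ensemble

Subjects are compared by $1 - r$ between their regional deviation
profiles: two patients belong together when their deviation *patterns*
are proportional, regardless of overall severity. Rows are centered and
scaled to unit norm, where the correlation is a dot product; Lloyd
iterations alternate nearest-centroid assignment with re-normalized mean
centroids, the objective (total within-cluster correlation distance) is
asserted non-increasing within each restart, and the best of `nInit`
random restarts wins. Empty clusters are reseeded at the point farthest
from its centroid. The global optimum is verified against exhaustive
search over all bipartitions on small instances in the tests.

The number of clusters is chosen by ensemble voting. Rather than
reimplementing the full battery of 26 indices of the NbClust tradition,
a documented default set of nine indices votes (silhouette,
Calinski–Harabasz, Davies–Bouldin, Dunn, C-index, gap statistic with the
one-standard-error rule, PBM, McClain–Rao, point-biserial); the set is
pluggable and odd-sized to reduce ties, and remaining ties go to the
smallest k (parsimony). The claim being operationalized is *ensemble*
voting, not the identity of any single index. An index that fails on a
given k abstains.

Stability is reported as the mean ARI between the full-sample solution
and (a) 100 re-clusterings of random 90% subsamples, (b) LOSO
re-clusterings. ARI is computed from the pair-counting contingency
formula and cross-checked against an independent implementation and a
literal pair-walking oracle. Cluster-label alignment (for cross-atlas
comparisons) solves the assignment problem on the confusion matrix
exactly for k ≤ 8 via permutation search — the regime this package
operates in — with a greedy fallback above.

## Regional contrasts

Voxel-wise inference is out of scope: the molecular and epicenter stages
only ever consume *region-level averaged* unthresholded t-statistics, so
the package computes region-level OLS contrasts directly
(`[intercept, group, age, sex, site dummies]`), which preserves the
downstream contract. This is the one deliberate methodological
substitution in the package. Sites lying entirely within one group have
dummies collinear with the group column; they are dropped from the
design with a loud warning naming the site. Significance masks are
Bonferroni at family $\alpha = 0.05$ across regions.

## Receptor models and dominance analysis

The subtype t-map is regressed on all (Z-scored) receptor density maps;
significance comes from permuting the region order of the t-map (10,000
iterations by default) and comparing $R^2$; Bonferroni correction spans
the subtype models fitted in one run. The permutation null does not
preserve spatial autocorrelation; for a volumetric parcellation there is
no canonical spin test, and this is flagged as the weakest inferential
link (the hook for a variogram-matched null is the permutation step
itself). Dominance analysis enumerates all $2^k$ predictor subsets
(normal-equation sub-solves of the full cross-product matrix, capped at
20 predictors), averages the $R^2$ increase a predictor brings to
sub-models of each size, and reports total dominance values that sum to
the full-model $R^2$ to $10^{-10}$; correctness is checked against a
naive re-enumeration oracle. Class contributions sum total dominance
within the excitatory and inhibitory classes; the class table for real
PET maps ships as an editable TSV (`inst/extdata/`), since published
atlases do not fix a unique categorization.

## CGE connectome, coupling, and epicenters

Genes are Z-scored across regions; the CGE weight $w_{ij}$ is the
Pearson correlation of regional expression profiles, negatives zeroed,
diagonal zeroed. The neighbor deviation of region $i$ is
$$ \tilde d_i = \frac{1}{N_i} \sum_{j : w_{ij} > 0} w_{ij} d_j, $$
with $N_i$ the number of positively connected neighbors; regions with
$N_i = 0$ are undefined and excluded listwise. Normalization by $N_i$
(not by $\sum_j w_{ij}$) follows the neighbor-deformation convention of
the network-spreading literature. Coupling is $\mathrm{cor}(d, \tilde
d)$; a subtype's coupling is compared with the all-patients coupling by
Steiger's Z for dependent, non-overlapping correlations (Fisher
transforms, asymptotic covariance from all six pairwise correlations,
pooled-r denominators — the $\bar Z_2^*$ variant), the structurally
correct case since the two correlations share no variable but are
computed on the same regions.

Epicenters: regions are ranked by $d$ and by $\tilde d$ (mean of the two
ranks = epicenter likelihood), against a null that permutes $d$ over
regions and recomputes everything. "Ascending" places the most negative
values first, appropriate for decrease-dominated maps; for an
increase-dominated subtype the direction flag flips to descending (the
pipeline chooses by the sign of the median t). The p-value is one-sided
(at least as epicenter-like as chance) with the add-one rule; epicenters
are regions with $p < 0.01$ by default.

# The synthetic harness

`generateCohort()` draws, per region, a baseline in [3, 9] (GMV units),
an age slope in [−0.02, −0.005] per year, a sex offset in [−0.2, 0.2], a
per-site additive shift (SD 0.4) and a multiplicative residual scale in
[0.8, 1.25] — the ComBat generative model, so harmonization has a
well-posed target. Ages are uniform on [18, 65]; sex is Bernoulli
(default 55% female, coded 1). Patients split evenly into two subtypes
carrying **opposite** deviation patterns on two disjoint region blocks
(a "cerebral-like" block where subtype 1 gains volume, a
"cerebellar-like" block where it loses volume; subtype 2 mirrors it),
scaled by `subtypeEffect` (default 1.5) residual SDs. The default cohort
is 4 sites × (50 controls + 50 patients) over 60 regions — large enough
for stable GP fits and clustering, small enough that the full chain runs
in minutes on one CPU.

`generateMolecularAssets()` builds (a) an expression matrix with
community-block means so the CGE is modular, and (b) receptor maps, each
a recorded mixture of the subtype pattern and a smooth nuisance field
plus noise. Three identifiability choices matter and were made once,
deliberately:

* excitatory receptors load on the cerebral-like block and inhibitory
  receptors on the cerebellar-like block (disjoint supports). If both
  classes loaded on the same signed pattern they would be confounded by
  construction and *no* method could attribute class-level contribution;
* pattern loadings are moderate (|loading| in [0.2, 0.5]) so receptor
  maps are associated with, but not collinear through, the disease
  pattern;
* each receptor's nuisance field sits at its own harmonic frequency —
  sinusoids at distinct integer frequencies are orthogonal on the region
  grid. Random smooth fields drawn from the same few low frequencies
  collide at |r| ≈ 0.3 in a 60-region parcellation, which silently hands
  dominance credit to irrelevant receptors.

`injectEpicenterPattern()` seeds a deviation on chosen epicenters and
iterates $d \leftarrow (1-\beta) d + \beta \bar W d$ with the
row-normalized positive CGE $\bar W$; rows without positive connections
propagate unchanged (with a warning). The coupling statistic does not
require a generative spreading model — this diffusion is a test-harness
choice. Recovery tests plant the epicenters as a transcriptomically
coherent set (members of one expression community, with ~10 communities
of ~6 regions): the epicenter statistic rewards regions whose
*neighborhood* is abnormal, so scattered point sources in a dense graph
are not epicenters in this framework's own terms, and planting them as
such would test a different hypothesis than the statistic encodes.
Diffusion in the recovery setting runs 4 steps — enough to spread
abnormality into the neighborhood, not enough to homogenize the field.

What the harness does **not** emulate: spatial autocorrelation of real
parcellations, realistic anatomy or scanner physics, donor-specific
expression noise, receptor maps with realistic cross-correlation
structure, or site-by-covariate confounding. Passing tests demonstrate
that the algorithms are implemented correctly and are calibrated under
the stated generative model — not that real MDD cohorts contain two
subtypes.

# Numerical choices and degenerate inputs

* Ties exactly at the deviation threshold (|Z| = 1.96) are **not**
  extreme (strict inequality).
* Rank ties use average ranks throughout the epicenter stage.
* Constant rows (undefined correlation), constant regions (undefined
  Z-scoring), single-site inputs, sites with < 3 subjects, singular
  designs, unclassified receptors and region-id mismatches all raise
  errors naming the offender; near-collinear receptor columns (condition
  number > 1e8) are refused.
* All permutation p-values use the add-one rule, so the minimum
  attainable p is $1/(n_{perm}+1)$ and p = 0 never occurs.
* Every stochastic routine takes an explicit seed; per-stage seeds are
  derived deterministically from the pipeline master seed and recorded
  in the report bundle. Identical config + seed reproduces bundles
  byte-identically.

# Problem sizes in the validation suite

The test suite validates calibration at moderate sizes chosen as a
package design point: 400-control calibration cohorts, a 60-region
atlas, 20-seed subtype-recovery sweeps, 200-run SigClust level checks
(200 null simulations each), 1,000-replicate Steiger Z calibration, and
2,000–10,000 permutation nulls. These sizes give the properties being
tested enough resolution (binomial bounds, KS tests) while keeping the
whole suite in the minutes range on a single CPU.

# Known limitations

* The permutation nulls (receptor models, epicenters) ignore spatial
  autocorrelation; on real parcellations they are anticonservative.
* The GP normative model assumes homoskedastic Gaussian residuals; no
  warped or heteroskedastic likelihoods are provided.
* Nonparametric-prior and longitudinal ComBat variants are out of scope.
* The nine-index ensemble is a curated replacement for the larger
  battery in the NbClust tradition; with strongly non-convex cluster
  shapes its vote can differ from the full battery's.
* `atlasSwapCompare()` requires an explicit region correspondence; no
  image-space resampling is performed (optional NIfTI ingestion is
  deliberately isolated from the core).
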