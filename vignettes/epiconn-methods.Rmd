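---
title: "Methods: epigenetic age acceleration, cognition, and connectomes"
author: "epiconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic age acceleration, cognition, and connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epiconn)
```

# The scientific question

Epigenetic clocks estimate biological age from CpG methylation; the residual
of a mortality-trained clock (GrimAge) on chronological age -- *AgeAccelGrim*
-- measures how much faster or slower a person is aging than their calendar
age predicts. By construction this age acceleration is orthogonal to
chronological age, so any association it carries with cognition or brain
organization is information that chronological age does not contain.

`epiconn` implements the full analysis chain needed to ask, in a cohort of
healthy older adults measured over repeated cognitive sessions with
resting-state fMRI and blood methylation:

1. How many latent cognitive domains does a 15-item battery span, and what
   are per-person scores on them? (*bootstrap exploratory graph analysis*)
2. Is age acceleration associated with those domain scores after adjusting
   for age, sex, testing lags, and blood cell composition? (*multivariate
   hierarchical robust Bayesian regression*)
3. Can age acceleration (and the domain scores) be predicted from
   functional-connectivity edges, and which brain regions drive the
   prediction? (*ridge connectome-based predictive modeling with
   permutation inference and eigenvector-centrality importance*)

Because no participant-level data are deposited for studies of this kind,
the package ships a first-class synthetic-cohort generator whose defaults
encode the published study conditions; every stage is exercised and tested
against it.

# The synthetic cohort: what it emulates

`cohort_config()` defaults encode the cohort descriptors: 103 participants
(98 imaged), three testing sessions, ages truncated-normal 68.98 ± 5.68 in
[59, 81] years, age acceleration Normal(0, 3.49) years residualized against
age by exact least squares (so the sample correlation is zero to machine
precision), 73/103 female, a log-normal blood-draw-to-testing lag matched
to mean 133.54 / SD 124.13 days, and seven i.i.d. standard-normal
cell-count adjustment columns (the analysis needs them only as covariates,
so their marginal scale is irrelevant).

`effect_config()` fixes the generating structure of the battery: four
latent factors (processing speed, memory, spatial/reasoning, vocabulary)
with standardized age-acceleration effects (-0.31, -0.33, -0.26, -0.24),
age effects (-0.39, -0.45, -0.33, -0.20), and per-session practice effects
(0.06, 0.01, 0.02, -0.18). Each factor's residual SD is solved internally
so the factor has unit population variance -- that is what makes the
configured betas standardized coefficients and makes large-n least squares
on the generated data an oracle for them. Choices the source conditions do
not pin down, fixed once here:

* **Factor residual correlation 0.45** (compound symmetric): mimics the
  positive manifold of inter-domain correlations.
* **Item loading 0.7, item noise SD `sqrt(1 - 0.7^2)`**: unit-variance
  items with reliability ~0.5, typical of single cognitive scales. Items
  are standardized on the pooled sample, not per session -- per-session
  standardization would absorb exactly the session practice effects the
  generator calibrates, leaving nothing for the model stage to recover.
* **Subject random effects**: intercept SD 0.5, session-slope SD 0.1,
  independent across factors (fitted but not reported quantities in this
  literature; values chosen as a realistic between-person spread for
  standardized scores).
* **Connectomes**: baseline edges Normal(0.2, 0.2) in Fisher-z units, a
  typical resting-state range. Signal lives on the edges among 20
  designated "Limbic" nodes; each signal edge equals
  `0.2 + 0.2 * (sign * rho * z(phenotype) + sqrt(1 - rho^2) * noise)` with
  `rho = 0.5`, so its population correlation with the phenotype is exactly
  `sign * rho` and its marginal matches the baseline edges. Signal edges
  alternate between the age-acceleration and memory phenotypes, giving the
  two analyses overlapping important regions, as observed empirically. The
  signal-edge density is the generator's calibration knob: against the
  random Gram matrix of ~35,000 baseline edges, a planted block must be
  dense enough for ridge prediction to sit at the accuracy scale reported
  for real connectomes (median Spearman rho ~0.3 and above); all 190
  within-block edges carry effect by default, which puts cross-validated
  prediction of age acceleration at median rho ~0.5-0.65 across cohort
  realizations.
* **Sessions**: random effects only; no residual autocorrelation across
  sessions is generated (none is reported to emulate).

What the generator does **not** emulate: raw test scales, voxel-level BOLD
data, methylation arrays, non-Gaussian item distributions, missingness,
motion artifacts, or distance-dependent connectome structure. Tests passing
on this generator demonstrate the estimators' correctness and calibration
under the stated conditions, not robustness to those real-data features.

# Stage 1: bootstrap exploratory graph analysis

`fit_glasso_network()` estimates a Gaussian graphical model over the items:
the graphical-lasso penalized likelihood is solved by block coordinate
descent (compiled core), the penalty chosen by EBIC with `gamma = 0.5` over
100 log-spaced penalties from `lambda_max` (the largest absolute
off-diagonal correlation, where the graph is empty) down to
`0.1 * lambda_max` -- the de-facto conventions of psychometric network
analysis. The selected precision matrix is reported as partial correlations
`w_ij = -theta_ij / sqrt(theta_ii * theta_jj)`. The diagonal is not
penalized. The solver is verified in the test suite against an independent
ADMM solver of the same convex objective.

`detect_communities()` maximizes weighted modularity on `|W|` with Louvain
(20 seeded restarts, best modularity kept, ties broken by the
lexicographically smallest label vector) or walktrap as a deterministic
cross-check. `boot_ega()` adds the parametric bootstrap: replicates drawn
from a multivariate normal with the sample correlation (a switch allows
the model-implied correlation instead; the sample correlation is the
default because the sparsified matrix can understate dependence that the
replicates are supposed to carry), EGA refit per replicate, the median
network and its communities taken as the typical structure, and item
stability computed after matching replicate communities to typical ones by
maximal Jaccard overlap (ties toward the smallest typical index).

`network_scores()` turns a community solution into per-person scores: an
item's loading on its community is the sum of `|w|` to the community's
other items; loadings are normalized to sum to one within the community,
applied to z-scored items, and the resulting score standardized. Only
own-community items enter a score -- the simplest loading rule consistent
with scores being "weighted composites of the items in each community";
it is fixed and documented because downstream coefficients depend on it.

# Stage 2: multivariate hierarchical robust regression

For observation *i* (subject *s*, session *t*) and response *j* (the four
network scores, standardized):

$$y_{ij} = x_i'\beta_j + u^{(0)}_{s j} + u^{(1)}_{s j} t_i + e_{ij},
  \qquad e_{ij} \sim t_{\nu_j}(0, \sigma_j)$$

with the 13-column fixed design: intercept, age acceleration, age, testing
lag (standardized), session number (raw 1..3, so its coefficient is a
per-session practice effect), a female indicator, and the seven cell-count
covariates (standardized). The 2R-dimensional subject effect
`(u0_1, u1_1, ..., u0_R, u1_R)` is jointly normal with an unstructured
covariance -- this is where the cross-domain correlation of the responses
is modeled. The residuals are per-response Student-t: heavier-tailed than
Gaussian, hence robust to outlying sessions, and per-response degrees of
freedom allow the vocabulary domain its deliberately heavier
`Gamma(12, 0.1)` prior (vocabulary responses chronically underestimate
`nu`); all other responses use `Gamma(2, 0.1)`. Remaining priors:
coefficients `N(0, 10)`, intercepts `t(3, 0.2, 2.5)`, residual scales
half-`t(3, 0, 2.5)`.

A residual-correlation formulation (one multivariate-t across responses)
was considered and rejected: a single multivariate-t forces one shared
`nu`, which is incompatible with the per-response degrees-of-freedom
treatment above; correlated subject-level effects carry the cross-domain
dependence instead.

**Computation.** The model is fit by a blocked Gibbs sampler written for
this package (no general-purpose MCMC engine for this model class is
available here), using the Gamma scale-mixture representation of the
Student-t. Design choices that matter:

* `nu` and `sigma` are updated by *partially collapsed* Metropolis steps on
  the marginal t-likelihood (mixture weights integrated out), cycled five
  times per sweep along their shared ridge, after which the weights are
  redrawn -- without collapsing, the weight coupling stalls both
  parameters.
* The fixed-effect and random-effect blocks are conjugate and are cycled
  (2 cycles of beta-then-u, with 3 inner cycles of u-then-covariance),
  approximating the exact joint draws whose couplings (subject-level
  predictors with random intercepts; the variance-hierarchy funnel)
  otherwise dominate the autocorrelation. The per-subject draw is compiled
  (RcppArmadillo).
* The random-effect covariance carries the Huang-Wand (2013) hierarchical
  inverse-Wishart prior with `nu = 2`, `A = 2.5`, whose implied marginals
  are half-t(2, 2.5) SDs and uniform(-1, 1) pairwise correlations -- the
  conjugate analogue of a half-t/LKJ(1) pair, chosen so this block stays a
  Gibbs draw.
* The intercept's t prior and the residual scale's half-t prior are handled
  exactly via auxiliary-variable mixtures.

Desk-scale sampling defaults are 4 chains of 2,000 iterations (1,000
warmup); the publication-scale configuration (7 chains of 20,000 with
10,000 warmup) is available through `sampler_config()`. Convergence is a
contract, not a hope: `summary()` and `posterior_predictive_check()` refuse
a fit whose fixed-effect coefficients miss split R-hat < 1.01 or bulk ESS
> 400 unless explicitly overridden; diagnostics for all stored parameters
(including `nu`, `sigma`, and the random-effect SDs) are reported.

**Inference.** Point estimates are MAPs -- the mode of a
Silverman-bandwidth kernel density over each marginal (the estimator is a
choice; medians and credible intervals are reported alongside). The
two-tailed posterior probability is twice the minority tail mass
(`2 * min(#draws > 0, #draws < 0) / N`, draws at zero counting to neither
side -- a measure-zero event), and the four age-acceleration probabilities
are adjusted across responses by Benjamini-Hochberg. Posterior-predictive
replicates are generated inside the sampler (one per kept draw, conditional
on the drawn random effects) and compared with the observed mean, SD, min,
and max per response. Note the classic caveat tested explicitly in the
suite: under a Gaussian-limit fit a single gross outlier inflates the
*extreme-value* statistic's tail probability, not the SD's, because the
fitted scale absorbs it.

# Stage 3: ridge connectome-based predictive modeling

Connectivity matrices are Fisher-z transformed Pearson correlations of
cleaned, concatenated node time series (`clean_timeseries()` projects out
confound columns and a discrete-cosine basis of components slower than
0.008 Hz -- regression, not causal filtering; `|r|` is clipped at
`1 - 1e-7` before `atanh`). The lower triangle in row-major order (i > j,
0-based) is the canonical edge vector -- 35,778 edges for 268 nodes -- and
that ordering is frozen because coefficient vectors are persisted in it.

The phenotype (one session-mean value per imaged subject) is residualized
on its confounds by least squares *once, on the full sample, before
cross-validation* -- matching the published procedure; this is a known
compromise in the CPM literature (confound coefficients see all subjects),
and the package keeps it as the default deliberately for fidelity.
Prediction then proceeds by 100 repeats (20 at desk scale) of outer
10-fold cross-validation with the ridge penalty tuned per training fold by
inner 2-fold mean squared error over 50 log-spaced penalties in
`[1e-2, 1e5]`; edges are mean-centered with training-fold statistics only,
and held-out subjects are provably untouched during tuning (a perturbation
probe in the test suite corrupts them and demands identical tuning).
With 35,778 edges and ~100 subjects everything is solved in the dual:
the full Gram matrix is computed once and per-fold centered submatrices
are obtained by double-centering identities, with one eigendecomposition
per training set serving every penalty on the grid.

Performance is the Spearman correlation of out-of-fold predictions with
the observed phenotype (rank prediction is what matters), aggregated
across repeats by the median. Significance uses the permutation null:
phenotypes are permuted across subjects and a single-repeat pipeline is
rerun per iteration (running all repeats per iteration would multiply cost
a hundredfold for no change in the null's location); the non-parametric
p-value is the fraction of null values at or above the observed median --
zero is possible, and an add-one smoothed variant exists behind a flag.

**Importance.** Fold-averaged coefficient vectors are devectorized and
split by sign into two nonnegative symmetric networks (the negative part
in absolute value, since eigenvector centrality requires nonnegativity).
Centrality is the principal eigenvector by power iteration (tolerance
1e-10), unit Euclidean norm -- the convention that puts 268-node hub
centralities in the 0.1-0.2 range; it is computed on the full signed parts
by default (a flagged alternative computes it on thresholded networks, as
the source procedure is ambiguous). The top 2% of edges per sign form the
visualization networks (ties broken by canonical edge index), and the
lobe-pair summary reports, per unordered lobe pair, the combined edge
count of the high- and low-phenotype networks standardized by the number
of possible edges between the pair (size) and the signed high-minus-low
difference (color) -- the numeric content of a Hinton diagram.

# Orchestration

`run_pipeline()` chains simulate, EGA, model, rCPM (phenotype and
control-adjusted confound variants: the age-acceleration and age analyses
control for each other plus sex and testing lag, adding the four cognitive
scores in the adjusted variants; cognitive phenotypes control for sex and
lag, adding age and age acceleration in the adjusted variants), and
importance. All 103 subjects feed the EGA and model stages; the 98 imaged
subjects feed the connectome stage, with session-mean phenotypes (the
source analyses predict one value per person; how sessions were collapsed
is not stated -- the session mean is assumed and flagged here). Stage
seeds derive from the global seed as
`(seed * 97 + stage_index * 1009) mod (2^31 - 1)`, so any stage reproduces
in isolation, and the manifest records per-stage seeds and checksums
(identical configuration implies identical checksums).

# Numerical choices and degenerate inputs

* GLASSO: coordinate-descent tolerance `1e-6` scaled by the mean absolute
  off-diagonal correlation; exact zeros below `1e-12` are hard zeros.
  Constant items and n < 4 raise errors.
* Correlations: constant time-series columns produce zero edges with a
  warning; `|r|` clipping keeps `atanh` finite.
* Rank-deficient confound matrices in time-series cleaning fall back to a
  pseudoinverse with a warning; rank-deficient phenotype confounds are an
  error naming the collinear columns.
* Louvain on an empty graph returns singleton communities with a warning;
  modularity local optima on toy graphs are flagged and their rate
  recorded by the tests rather than treated as failures.
* Ridge penalty ties select the smaller penalty; fold sizes differ by at
  most one; `n >= 2 * outer_k` is enforced.
* Power iteration on a disconnected network concentrates on the dominant
  component and warns.

# Problem sizes used by the test suite

The suite runs the full stack at sizes chosen to make its statistical
assertions sharp rather than exhaustive: dimensionality recovery over 20
seeded cohorts at the default n = 103; effect recovery on one n = 1,000
cohort with the 4 x 2,000 desk sampler; connectome recovery at n = 98 with
268 nodes, 20 repeats, and a 200-iteration permutation null; bootstrap
stability demonstrations at 25-30 replicates; and null-calibration checks
(credible-interval coverage, permutation-p uniformity) at reduced seed
counts with the thresholds stated in the tests. The 1,000-replicate
bootstrap and 100-repeat/1,000-permutation connectome defaults remain the
package defaults.

# Known limitations

* The sampler is specific to this model family (per-response Student-t,
  intercept + one slope of random structure); it is not a general engine.
* The Huang-Wand covariance prior approximates, not equals, a
  half-t/LKJ(1) specification; with four responses the induced correlation
  prior is marginally but not jointly uniform.
* Network scores use the own-community loading rule; cross-community
  loadings are ignored, unlike factor-analytic scores.
* Full-sample residualization leaks confound information across CV folds
  by design fidelity; the leakage-safe variant is available by
  residualizing within training folds externally.
* The synthetic connectome generator plants linear edge-phenotype signal;
  it cannot probe nonlinear or network-topological predictive structure.
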