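---
title: "Predicting unobserved environments: models, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting unobserved environments: models, protocol, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envpls)
```

## The problem

A multi-environment trial (MET) phenotypes $J$ lines in $I$ environments
(locations, seasons, management regimes). The hardest prediction task a
breeding program faces is a *new* environment: no phenotype from the target
environment is available, so the training and testing distributions differ
systematically. `envpls` implements two predictors for this task and an
evaluation protocol — leave-one-environment-out (LOEO) — that measures
exactly it.

## The generative and benchmark model

Both the simulator and the Bayesian benchmark use the reaction-norm
variance-component model

$$y_{ij} = \mu + L_i + g_j + gL_{ij} + \epsilon_{ij},$$

with environment effects $L \sim N(0, \sigma^2_E H)$, line effects
$g \sim N(0, \sigma^2_g G)$, interaction effects
$gL \sim N(0, \sigma^2_{gL} (H \otimes G))$ and i.i.d. residuals with
variance $\sigma^2$. $G$ is the genomic relationship matrix of the lines
and $H$ the environmental relationship matrix of the environments;
$\otimes$ is the Kronecker product, so the interaction covariance between
cells $(i,j)$ and $(i',j')$ is $\sigma^2_{gL} H_{ii'} G_{jj'}$.

### Relationship matrices

`genomic_kinship()` and `env_kinship()` share one recipe: center and scale
every column to unit *sample* variance ($n-1$ denominator), drop constant
(monomorphic) columns with a logged count, and form $K = WW^\top/p'$ with
$p'$ the retained column count. The sample-variance convention gives the
exact identity $\mathrm{tr}(K) = n - 1$ when nothing is dropped, which the
tests exploit; dropping constant columns (rather than zero-imputing them)
preserves that identity and avoids 0/0. Whether the markers should instead
be scaled by $2\sum_k p_k(1-p_k)$ (the classical allele-frequency scaling)
is not settled usage; the default mirrors the covariate recipe so $G$ and
$H$ are exchangeable objects, and `method = "vanraden1"` switches to the
allele-frequency scaling. When no environmental covariates exist, $H$ is
the identity (`identity_kinship()`): environments are exchangeable a
priori, and for a held-out environment the main effect and interaction then
contribute predictive variance but no mean shift.

`kinship_sqrt()` returns the *symmetric* PSD square root
$L = U\,\mathrm{diag}(\sqrt{\lambda})\,U^\top$, unique and satisfying
$LL = LL^\top = K$, so post-multiplying a design matrix by it is well
defined regardless of transposition convention (a Cholesky factor would
not be). Eigenvalues in $[-10^{-8}\lambda_{\max}, 0)$ are clipped to zero
as floating-point noise; anything more negative is an error.

## The PLS route

The design matrices are 0/1 incidences $X_L$ ($n \times I$), $X_g$
($n \times J$) and $X_{gL}$ ($n \times IJ$), and the PLS predictor matrix
is their relationship-augmented concatenation
$X = [X_L L_E \mid X_g L_g \mid X_{gL}(L_E \otimes L_g)]$, of width
$I + J + IJ$ with the interaction block and $I + J$ without. Interaction
columns are ordered environment-major — column $(i-1)J + j$ is
(environment $i$, line $j$) — to match the block structure of
$L_E \otimes L_g$; this is the package-wide convention (any consistent
order is equivalent after PLS, but one must be fixed and documented).
Under unbalanced trials only *rows* are dropped; all $IJ$ interaction
columns are kept so the Kronecker multiplication stays well formed. The
incidence matrices are built dense: at the problem sizes this package
targets (up to a few thousand cells) a sparse path would add code without
measurable benefit.

`pls_fit()` is NIPALS with the SVD-of-cross-product start: for univariate
$y$ the first left singular vector of $E^\top f$ is just the normalized
cross-product. Numerical conventions that matter:

* **Score normalization.** Scores are normalized to unit Euclidean norm.
  One sometimes sees the normalization written with the squared norm
  $t^\top t$; the final coefficients $B$ are invariant to this choice, and
  the route-equivalence test ($X_{new}B$ vs $T_{new}b$, agreement to
  $10^{-10}$) pins that down.
* **Sign convention.** Each weight vector's largest-magnitude entry is made
  positive, so output is reproducible across linear-algebra backends.
* **Y-deflation** is performed even though it is redundant for a univariate
  response; it costs nothing and keeps the algorithm in its standard form.
* **Early stopping.** Extraction stops when the residual predictor matrix
  (or the cross-product) is numerically zero
  ($\|E\|_F < 10^{-12}\|X\|_F$), recording the effective component count.
* **Scaling flag.** Predictor columns are centered but by default *not*
  scaled: the augmented blocks are already on a common scale through the
  kinship roots. `scale = TRUE` is available for raw-covariate regressions.

`select_ncomp()` chooses the component count by k-fold cross-validated
RMSEP, pooled over held-out points, with the smallest count attaining the
minimum (ties break toward parsimony) and a default cap of
$\min(n_{train}-1, p, 30)$ — RMSEP curves on these augmented genomic
designs flatten early, and the cap keeps tuning cheap. A known behaviour of
the strict-minimum rule on noisy data is an occasional extra component
chasing noise; the package reports the whole RMSEP curve so users can apply
a one-standard-error style choice by hand if preferred.

## The GBLUP route

`gblup_fit()` is a Gibbs sampler. Each random term is represented in the
orthonormal eigenbasis of its kernel restricted to the observed cells
($Z K Z^\top = \Phi \Lambda \Phi^\top$, coefficients
$\delta \sim N(0, \sigma^2_k \Lambda)$): because $\Phi^\top\Phi = I$, each
block's full conditional is *diagonal* and a sweep costs two matrix-vector
products per term. The interaction kernel on observed cells is the
Hadamard product $H[e,e] \circ G[l,l]$, so the $IJ \times IJ$ Kronecker
matrix is never formed during sampling.

Variance components get scaled-inverse-$\chi^2$ priors with 5 degrees of
freedom and scales set so each term's prior mode implies an equal split of
the phenotypic variance across terms — the default-hyperparameter ethos of
standard Bayesian genomic-prediction software. Chain defaults are 12,000
iterations, 2,000 burn-in, thinning 5; tests and the acceptance script use
shorter chains (documented per call) after verifying that estimates agree
with long chains to three decimals on the cases exercised. `fix_varcomp`
pins any subset of variances, which turns the sampler into a
conjugate-Gaussian effect sampler used to validate it against the
closed-form `blup_oracle()` (GLS mean plus kernel cross-covariance — exact
best linear unbiased prediction, itself tested against a brute-force
Gaussian conditional).

Predictions for test cells are **Rao-Blackwellized posterior predictive
means**: at each kept draw, the conditional mean of every random term at
the test cells given the sampled training-cell effects
($C\,\Phi\Lambda^{-1}\delta$, with $C$ the test/train kernel
cross-covariance). Adding the conditional *draw* noise would leave the mean
estimand unchanged while inflating Monte-Carlo error, so the conditional
mean is used. For a wholly unobserved environment with $H = I$ all
cross-covariances through $H$ vanish and the prediction reduces to
$\mu + g_j$ — the structural limit of what this model can say about a new
exchangeable environment.

**An identifiability caveat** users should know: with each (environment,
line) cell observed once, $\sigma^2_{gL}$ and $\sigma^2$ are separated
only through the off-diagonal structure of $G$ within environments, and
with few environments the posterior for $\sigma^2_E$ tracks the *realized*
spread of the handful of drawn environment effects rather than the
generative variance. Posterior means for these two components are
therefore prior-influenced and noisy at small $I$ even when the sampler is
exact (the package validates the sampler against exact grid integration of
the marginal variance posterior on a small dataset). Line and residual
variances, which carry hundreds of effective observations, recover well.

## The LOEO protocol and metrics

`loeo()` holds out each environment once; PLS tuning runs entirely inside
the training environments (nested k-fold), the model is refit on the full
training set at the selected count, and the whole held-out environment is
predicted. GBLUP needs no tuning. Accuracy is
$\mathrm{NRMSE} = \mathrm{RMSE}/\bar y$ (undefined, and an error, for
mean-zero responses) and the comparison is
$RE = \mathrm{NRMSE}_{GBLUP}/\mathrm{NRMSE}_{PLS}$, with $RE > 1$ meaning
PLS superior and $RE = 1$ parity.

Two protocol details were genuinely open and are resolved as follows:

* **Inner CV folds.** Both 10-fold (the component-selection convention) and
  5-fold/80–20 (the nested-protocol convention) are standard descriptions;
  `select_ncomp()` defaults to 10 and `loeo()` to 5, both configurable.
  The discrepancy is documented rather than resolved.
* **Global NRMSE** is computed on the *pooled* concatenation of all
  held-out predictions (one ratio across environments); the mean of
  per-environment NRMSEs is also reported for comparison.

Lines appearing only in the held-out environment are allowed — their
effects are predicted purely through $G$ (GBLUP) or the marker-augmented
columns (PLS) — and counted per fold in the report. Reproducibility: one
master seed; per-fold seeds for the inner CV and the Gibbs chain are
derived deterministically from (environment ID, purpose), so a rerun is
bit-identical.

## The simulator

`simulate_met()` draws markers per locus as Binomial(2, $p_k$) with
allele frequencies uniform in a configurable range (default 0.1–0.9),
covariates as standard normals, and effects from the model above using the
**realized** $G$ and $H$ of the drawn data — so parameter-recovery
experiments are internally consistent rather than contaminated by
kinship-estimation error. Defaults (100 lines, 5 environments, 1,000
markers, variance components $(1, 1, 0.5, 1)$, intercept 10) emulate the
scale structure of elite yield-trial data: a few hundred lines, a handful
of environments, thousands of markers, heritable main effects with
moderate GE. Unbalancedness removes a configured fraction of cells
uniformly, resampling if a line or environment would be orphaned.

What the simulator does *not* emulate: linkage disequilibrium, population
structure, QTL architecture, spatial field trends, or trait networks.
Passing tests therefore demonstrate correctness of the algorithms under
the stated model, not performance claims on real breeding data, where
those unmodelled features drive much of the difficulty.
`truth_nrmse_floor()` exposes the residual-noise lower bound so any
method's test NRMSE can be sanity-checked against the best achievable.

## Marker quality control

`qc_markers()` applies, in order: (1) remove markers with more than 15%
missing calls (default), (2) impute remaining missing cells with the
expected dosage $2\hat p$ under the observed allele frequency
(real-valued; rounding would discard information that column
standardization uses anyway), (3) remove markers with MAF below 0.05
computed from the observed, pre-imputation calls. Whether a MAF filter
should run before or after imputation is ambiguous in common pipeline
descriptions; filtering on observed calls avoids letting imputed values
shift the frequency estimate. The pipeline is idempotent and never alters
observed cells. Recoding of unexpected heterozygous calls is out of scope
(assay-specific).

## Problem sizes used in the test suite

The suite exercises the full stack at desk scale: PLS exactness on
12×4 problems, the GBLUP/oracle agreement on a 4-line × 3-environment toy,
variance recovery at 100 lines × 5 environments over 10 replicate
simulations, and the LOEO benchmark on a GE-dominant trial of 30 lines ×
6 environments with 3 environmental covariates — chosen so that an
informative $H$ genuinely transfers signal to a held-out environment,
which is the regime where modelling GE pays. These sizes are the package's
own choices for fast, deterministic verification; all generators scale to
realistic dimensions.

## Known limitations

* Univariate response only (multi-trait PLS and GBLUP are out of scope).
* No dominance/epistasis kernels, pedigree matrices, or nonlinear kernels.
* REML is not implemented; fixed-variance prediction uses `blup_oracle()`.
* The Gibbs sampler's variance posteriors at small $I$ are
  prior-influenced (see the identifiability caveat above).
* The simulator's idealized marker model understates real-data difficulty.
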