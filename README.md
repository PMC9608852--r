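# envpls

Genomic prediction of **entire unobserved environments** in plant breeding
multi-environment trials (METs), for quantitative geneticists and breeding
analytics teams. When a breeding program must decide which lines to advance
into a season or location where nothing has been phenotyped yet, standard
random cross-validation is the wrong yardstick: the whole target environment
is missing from training. `envpls` implements and benchmarks two predictors
under exactly that scenario.

## The two models

**Partial least squares (PLS) on relationship-augmented designs.** The
phenotype vector over all observed (environment, line) cells is regressed on

```
X = [ X_L L_E | X_g L_g | X_gL (L_E ⊗ L_g) ]
```

where `X_L` (n × I), `X_g` (n × J) and `X_gL` (n × IJ) are 0/1 incidence
matrices for environments, lines and their interaction, `L_g` is the
symmetric square root of the genomic relationship matrix
`G = W Wᵀ / p` (W the column-standardized marker matrix), and `L_E` the
square root of the environmental relationship matrix `H = X_E X_Eᵀ / r`
built from environmental covariates (the identity when none exist). PLS
extracts latent variables by NIPALS — per component the weight
`w ∝ Eᵀf`, score `t = Ew` (unit norm), loadings `p = Eᵀt`, `q = fᵀt`,
deflation `E ← E − t pᵀ`, `f ← f − t q` — and maps back to original
coefficients via `R = W(PᵀW)⁻¹`, `B = R(TᵀT)⁻¹Tᵀy`. The number of latent
variables is chosen by minimizing cross-validated RMSEP on the training
environments only.

**Bayesian GBLUP reaction norm** (the benchmark):

```
y_ij = μ + L_i + g_j + gL_ij + ε_ij,
L ~ N(0, σ²_E H),  g ~ N(0, σ²_g G),  gL ~ N(0, σ²_gL (H ⊗ G)),  ε ~ N(0, σ²I)
```

fitted by Gibbs sampling with scaled-inverse-χ² priors on the variance
components.

**Evaluation** is leave-one-environment-out (LOEO): each environment in
turn is the entire test set; PLS hyperparameter tuning runs in a nested
k-fold cross-validation inside the training environments. Accuracy is the
normalized RMSE, `NRMSE = RMSE / ȳ`, and the headline comparison is the
relative efficiency `RE = NRMSE_GBLUP / NRMSE_PLS` (RE > 1 favours PLS).

## Worked example

```r
library(envpls)

sim <- simulate_met(J = 40, I = 4, p = 300, r = 3,
                    varcomp = c(env = 0.3, line = 1, ge = 0.5, resid = 0.5),
                    seed = 42)
report <- loeo(sim, inner_folds = 5,
               chain = c(iterations = 4000, burn_in = 1000, thin = 2),
               seed = 7)
print(report)
```

```
Leave-one-environment-out report: trait 'y', predictor E+G+GE
  env n_test n_train n_new_lines train_mean ncomp nrmse_PLS nrmse_GBLUP
1 E01     40     120           0     10.185    11    0.1313      0.1323
2 E02     40     120           0     10.361     7    0.1476      0.1662
3 E03     40     120           0      9.856     8    0.1019      0.1115
4 E04     40     120           0     10.018     3    0.1005      0.0977

Global (pooled held-out predictions):
  method nrmse_global nrmse_env_mean
1    PLS       0.1200         0.1203
2  GBLUP       0.1271         0.1269

Relative efficiency (NRMSE_GBLUP / NRMSE_PLS; >1 favours PLS):
  environment re_nrmse
1         E01   1.0077
2         E02   1.1263
3         E03   1.0941
4         E04   0.9724
5      Global   1.0592
```

Each row is one fold: environment `E02`, say, was predicted by models that
never saw any `E02` phenotype, with 7 latent variables chosen by the inner
CV; its PLS NRMSE of 0.148 means the prediction RMSE was 14.8% of the mean
phenotype. The Global RE of 1.059 says PLS beat GBLUP by about 6% in pooled
NRMSE on this simulated trial. `truth_nrmse_floor(sim)` (0.064 here) is the
residual-noise lower bound no predictor can beat.

File-based workflows use `read_met_dataset()` + `qc_markers()` (MAF and
missingness filtering with allele-frequency imputation), or the thin CLI at
`inst/cli/envpls.R` (`simulate`, `qc`, `loeo` subcommands).

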