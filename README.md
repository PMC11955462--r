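# hemil

Weakly supervised prediction of M2-macrophage infiltration from H&E
histopathology, with immune deconvolution labeling and survival analysis.

## The problem

Tumor-associated M2 macrophages mark an immunosuppressive tumor
microenvironment, and in serous ovarian cancer a high estimated M2
fraction is associated with worse overall survival. The fraction is
usually estimated from bulk gene expression by signature-based
deconvolution, or from immunohistochemistry. `hemil` implements the
alternative analyzed in recent digital-pathology work: predict the M2
group (high vs. low infiltration) *directly from routine H&E slides*
with a weakly supervised deep-learning pipeline, then ask whether the
imaging score stratifies survival.

The pipeline, end to end:

1. **Labels** — bulk expression is deconvolved against a gene × cell-type
   signature matrix by linear ν-support-vector regression
   (the CIBERSORT principle): for each sample solve a ν-SVR of the
   mixture *m* on the signature *S* (both z-scored), clamp negative
   coefficients, renormalize to the simplex, and keep the fit maximizing
   cor(Sŵ, m) over ν ∈ {0.25, 0.5, 0.75}. Samples with zero M2 fraction
   are excluded; the rest are dichotomized at the cohort **mean** M2
   fraction.
2. **Patches** — tiles are cut into 224×224 patches; patches that are
   ≥ 95% near-white background are discarded; pixels are standardized
   with the ImageNet channel moments (0.485, 0.456, 0.406) /
   (0.229, 0.224, 0.225).
3. **Classifier** — a residual CNN with `1 + stages·blocks·2 + 1`
   weighted layers (default 4 stages × 2 blocks = the classical 18-layer
   network), trained with cross-entropy and SGD (momentum 0.9) under a
   patient-level stratified 80/20 split; the checkpoint with the best
   validation accuracy is kept. Each patch inherits its patient's label —
   the weak supervision.
4. **Multiple-instance learning** — a patient is a *bag*, its patches are
   *instances*; the bag score pools instance probabilities by one of four
   strategies (mean, top-10 mean, top-100 mean, maximum;
   `k_used = min(k, bag size)`), thresholded at 0.5, and scored with
   accuracy, precision, recall, F1 = 2PR/(P+R), and the Mann–Whitney
   AUC (ties half-credited).
5. **Interpretation** — Grad-CAM heatmaps from the last residual stage:
   α_k = spatial mean of ∂(class logit)/∂A_k, heat = ReLU(Σ α_k A_k).
6. **Survival** — Kaplan–Meier curves, two-group log-rank test, and Cox
   proportional-hazards fits (Breslow ties, Wald 95% CI) of the M2 group
   and clinical covariates.

Because the original cohorts are external downloads, the package ships a
**synthetic cohort generator**: H&E-like tiles whose brown "macrophage"
blob density rises with a latent per-patient M2 fraction
(`base_density · (1 + visual_effect · m2)` blobs per megapixel of
tissue), bulk expression `S·f + noise`, and exponential survival with a
planted hazard ratio and calibrated uniform censoring. Everything is a
pure function of a seed, so the whole analysis loop runs offline and is
testable. The residual network itself — forward, backward, SGD, batch
norm, Grad-CAM gradients — is implemented in RcppArmadillo, since no
deep-learning framework is available to R here.

Audience: computational pathology and tumor-immunology researchers who
want a reproducible, dependency-light reference implementation of the
deconvolution-label → MIL-CNN → survival loop, and a test bed for its
statistical behavior.

## Worked example

The reference desk-scale experiment (40 synthetic patients, four patches
each, reduced 8-layer backbone, one CPU, a few minutes):

```r
library(hemil)
cfg <- e2e_demo_config("demo_run", seed = 1)
man <- run_pipeline(cfg)
str(man$metrics$mean)
```

```
List of 10
 $ tp       : int 3
 $ fp       : int 0
 $ fn       : int 0
 $ tn       : int 5
 $ accuracy : num 1
 $ precision: num 1
 $ recall   : num 1
 $ f1       : num 1
 $ auc      : num 1
 $ n        : int 8
```

The eight held-out patients (3 high / 5 low under the deconvolution
labels) are perfectly separated by mean-pooled bag probabilities: bag
AUC 1.0 — the planted texture signal is strong and the weak supervision
suffices to recover it. The survival arm of the same run fits the
planted group effect:

```r
read.csv("demo_run/cox_univariate.csv")
#>   covariate hazard_ratio   ci_low  ci_high      p_value  n n_events
#> 1 grouphigh      4.13969 1.849348 9.266527 0.0005493586 40       27
```

a hazard ratio of 4.1 (95% CI 1.8–9.3) against a planted true HR of 4 on
40 patients (27 observed deaths). The no-signal control,

```r
shuffled_label_control("demo_run", seed = 41)
#> [1] 0.4166667
```

re-trains on labels permuted across patients and lands near chance
(AUC ≈ 0.5), confirming the separation is carried by the planted
image–label association and not by the pipeline itself.

Grad-CAM overlays for validation patches are written under
`demo_run/gradcam/`; heat concentrates on blob-dense tissue regions.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulate the reference cohort, tile and filter it, derive
deconvolution labels, train the reduced backbone, aggregate the four MIL
strategies, evaluate, and fit the survival models — prints the
validation metrics per pooling strategy plus the univariate Cox fit, and
writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
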