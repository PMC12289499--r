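---
title: "Methods: robust radiomic selection and clinical-radiomic scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust radiomic selection and clinical-radiomic scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscore)
```

## Scope and model

`radscore` builds diagnostic scores for CT-negative adrenal glands in
primary aldosteronism. Each sample is one adrenal: label 1 when adrenal
venous sampling confirmed the CT-negative gland as the dominant-secretion
side, label 0 when it was the non-dominant side. Inputs are a samples ×
features table of radiomic descriptors (seven standard classes: shape,
first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM; 107 features by default) and
a 24-variable clinical table. The pipeline produces:

1. a **Radiomics Score** (RS): a linear combination of selected, robust
   radiomic features with penalized-regression coefficients plus an
   intercept, computed on features standardized with *training-set* means
   and standard deviations;
2. a **Clinical-Radiomic Score**: the fitted probability of a logistic
   model over RS and the retained clinical covariates.

The statistical heart is a stability-selection procedure: features are
retained not because one model picked them, but because they recur across
thousands of resampled modeling attempts that each had to pass two
explicit quality gates.

## The iterative selection loop

Per candidate (one iteration × one split ratio):

1. **Stratified split** at a train fraction from (0.8, 0.75, 0.7, 0.65,
   0.6, 0.55, 0.5). Stratification by label is a deliberate choice: the
   cohorts are balanced by design, and balanced splits make the balanced
   confusion matrices (and the kappa = 2·accuracy − 1 identity they imply)
   reproducible.
2. **Zero-variance drop** (exact-zero rule) and **standardization** with
   train statistics (sample SD, n−1 denominator; the RS values depend on
   this convention, so it is fixed package-wide). Standardizing a constant
   column is undefined, so the constant columns are removed before the
   scaling parameters are computed; both operations are train-set-only.
3. **Redundancy filter**: feature pairs with |r| > 0.9 and correlation-test
   p < 0.05 are pruned to one member. Pearson correlation is used when both
   features pass Shapiro-Wilk normality at α = 0.05, Spearman otherwise;
   p-values use the t reference for both (an approximation for Spearman,
   chosen so all pairs can be tested from two correlation matrices). The
   scan is greedy in column order; of a flagged pair the member with the
   larger permutation-screen p (weaker group separation) is dropped, ties
   broken lexicographically. The surviving set depends on scan order, which
   is why the order is fixed and documented.
4. **Permutation screen**: per-feature two-sample Monte-Carlo permutation
   test, statistic = absolute difference of group means on the standardized
   values, add-one correction p = (1 + #extreme)/(B + 1). One shared set of
   label permutations serves all features, which is statistically identical
   to per-feature draws and vectorizes the screen. Features with p ≥ 0.05
   are removed.
5. **Lasso at the CV-minimum penalty**: penalized linear regression of the
   0/1 label, penalty grid logarithmic over four decades downward from the
   smallest penalty nulling all coefficients (100 points), chosen by
   10-fold cross-validated mean squared error at its *minimum* (not a
   one-standard-error rule). The fold loop is written out explicitly over
   `glmnet` path fits; tests pin it to `cv.glmnet` at identical fold
   assignments.
6. **Dual acceptance gate**: the candidate is accepted iff the unpaired
   DeLong test finds no train/test ROC difference (p > `delong_alpha`) and
   the test-set RS separates the groups (permutation p < 0.05). The DeLong
   gate level is a configuration knob (`delong_alpha`, default 0.05)
   because the procedure is described with both p > 0.05 and p > 0.50 in
   its source; the package takes the methods-level statement as default
   and leaves the stricter variant one argument away.

Accepted candidates increment a selection count for each feature with a
nonzero Lasso coefficient (per accepted model, so a feature can score up to
7 per iteration). At full scale — 1000 iterations × 7 ratios = 7000
candidates — features selected **strictly more than 100 times** form the
robust set. Counting per accepted model (rather than once per iteration) is
the reading consistent with "seven models per iteration"; both the count
log and all per-candidate records are retained in the `selection_result`.

Every candidate derives an independent RNG substream from the master seed,
so any single candidate can be reproduced in isolation and the whole loop
is bit-reproducible.

## The six model families

On the robust features the derivation cohort is re-split 6.5:3.5 and six
families are trained on standardized features: ridge and Lasso (penalty by
10-fold CV minimum MSE), logistic regression (RS = linear predictor), LDA
(RS = posterior log-odds, which is linear; the fit is cross-checked against
`MASS::lda` posteriors), KNN (k swept over 1..50 by 10-fold CV accuracy,
ties toward smaller k, Euclidean distance on standardized features,
probabilities = neighbor vote fractions), and SVM (kernel chosen over the
seven kernlab kernels by validation accuracy on a 65/17.5/17.5 three-way
stratified split; cost fixed at 1, RBF-type kernel widths by the median
heuristic; probabilities by Platt calibration of decision values). The
three-way SVM proportions are a package default — the source procedure
specifies the three-way structure but not its proportions.

A family is a **success** when its score separates the groups on both the
train and test split (permutation p < 0.05 on each). Among successes the
best scorer maximizes test AUC, with ties broken by the smaller train/test
AUC gap, then the larger train AUC — the published ranking rationale.
Operating cutoffs are always computed by Youden index on the training
scores and reapplied unchanged to test data; ties in J break toward the
higher-specificity cutoff, matching the stated preference for minimizing
misdiagnosis of non-dominant glands.

## Clinical integration

Clinical covariates are imputed by distribution: continuous variables
passing Shapiro-Wilk at α = 0.05 get the mean, failing it the median;
categorical variables the mode. Screening uses chi-square (Fisher when an
expected cell is below 5) for categorical variables and t versus
Mann-Whitney for continuous ones, again branched on per-group normality.
Flagged variables plus RS enter a staged logistic selection: univariate
fits drop candidates with p ≥ 0.05; the multivariate fit is then pruned
and refitted until every term has p < 0.05 or nothing remains. This
"iterate until stable" loop generalizes the published two-round trace
(one covariate lost univariately, two lost multivariately, a clean second
round). RS is always entered as a candidate; the pipeline warns and forces
it if it is ever pruned, since the fused model is defined around it.
Perfect separation — a real risk in small synthetic cohorts — triggers a
weak-ridge IRLS fallback (penalty 1e-4 on non-intercept terms) with a
warning rather than a failure.

The fused model's fitted probability is the Clinical-Radiomic Score. Its
default cutoff is the derivation Youden point; a fixed operating cutoff
(e.g. a specificity-oriented 0.440) can be supplied instead and flows into
every report. The nomogram export linearizes the model into point axes:
variable v at value x contributes `100 · β_v (x − ref_v) / M` points with
`M = max_w |β_w| · range_w`. The reference `ref_v` is the derivation-range
endpoint that minimizes the contribution (minimum for positive, maximum
for negative coefficients). Using the signed reference rather than the
variable minimum everywhere keeps all axes non-negative *and* makes total
points a strictly monotone function of the linear predictor, so the
total-points → probability table inverts the logistic link exactly; with
minima as references for negative coefficients the total-points mapping
would not be well defined.

## Evaluation statistics

All primitives are implemented from their definitions and pinned to
independent oracles in the tests: DeLong AUC/variance via structural
components with midranks (equals exhaustive pair counting; variance and
paired comparison match pROC to machine precision), unpaired DeLong for the
train-vs-test gate (disjoint samples) and paired DeLong for same-cohort
comparisons, Youden by exhaustive midpoint sweep, Monte-Carlo permutation
tests with add-one correction, confusion metrics with undefined-ratio
handling (`NA`, never 0), Hosmer-Lemeshow on equal-frequency risk deciles
(ties kept together, g = 10 default, chi-square with g − 2 df), calibration
bins, and decision-curve net benefit `NB(t) = TP/n − FP/n · t/(1−t)` over a
0.01–0.99 grid with treat-all/treat-none references. AUC confidence
intervals are normal-approximation on the DeLong SE. The standard F1
formula is used; note that the source's printed F1 values are not
consistent with its own sensitivities and precisions, so no attempt is made
to reproduce them.

## The synthetic-data generator

The generator exists so every stage is testable without patient data, and
its defaults are the study conditions: a derivation cohort of 120 (60/60)
and a temporal validation cohort of 50 (25/25); 107 features in the
standard seven-class breakdown (14/18/24/16/16/14/5); five informative
features planted at standardized effect d = 1.2; three near-duplicate pairs
at latent r = 0.95; two constant columns; clinical effects of |d| = 0.8 in
the seven discriminative variables (K+(Min.), Echo-IVSd, RF-UA,
24h AE(Max.), Renin, Aldo-max, BL-TG), signed so the lesional group has
lower aldosterone indices and higher triglycerides and uric acid.

Features are drawn from a latent multivariate normal with exchangeable
within-class correlation (0.3), effects planted as latent location shifts,
then the GLSZM and GLDM classes pass through a monotone exponential
transform to create skewed margins — so the normality-adaptive branches
(Pearson/Spearman, t/Mann-Whitney, mean/median imputation) are genuinely
exercised. Monotone transforms leave rank statistics untouched, so a
feature with planted effect d has population AUC Φ(d/√2) in every class;
the tests verify this against the closed form. Rater replicates add
independent per-feature Gaussian noise to both copies, giving expected ICC
σ²_b/(σ²_b + σ²_e). Clinical marginals are synthetic conventions (normal
for anthropometrics and routine chemistry, log-normal for
aldosterone/renin/triglycerides/urinary indices and durations, 0/1
gender); the source reports no distributions, so these are documented
choices, not estimates. The phantom generator produces a textured
ellipsoid in a noisy background with voxel spacing metadata (default
1 × 1 × 5 mm, a thick-slice axial geometry).

What the generator does **not** emulate: real CT anatomy and scanner
physics, the heavy inter-feature dependence structure of true radiomic
sets (hundreds of algebraically related descriptors), non-Gaussian tails,
or cohort drift between derivation and temporal validation. Passing
recovery tests therefore demonstrates that the procedure does what it
claims under its own assumptions — not that the published patient-level
AUCs are reproducible, which they are not without the undeposited data.

## The extraction front-end

No radiomics engine is available to R in this environment, so the package
carries its own compact extractor for the standard 107-feature inventory:
shape descriptors from the mask and spacing, first-order statistics, and
the five texture-matrix families on intensities discretized at a fixed bin
width (default 25, the common engine convention). Texture matrices use
26-connectivity (13 unique directions; GLCM/GLRLM features averaged over
directions; GLSZM zones by 26-connected components; GLDM with dependence
tolerance 0). Shape surface measures are voxel-based: surface area from
exposed voxel faces and mesh volume as interior voxels plus half the
boundary layer. These staircase approximations differ numerically from a
marching-cubes engine — sphericity is biased low, for example — but they
are deterministic, internally consistent, and sufficient for a pipeline
whose contract is the named 107-feature table. The extractor is exercised
on phantoms whose mask volume is checked against the analytic ellipsoid
volume.

## Numerical choices and degenerate inputs

- Sample SD (n−1) throughout; Shapiro-Wilk at α = 0.05 wherever a
  normality branch is needed.
- Permutation p-values are floored at 1/(B+1); B defaults to 9999 for
  one-off tests, and is a config knob in the iteration loop where the
  procedural results (counts, acceptance decisions at strong signal) are
  insensitive to it.
- Candidates whose screen leaves fewer than two features, whose Lasso
  selects nothing, or whose RS is constant are auto-rejected with a logged
  reason; stage errors are caught per candidate and never abort the loop.
- Constant score vectors give a degenerate Youden point (J = 0, flagged);
  zero-denominator rates are `NA`; an all-constant feature table is an
  error.
- `run_pipeline()` aborts with the stage name if selection returns fewer
  than two robust features or no model family passes the success gate.

## Problem sizes in the tests

The test suite runs the full published scale where the claim *is* the
scale (1000 × 7 = 7000 candidates on a 20-feature table) and scaled-down
versions elsewhere: recovery uses 200 iterations with the count threshold
scaled pro rata (>20/1400), null calibration uses 30 iterations, and the
Monte-Carlo oracle suites use a few hundred replicates each. The
clinical-fusion experiment runs at moderate radiomic signal (planted
d = 0.6, population RS AUC ≈ 0.74 under the generator's correlation
structure) because that is the AUC regime the method targets; at the
generator's strong default (d = 1.2) both the RS and the fused model
saturate at validation AUC 1.0 and the comparison is uninformative.
Scaling choices live in the tests, not in the package defaults, which
remain the full-scale study conditions.

## Known limitations

- The extractor's voxel-based shape measures and un-resampled geometry are
  simplifications relative to mesh-based engines; absolute feature values
  are not interchangeable with those engines' outputs.
- The Spearman correlation p-value uses the t approximation, slightly
  anticonservative below n ≈ 10.
- KNN probability estimates are vote fractions, coarse for small k; with
  even k, neighbor-vote ties are resolved by the underlying `class::knn`
  machinery under a fixed seed.
- The staged logistic selection assumes numerically encoded covariates
  (gender 0/1, continuous untransformed); factor handling beyond binary
  categorical variables is out of scope.
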