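---
title: "Methods: screening and panel discovery in two-group metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and panel discovery in two-group metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metpanel` implements the statistical workflow of a small case-control
metabolomics study: roughly 30 case and 29 control participants, a targeted
quantitative panel of ~20 folate one-carbon metabolism / transsulfuration
(FOCM/TS) measurements plus a few nutritional markers and two binary MTHFR
genotype indicators, and several hundred semi-quantitative metabolites from
broad profiling. This vignette records the model choices, the tunable
parameters, and the places where the design was genuinely open.

## Data model and censoring

A `cohort_matrix` holds a participants-by-features abundance matrix, a
two-level group factor (the first level is the positive/case class), feature
metadata (assay panel, continuous/binary kind, standard-confirmation flag)
and a logical below-detection-limit mask. Censored cells carry `NA` until
`impute_below_detection()` replaces each one with the feature's minimum
*uncensored* value divided by \(\sqrt{2}\) — the conventional fill-in for
left-censored intensities, which places imputed values strictly below every
observed one and keeps the operation idempotent. `NA` cells that are not in
the censored mask mean "never measured"; such features are excluded from
classification subsets (they would make cross-validation folds ill-defined)
but stay in the univariate screen with pairwise-complete samples.

## Univariate screen

For each continuous feature the two-sample test is chosen adaptively:

1. Anderson-Darling normality on each group (estimated mean/variance case,
   Stephens' small-sample correction). This test is implemented in the
   package because the pre-installed stack does not provide it; its null
   calibration is checked in the test suite.
2. If both samples look normal, a two-sided F-test chooses between the
   pooled Student *t* (`t_eq`) and the Welch *t* (`t_neq`).
3. Otherwise a two-sample Kolmogorov-Smirnov test on **median-centered**
   samples decides between the Mann-Whitney U test (`mw`) and a Welch *t*
   applied without the normality premise (`t_neq_dagger`).

Median-centering in step 3 is a deliberate operationalization of "same
shape": the raw two-sample KS test compares full distributions, so any
location effect — the very thing being screened for — would reject and make
the Mann-Whitney branch unreachable. Centering removes location and leaves
shape. All pre-tests run at the same \(\alpha = 0.05\) as the main test; the
KS step uses the asymptotic p-value (ties after centering make the exact
computation ill-defined, and the resampling score below re-runs the tree
thousands of times). The Mann-Whitney p-value is the tie-corrected normal
approximation without continuity correction; at very small n (4 vs 4) it
tracks the exact permutation p only loosely (deviations up to ~0.1 are
possible), which the tests document honestly.

Binary features (genotypes, categorical history variables) use the Pearson
chi-square test of independence without continuity correction.

### Leave-k-out robustness score

The study's "FDR" is not a Benjamini-Hochberg rate but a jackknife
stability score: every subset of 1 and 2 participants (1770 deletions at
n = 59; depth 3 is available by argument) is removed from the pooled
cohort, the test scenario is re-selected, the p-value recomputed, and the
score is the fraction of resampled p-values **above** \(\alpha\). The
source text describes the fraction *significant*, but its result tables
print 0.00 for strongly significant features and 1.00 for null ones, which
forces this orientation; the package follows the tables. A feature is
flagged only when \(p \le 0.05\) *and* the score \(\le 0.1\) — this joint
rule is the only multiplicity control anywhere in the pipeline, by design.

Deletion subsets are drawn from the pooled cohort (either group); a
deletion that would push a group below four observations is skipped with a
warning rather than evaluated on a meaningless sample.

ROC AUC is computed through the Mann-Whitney identity \(U/(n_1 n_2)\) with
half credit for ties and reported as \(\max(A, 1-A)\), so 0.5 always means
"uninformative" regardless of effect direction.

## Classification

### Fisher discriminant analysis

`fda_fit()` maximizes
\(J = (\bar t_1 - \bar t_2)^2 / (s_1^2 + s_2^2)\)
over unit directions \(p\), where \(t = X p\) and \(s_g^2\) are unbiased
projected group variances. The closed-form maximizer is
\((S_1 + S_2)^{-1}(\bar x_1 - \bar x_2)\) with \(S_g\) the unbiased group
covariance matrices — the *sum* (not the pooled weighted average) is used
because it is exactly the denominator structure of \(J\). A ridge of
\(10^{-6} \times \mathrm{tr}(W)\) is added only when the solve fails
numerically. The sign convention puts the case group on the lower-score
side.

Features are z-scored with pooled training statistics before both FDA and
logistic fitting. The source study does not state whether it standardized;
with raw abundances spanning four orders of magnitude an unstandardized FDA
would be dominated by the large-scale features, so standardization is this
package's documented choice (and a known deviation risk when comparing to
the original numbers). Cross-validation folds recompute the constants from
the training fold only.

### Decision boundary

The boundary on the score axis is placed by a Gaussian-kernel density
estimate (Silverman bandwidth, 2048-point grid extending four bandwidths
beyond the data range) of the **case** scores: the threshold is the score
at which the cumulative KDE mass reaches a one-sided confidence level, and
a score \(\le\) boundary is labelled case. The confidence level is chosen
by grid search over \(0.50, 0.51, \ldots, 0.99\) to minimize
\(|\text{type I} - \text{type II}|\) on the training data, ties broken
toward smaller total error and then the smaller level. Kernel and bandwidth
are unstated in the source; Gaussian/Silverman are the field defaults.

### Logistic regression

Mixed continuous/binary panels use maximum-likelihood logistic regression.
Under (quasi-)separation the MLE diverges; the fit falls back to a ridge
penalty of \(10^{-4}\) on the slope norm (intercept unpenalized) and flags
the model, trading a deterministic, finite answer for a silently divergent
one. A predicted probability of exactly 0.5 is labelled control — an
arbitrary but stated and tested tie rule.

## Cross-validated panel search

`loocv_evaluate()` refits everything — standardization, direction, KDE
boundary, balanced confidence — inside each leave-one-out fold, the
leakage-safe reading of the protocol (the source does not say whether the
confidence level was re-balanced per fold). `search_panels()` ranks
combinations by total misclassification, then \(|\text{typeI} -
\text{typeII}|\), then feature names. Exhaustive enumeration is guarded by
an explicit budget; the full protocol (all combinations of 2-10 of 76
variables, ~\(10^{12}\) evaluations) is not desk-feasible, so beam search
(default width 50, panels grown one feature per round) is the documented
scaled-down surrogate for the largest subset. Beam search assumes partial
panels carry signal; a purely interaction-driven panel (features useless
alone, informative jointly) defeats it, and the test suite contains exactly
such a construction as a negative control of this limitation.

Subset assembly follows the study layout: (i) the targeted FOCM/TS panel,
(ii) plus nutritional markers, (iii) plus the binary genotypes, (iv) plus
the 50 top-AUC broad metabolites (ties at the cutoff broken by name). The
printed size of subset iv (76 rather than 27 + 50) implies one name is
shared between blocks; since synthetic cohorts have no such collision,
`build_subset()` deduplicates by name and asserts a caller-supplied
expected size instead of hard-coding 76.

## Correlation decomposition

Around the best panel's features ("cores"), Pearson correlations with all
candidate features are computed on the pooled 59 samples; members are kept
at unadjusted two-sided \(p \le 0.05\) (the source reports raw correlation
p-values, and its smallest reported member correlations are |r| ≈ 0.25 at
p = 0.05, consistent with this pooled-n threshold). Features significant in
the screen but in no member list are "orphans"; their pairwise correlation
table tests for an additional group. No multiplicity correction and no
partial correlations, matching the star-shaped core-member structure of the
original analysis.

## Synthetic cohorts

`generate_cohort()` states the world the pipeline assumes rather than
tuning toward any result:

* 30 cases / 29 controls;
* ~600 broad metabolites, log-normal (latent Gaussian on the log scale)
  with baselines uniform on \(\log(10^4)\)–\(\log(10^8)\) and a single
  abundance-scale coefficient of variation, default 0.5 — log-normality is
  a modeling decision (the source gives no distributional description),
  chosen because semi-quantitative intensities are right-skewed across four
  decades; 0.5 is a typical broad-profiling biological CV;
* five latent clusters of 8-15 members; member loadings are drawn so
  pairwise within-cluster correlations land in 0.4-0.9;
* case/control mean ratios of affected clusters drawn from 0.63-0.87 (the
  depressed-cluster ratio range of the study), applied multiplicatively on
  the mean, matching how ratios are reported;
* five affected-but-independent orphan features;
* left-censoring at the 5% quantile of each feature's null distribution;
* 20 null targeted features at CV 0.12 (quantitative assays are much
  tighter than broad profiling) and two Bernoulli genotype columns with
  carrier frequencies 0.31/0.33, independent of the metabolite structure
  (the study found the genotypes non-significant).

What a green test on synthetic data establishes: the machinery recovers
known effects, keeps its type-I rate, and does not leak across folds. What
it does not establish: batch/drift structure, inter-assay unit effects,
dietary covariate structure, or the study's actual numbers — the raw data
workbook has no public accession, so the real-data acceptance figures
cannot be recomputed here.

## Numerical notes and degenerate inputs

* Constant samples: the two-sample p is 1 and AUC 0.5; constant features
  are dropped from classifiers with a warning.
* Zero pooled variance with equal means gives p = 1; with unequal means,
  p = 0.
* Degenerate (all-equal) score vectors collapse the KDE boundary to the
  common value.
* All ranking ties are broken deterministically (lexicographic feature
  names), so every output is reproducible byte-for-byte from the seed.
* The generator keeps all seeds below \(2^{31}\); a single seed fixes every
  generated byte.

## Known limitations

* Exhaustive search over the largest subset is approximated by beam search
  (see above); exhaustive/beam agreement is verified only at small scale.
* The resampling robustness score is \(O(n^2)\) test evaluations per
  feature and dominates screen runtime; depth 3 multiplies it by another
  ~\(n/3\).
* No covariate adjustment, paired designs, nested cross-validation, or
  bootstrap confidence intervals on error rates.
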