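---
title: "Methods: replicated metabolomics biomarker discovery with network and genetic risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicated metabolomics biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabrisk)
```

# The analysis this package implements

`metabrisk` implements the discovery pattern of pre-diagnostic case-control
serum metabolomics: blood drawn from healthy cohort participants, cases
defined by later diagnosis, controls matched 1:1, and the question of
whether the metabolome already separates the groups at baseline. The
pipeline runs two independent sets in parallel and only trusts what
replicates in both; it then characterises the selected metabolites as a
conditional-dependence network, and asks whether adding a genetic risk
score improves a metabolite-based prediction model.

Every stage is exercised end-to-end on synthetic data with planted ground
truth, because the kind of study this emulates rarely deposits raw data.
The generator is first-class, tested code: recovery of the planted
biomarkers, network edges and SNP effects is part of the test suite.

# Stages, models and assumptions

## Matching and baseline comparisons

Controls are matched to cases 1:1 by greedy nearest-neighbour matching on
the propensity scale (logistic regression of case status on age and
blood-collection time), hardest-to-match cases first, without replacement.
No caliper is applied by default — the matching family and caliper are
genuinely open design choices here, so greedy/no-caliper is the documented
default and a `caliper` argument is exposed. Baseline tables use a
Shapiro-Wilk screen at α = 0.05 per group to choose between a t-test, a
t-test on logs, and a Mann-Whitney U-test (exact for small groups without
ties, normal approximation with tie correction otherwise); nominal
variables get a chi-square test; covariate-adjusted p-values come from a
linear model of the (possibly log) response on group plus the covariate.

## Preprocessing

Features detected in fewer than 80% of QC injections are discarded
(`qc_filter`, threshold configurable). Assay precision is reported as
%RSD = 100·sd/mean over repeated QC injections, with ≤ 15% the
conventional acceptance level. Missing abundances are imputed as half the
per-feature observed minimum — a common metabolomics convention; the
upstream protocol does not prescribe one. Abundances are natural-log
transformed and then Pareto scaled (centre, divide by √sd). The order
impute → log → Pareto is the only numerically sensible one; scaled columns
have mean 0 and variance equal to the pre-scaling SD of the logs, which
damps high-abundance dominance without inflating noise the way full
unit-variance scaling does. Transform parameters are fit per set, since
the sets are analysed separately throughout.

## OPLS-DA, Q², permutation, VIP

The discrimination model is OPLS-DA with one predictive component (the
standard choice for a two-class response) and `n_orth` orthogonal
components removed first. With a univariate ±1-coded centred response the
PLS weight vector is available in closed form per component, so fitting is
fully deterministic — no RNG, no convergence tolerance to tune. The number
of orthogonal components is chosen by maximising cross-validated Q² up to
a cap of 5 (`select_n_orth`); the upstream software's choice is not
documented, so the cap and criterion are explicit here.

Q² uses stratified k-fold cross-validation (default 7 folds, the field's
common default; fold membership is assigned round-robin within class, so
it is deterministic) with the model refitted from scratch per fold:
Q² = 1 − PRESS/SS. Permutation significance permutes labels uniformly and
recomputes the statistic (Q² by default); the result is reported both in
the conventional raw form `k/n` — a fully separated model prints "0/100",
i.e. p < 0.01 — and as the unbiased `(k+1)/(n+1)`, which is what
downstream inference should use.

VIP is computed from the predictive components only,
`VIP_j = sqrt(p · Σ_a SSY_a w_ja²/Σ_a SSY_a)`, so squared VIPs average 1
exactly; VIP > 1 marks above-average contribution. Replicated selection
takes the intersection of VIP > 1 across the two sets. Fold changes are
case/control ratios of per-sample relative abundance on the raw scale.

Super-class enrichment of the selection is one-sided hypergeometric
over-representation with BH-FDR across classes. Quantitative set
enrichment (MSEA) would be an alternative reading of "metabolite set
analysis"; over-representation on the selected list is the interpretation
implemented, with the background fixed to all identified metabolites
rather than all detected features.

## Gaussian graphical model

Partial correlations come from the inverse of the correlation matrix,
optionally shrunk toward the diagonal with an analytic (Ledoit-Wolf style)
intensity; shrinkage engages automatically when p/n > 0.2, since a
23-node network on ~130 samples is estimable unshrunk but subgroup
analyses are not. Edge significance uses Fisher's z with variance
1/(n − (p−2) − 3), accounting for the conditioning set, and BH-FDR across
all pairs; the significant-edge graph (q < 0.05) feeds unweighted,
non-normalised betweenness centrality. The "centrality cutoff of 0.5" is
interpreted as a *display* threshold on node centrality, not an edge
filter — the wording is ambiguous, so the threshold only flags nodes
(`displayed`), never removes them.

Per-metabolite effect "z-scores" are not defined upstream; here they are
Welch t statistics of log abundance mapped through their p-value to a
standard-normal quantile, signed by direction, with BH-FDR across nodes.
This gives a common normal-scale effect measure under unequal variances; a
plain standardized mean difference is the obvious alternative and would
order nodes nearly identically.

## Genetics

SNP QC applies, in a documented order (marker missingness > 5% → sample
missingness > 5% → MAF < 0.05 → exact Hardy-Weinberg p < 1e-6), with
statistics recomputed after each step; the order matters in edge cases,
which is why it is fixed and logged. The HWE test is the exact test
conditional on allele counts (the PLINK convention), implemented in-house
and checked against a Monte Carlo allele-shuffling oracle. Per-SNP
association is additive logistic regression adjusted for age, Wald-tested;
separation is flagged rather than silently reported.

GRS weights are the log-odds estimates of SNPs passing the selection
threshold p < 5e-5 (the numeric threshold governs; "Bonferroni" alongside
that fixed threshold is contradictory). "Weight" is not defined upstream;
the GWAS beta is the documented assumption. Each SNP is oriented to its
risk allele (negative estimates flip the count to `2 − count`), missing
genotypes contribute the mean-imputed `2 × risk-allele frequency`, and
`GRS_i = Σ_j count_ij × weight_j`. GRS groups are a median split with ties
to the low side — the split point is likewise an undocumented upstream
choice, recorded here as a default rather than an inference.

A deliberate design point: the pipeline estimates GRS weights on a
simulated *reference cohort* (default n = 500) drawn from the same ground
truth, then scores the study subjects. Selecting dozens of SNPs at
p < 5e-5 from only ~130 subjects is not a procedure that can be emulated
honestly at a few hundred simulated SNPs: with a realistic dense
architecture no SNP reaches that threshold, and apparent hits at
genome-wide scale are dominated by winner's curse. The reference-cohort
design keeps the selection rule intact while giving it real power, at the
cost of assuming external weights — the trade-off is stated rather than
hidden. Consistent with this, the generator's default genetic architecture
is sparse and strong (10 causal SNPs of 500 at log-OR 0.8) rather than the
nominal "92 risk SNPs" of the emulated design.

## Prediction

Markers for the prediction models are the network-significant metabolites
ranked by mean VIP (top 5 by default). Three logistic models are fitted:
markers, markers without the top marker, and markers + GRS. AUCs are
apparent (in-sample), reproducing the upstream procedure; apparent AUC is
optimistic, which is why the ROC machinery is exposed separately so a
cross-validated score vector can be supplied instead. The trapezoid AUC
equals Mann-Whitney concordance exactly (tested to 1e-12). Confidence
intervals use the DeLong placement-value variance with a normal
approximation, falling back to a seeded stratified bootstrap (2000
resamples, percentile) when the variance degenerates, e.g. at AUC = 1.

# The synthetic generator: what it emulates, and what it does not

Defaults reproduce the emulated study conditions: sets of 35+35 and 31+31
male subjects aged 35–69, 2610 detected features with 250 identified
metabolites, a 23-metabolite network block, 13 QC injections (one per ten
study samples) and 7 intra-assay replicates with ~10% analytical RSD.
Values the design does not pin down were chosen once, on field grounds:

* **Abundances are log-normal** (Gaussian on the log scale, log-SD 0.5),
  so the log transform recovers exactly the Gaussian assumption of the
  graphical model.
* **Effect size 0.75 SD** on 17 of the 23 network metabolites: with
  log-SD 0.5 this corresponds to fold changes near 1.45, the scale
  reported for replicated serum biomarkers in this setting, and 17 matches
  the reported count of z-score-significant network metabolites.
* **Planted partial correlations of magnitude 0.4** at edge density 0.1,
  the scale of the reported metabolite-pair correlations. The precision
  matrix plants edges at ±strength with unit diagonal; edges touching a
  node whose absolute off-diagonal row sum would reach 1 are shrunk
  per-edge (never globally), so low-degree nodes keep the full planted
  strength and positive definiteness is guaranteed and asserted.
* **Disease is genetic**: case status comes from a logistic model on the
  causal SNP allele counts, then subjects are sampled stratified to the
  exact group sizes, so GRS recovery is testable against the generative
  linear predictor. Allele frequencies are uniform on (0.1, 0.4); sporadic
  genotype missingness is < 2% per SNP.
* One global seed is expanded into fixed per-stage substreams (truth,
  annotation, QC, each set's subjects, genotype missingness), so identical
  configurations are byte-identical and stages are individually
  reproducible.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: raw spectra, retention behaviour, adducts and
isotopes (feature tables are the entry point by design); correlated
background chemistry — background features are independent, so the
leading principal components explain far less variance than in real serum
data, where shared lipid/amino-acid structure dominates; batch and drift
effects; annotation error; and any super-class signal (classes are
assigned uniformly, so enrichment behaves as a calibrated null rather than
reproducing particular enriched classes).

# Numerical choices and degenerate inputs

Constant columns are rejected before latent-variable fitting (they would
be division-by-zero under Pareto scaling upstream). Zero-variance baseline
variables are skipped with a reason, zero-mean QC features flagged as
RSD-not-computed, monomorphic SNPs get HWE p = 1, isolated network nodes
betweenness 0, all-equal GRS vectors a warning and an empty high group
(ties go low). Cross-validation folds are capped at the smaller class
size; a permutation p-value can never be 0 in inference form. Singular
covariance under shrinkage = 0 is an error that names the remedy.

# Problem sizes used by the tests and the acceptance script

The acceptance script runs the full default-scale study (2610 features,
132 subjects, 500 SNPs, 100 permutations per set). Simulation-heavy tests
use deliberately small instances chosen to keep the whole suite fast while
leaving the tested properties identifiable: null-calibration sweeps use
24×15 matrices with 49 permutations over 200 replicates; recovery sweeps
use 20 replicates of a 80-feature/40-identified study; GGM edge recovery
uses n = 500 at p = 23; GWAS recovery uses 500 case-control subjects.
These sizes are the package's own test-design choices.

# Known limitations

Apparent AUC overstates transferable performance; the cross-validated
alternative is available but off by default to mirror the emulated
procedure. The GGM at n ≈ 130, p ≈ 25 has limited power for |pcor| ≲ 0.3
after FDR control, so sparse significant-edge graphs (sometimes empty, with
betweenness 0) are the honest outcome at this scale — centrality values
should be read comparatively, not as stable network statistics. The
enrichment stage implements over-representation, not quantitative MSEA.
The genetics module does no LD pruning, imputation or population-structure
correction, and the reference-cohort weight estimation sidesteps — rather
than solves — the small-n in-sample SNP selection problem discussed above.
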