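---
title: "Methods: intra-pair EWAS of lung function in MZ twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-pair EWAS of lung function in MZ twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinewas)
```

## The model

Monozygotic co-twins share their genome and much of their rearing
environment. Within a pair, order the twins by a lung-function z-score:
the "superior" twin has the higher z, and the intra-pair difference
Δz = z_sup − z_inf ≥ 0 measures quantitative discordance. Differencing
every variable the same way (superior minus inferior) removes all
pair-constant confounding — genetic background, cohort, shared exposures —
so that for each CpG probe the model

ΔM = β₀ + β₁·t(Δz) + β₂·sex + β₃·age + β₄·ΔBMI + β₅·Δpack-years +
β₆·Δsmoking + Σ_c β_c·Δf_c + ε

estimates β₁, the change in intra-pair M-value difference per unit of
(possibly log-transformed) lung-function discordance. Six analyses run:
the three follow-up metrics (cross-sectional) and their changes over the
follow-up period (longitudinal). The log transform t(·) = ln is applied to
Δz of zFEV1, zFVC and their changes, whose distributions are extremely
right-skewed; the two FEV1/FVC metrics enter untransformed.

Because sex and age are identical within an MZ pair, their differences
are identically zero; they can only enter at pair level, which also
requires the intercept. That is the only reading under which adjusting for
sex and age is estimable in a pure difference design, and it is what this
package does.

## Z-score standardization

Reference equations of the LMS family describe a healthy non-smoking
population by three curves per sex: skewness L, median M and coefficient
of variation S, tabulated on an age grid, with M scaled by
(height/h_ref)^γ. The z-score is ((y/M)^L − 1)/(L·S), computed via
`expm1` so it degrades gracefully to ln(y/M)/S as L → 0, and inverts in
closed form. Design choices:

* **Linear interpolation in age, no extrapolation.** Published tables are
  dense; requesting an age off the grid is a hard error rather than a
  silent extrapolation.
* **Follow-up height at both visits.** Height is measured objectively
  only at follow-up and is effectively constant at these ages.
* **The ratio is its own metric.** zFEV1/FVC is standardized from the
  measured ratio with its own L/M/S rows, never derived from the two
  volume z-scores.
* **Single ethnicity stratum.** The target cohort is single-ethnicity;
  the coefficient-table format would extend naturally.

The shipped coefficient curves are synthetic stand-ins with the right
structure (M decaying in age, S ≈ 0.05–0.13, height exponent ≈ 2 for
volumes and 0 for the ratio); a real coefficient table in the same TSV
format can be dropped in.

## Methylation processing

Beta values (proportion methylated) are regressed on the M scale,
M = log2(β/(1−β)). "Logit-transformed" is read as the base-2 logit — the
universal M-value convention for this array family. Betas are clipped to
[1e−6, 1−1e−6] first: exact 0/1 arise from rounding, not biology, and the
clip keeps M finite without measurably moving any interior value.

QC composes per-measurement rules — bead count < 3, detection p > 0.01,
zero signal (operationalized as missing β, or β = 0 with bead count 0,
since raw intensities are out of scope) — into a per-probe rule: removal
when the failed fraction strictly exceeds 5% of samples, plus removal of
blacklisted (cross-reactive) probes. The order of composition
(measurement rules first, then the 5% rule, blacklist attribution taking
precedence) is a documented choice; the upstream pipelines do not pin it
down. Functional normalization needs raw IDATs and is deliberately not
implemented; `normalize_betas()` is an identity hook marking the seam.

Cell composition uses the five-type differential count (monocytes,
lymphocytes, basophils, neutrophils, eosinophils). Missing samples are
imputed from the methylome by least squares of the sample's β profile on
the reference panel's columns, constrained to the probability simplex.
With five cell types the constrained optimum is found *exactly* by
enumerating the 31 support subsets and solving each equality-constrained
KKT system — no iterative solver, no tolerance. In the regression design
one fraction difference (neutrophils, the most abundant type) is dropped:
the five differences sum to zero and would otherwise be collinear.

## EWAS mechanics

All probes share one design matrix, so one QR decomposition serves the
whole scan; estimates, standard errors and two-sided t p-values (df =
pairs − rank) are identical to probe-wise OLS to numerical precision,
which the test suite verifies against an independent normal-equations
oracle. Degenerate zero-residual fits return a p = 0 sentinel with a
warning. Rank deficiency is an error naming the collinear columns rather
than a silent drop.

Multiplicity control is Benjamini–Hochberg step-up, implemented directly
(sort, adj_i = min_{j≥i} p_(j)·n/j, cap at 1). `bh_adjust()` accepts an
`n_tests` larger than the supplied vector, which lets the adjusted value
of a scan's top probes be recomputed from the few published p-values of a
453,014-probe analysis — the acceptance suite checks the printed 0.03 this
way. Thresholds are strict: p < 1e−6 "significant", p < 1e−5 "tabled";
the corresponding FDR significance level is 0.05. Genomic inflation λ is
the median observed 1-df chi-square over its theoretical median, purely
diagnostic.

The sign convention runs through the whole chain: ΔM is superior minus
inferior, so a negative β₁ means the inferior twin is relatively
hyper-methylated where discordance is large — labelled "Hyper" (and
"Hypo" for positive β₁).

Open questions resolved as documented decisions: an intercept is included
(required by pair-level covariates); smoking status is coded ordinally
never = 0 / non-current = 1 / current = 2 and differenced; natural log
(not log10) for the predictor transform; ties (Δz = 0) are excluded from
the affected metric with a logged reason — under a continuous z they have
probability zero.

## Enrichment

Hit probes (p < 1e−5) map to unique proximal genes, dropping intergenic
probes. Each gene set is tested by the upper-tail hypergeometric
P(X ≥ O) against the array-restricted universe, with C (category size in
universe), O (overlap), E = kC/N, R = O/E and O = 0 ⇒ rawP = 1. BH runs
within each database separately — published per-database rows back-solve
to mutually inconsistent universe sizes, so each database is its own
multiplicity family with its own effective universe. Gene matching is
exact, case-sensitive symbol equality; alias resolution is out of scope.
The default minimum in-universe category size is 2, matching the smallest
overlap ever reported in this kind of table.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the stated world of the target cohort:
86 male and 83 female MZ pairs, follow-up ages 56–79 (median ≈ 66),
follow-up gap uniform in (9.6, 13.4) years, per-sex height/weight centres
(174/161.9 cm, 81.9/67.7 kg), zero-inflated gamma pack-years calibrated so
the marginal means land near 20.8 (male) and 7.3 (female) with
discordant-pair mean differences of ~14 and ~8, and the "quit < 2 years ⇒
current smoker" rule applied to generated quit dates. Lung-function
z-scores have a pair-shared component plus individual deviations and are
inverted through the LMS table to measured volumes, so standardizing the
generated cohort recovers the generated z exactly.

Methylomes are cell-type mixtures of a bimodal reference panel plus an
additive pair-shared random intercept on the M scale: with total residual
SD σ and shared fraction ρ (`pair_correlation`), the within-pair
correlation is controlled analytically. The within-pair methylation
correlation of the real cohort is unknown — ρ is a free parameter
(default 0.5), not an emulation claim. Planted effects are injected on
the M scale after mixture construction, ± slope·t(Δz)/2 on the
superior/inferior twin, so the pair difference carries exactly the
coefficient the EWAS estimates; parameter-recovery tests therefore target
the estimator itself, not a proxy.

Not emulated: raw IDAT intensities, control probes, chip/batch effects,
dye bias, and any real probe coordinates or gene symbols (manifests are
synthetic, labelled as such). A green test establishes that the pipeline's
mathematics is correct under its own assumptions — Gaussian M-scale noise,
linear cell-composition effects, no batch structure — not that any
particular biological finding replicates.

## Numerical choices and degenerate inputs

* Beta clip 1e−6; z-score L→0 switch at |L| < 1e−12 via `expm1`/`log1p`.
* Zero-residual regression: p = 0 sentinel + warning, never NaN.
* BH input domain (0, 1] enforced; p-values floored at the smallest
  positive double before adjustment of sentinel zeros.
* Deconvolution feasibility tolerance 1e−10 on nonnegativity; candidate
  solutions renormalized onto the simplex.
* Ties in pair ordering are flagged and excluded, keeping the stored twin
  order for determinism; exclusions are logged and accounted (analyzed +
  excluded = input pairs, asserted in tests).
* All generation flows from integer seeds; derived stage seeds stay below
  2^31.

## Known limitations

* The LMS curves, manifests, reference panels and gene sets are synthetic;
  the package reproduces the *procedure*, not any cohort's coefficients.
* No mixed models, robust/clustered errors, surrogate variables, or
  DMR-level analysis — single-probe OLS only, as specified.
* Imputation of cell counts is the constrained-projection stand-in for
  the published reference-based pipeline, not a reimplementation of it.
* Smoking-status coding and intercept inclusion are documented guesses at
  unstated details of the original analysis; both are isolated behind
  single functions if a different convention is needed.
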