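---
title: "Methods: episignature discovery and classification on synthetic EPIC-like data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature discovery and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episig)
```

# Scope and model

`episig` implements the standard blood episignature workflow for a
monogenic syndrome: probe QC on an EPIC-style beta matrix, reference-based
leukocyte deconvolution, covariate-adjusted moderated differential
methylation, dual-threshold signature selection, SVM probability
classification, and genomic-context enrichment. Because patient-level
methylation data for syndromes like Koolen-de Vries are not generally
shareable, the package treats a synthetic-cohort generator with known
ground truth as a first-class component: every downstream stage is
validated against what the generator planted.

The observation model behind both the generator and the analysis is:

* a sample's baseline methylation is a convex mixture of cell-type mean
  profiles, `b = R w` with `w` on the simplex (whole blood is a cell
  mixture, and case/control differences in composition confound
  probe-level tests — hence deconvolution-derived covariates);
* disease, age and sex add small probe-specific offsets on the beta scale;
* measurement noise acts on the logit scale, which keeps observed betas in
  (0, 1) and reproduces the variance shrinkage near 0 and 1 seen on arrays.

# The generator and what it does (and does not) emulate

`simulation_config()` defaults *are* the study design the workflow
targets: 8 cases vs 21 controls aged 3–15 years, a planted signature of
100 CpGs at |Δβ| = 0.15 (the scale of reported syndrome episignatures,
comfortably above the 10% selection threshold), logit-scale noise with
SD 0.3, and planted QC failures in all six removal categories. The
six-cell-type Dirichlet concentration (Neu 18, CD4T 3.9, CD8T 2.4,
Bcell 1.8, NK 1.8, Mono 2.1) gives mean proportions matching typical
pediatric whole blood (≈60% neutrophils) with realistic inter-individual
spread (total concentration 30). Age trends default to 0.005 beta/year at
200 probes and sex offsets to 0.05 beta units at 200 probes — the order of
magnitude reported for age- and sex-associated CpGs. No published noise
model exists for these data; the logit-normal choice with SD 0.3 is a
calibration decision, selected once as realistic for array blood DNAm, not
a claim about any particular dataset.

Annotation geography is simplified but structurally faithful: CpG islands
are runs of 3–8 consecutive probes, shores are probes within 2 kb of an
island edge, shelves within the next 2 kb. The generator does **not**
emulate the real EPIC manifest, Infinium type-I/type-II chemistry
differences, batch or chip effects, or probe-specific variance structure.
Consequently, passing tests demonstrate that the *machinery* is correct
and calibrated under the stated model; they do not certify performance on
real arrays, where batch structure and manifest idiosyncrasies dominate.

Planted effects are added on the beta scale (the selection threshold is a
beta-scale Δβ) *before* logit noise; the nonlinearity therefore attenuates
group-mean differences slightly toward 0.5. Tests account for this: the
signed attenuation at |Δβ| = 0.15 is under 0.03 on average. Clipping
events (effects pushing betas outside [0, 1]) are counted in the truth
object. All draws flow from one integer seed, so identical configurations
reproduce bitwise-identical cohorts.

# Probe QC

The cascade applies, in order: (1) detection failures — detection p > 0.01
in more than 5% of samples (both knobs exposed in `qc_params()`; 0.01 is
the platform convention, and probes with any missing beta are folded into
this category because downstream modelling needs complete rows); (2) SNP
overlap with MAF > 1%; (3) cross-reactivity; (4) beta exactly 0/1 in more
than 25% of samples; (5) non-CpG probe class; (6) sex chromosomes.
Published per-category counts in this field generally do not sum to
(input − remaining), implying overlaps were resolved in some unstated way;
`episig` uses sequential first-hit accounting — each probe is counted once,
under the first category that removes it — because it makes the report
auditable: counts always sum exactly, and filtering is idempotent.

# Deconvolution

Proportions are estimated by non-negative least squares with a sum-to-one
augmentation row of weight 1000, then exact renormalization. The simplex
constraint (rather than inequality-only variants) is deliberate: the
proportions enter a design matrix, and compositional covariates must be
collinearity-controlled — one reference cell type is dropped downstream.
The default feature set is the 200 probes with the largest between-type
beta range (ties broken by probe id). Noiseless mixtures are recovered to
solver tolerance whenever the reference has full column rank; under logit
noise of SD 0.2 the mean absolute error stays below 0.05. Which reference
panel and probe count to use on real data is the caller's choice; results
are conditional on the supplied reference.

# Differential methylation and moderation

Per-probe OLS uses a single QR decomposition of the shared design
(intercept, group, age, sexM, cell proportions minus one type, in that
fixed order; constant columns are dropped with a warning and the design is
rank-checked). The empirical-Bayes prior (d₀, s₀²) is fit by method of
moments on log s²: with e = log s² − ψ(d/2) + log(d/2), the excess of
var(e) over ψ′(d/2) identifies ψ′(d₀/2) (inverted by Newton iteration),
and mean(e) then identifies s₀². When the excess is non-positive the prior
is degenerate (d₀ = ∞) and s₀² is the mean observed variance — so a set of
probes with identical variances moderates to itself; if the inversion
fails, the fit falls back to no moderation (d₀ = 0) with a warning. Total
df are capped at the pooled residual df. Zero variances are offset to
1e-5 of the median before taking logs. The implementation is checked in
the test suite against the independent Bioconductor implementation of the
same moderation (agreement ≈ 1e-9 on d₀, s₀², t and p) and against a
normal-equations OLS oracle at 1e-10.

Δβ is computed from raw group means, not from the adjusted coefficient:
it is an effect size on the methylation-fraction scale, and the published
definition for this workflow is the difference in mean DNAm between
groups. Its stated use in the fibroblast analysis is adopted globally
(the blood-analysis definition is not stated anywhere more precisely).
Signature selection applies strict dual thresholds (adjusted p < α = 0.05
and |Δβ| > δ = 0.10), sorted by adjusted p, then |Δβ| descending, then
probe id; an empty signature is a legal, serializable result.

The cross-tissue variance pre-filter keeps probes whose beta *range*
across all samples exceeds 10%. "Most variable (>10%)" could equally mean
SD; range is the default and SD is available behind a flag — this is a
documented choice, not an inference about intent.

# Classification

A linear-kernel SVM (cost 1) is trained on standardized betas at the
signature probes. Linear is the default because at p ≫ n it is as
accurate as and far more interpretable than kernels, and the underlying
caret-style wrapper used in this field leaves the kernel unreported; the
radial kernel is available via `params`. Probability calibration is a
sigmoid (Platt) fit on decision values from an internal *stratified
3-fold* cross-validation whose folds derive from the training seed — the
package deliberately does not use the SVM library's built-in probability
mode, whose internal shuffling is not reproducible from R's RNG. If a
class has fewer than 3 members the calibration falls back to training-set
decision values with a warning. Models serialize to JSON (feature order,
scaling constants, case-positive weights, sigmoid coefficients, training
metadata) at 17 significant digits, so a reloaded model scores bitwise
identically. Scores are P(case) ∈ [0, 1]; labels follow the 0.5 rule, and
an exact 0.5 — which the rule's published form does not cover — is labelled
"indeterminate".

# Enrichment

Island/shore enrichment is a one-sided hypergeometric upper tail computed
in log space (`phyper(..., log.p = TRUE)`), with foreground = probes
annotated Island/N_Shore/S_Shore; shelves and open sea are non-foreground.
One-sided is the default because the scientific claim is directional
("higher overlap than background"); a two-sided variant doubles the
smaller tail. CpG-to-gene mapping is strand-agnostic over the closed
interval [start − 10 kb, end + 10 kb], 1-based inclusive; one CpG may hit
several genes. Category enrichment tests only categories with at least one
background gene, BH-adjusts across those, and reports records with
adjusted p < 0.05 and ≥ 3 foreground gene hits — a pure post-filter that
never alters p-values. The test machinery is verified against exhaustive
enumeration on all urns of population ≤ 12 at 1e-12.

# Numerical choices and degenerate inputs

* Betas outside [0, 1] on input are an error, never silently clamped;
  missing values are allowed only before QC.
* The NNLS augmentation weight is 1e3; proportions are renormalized to the
  simplex and certified against 1000 random simplex points in tests.
* Greedy control matching (`match_controls`) selects, per case in input
  order, the unused same-sex pool member with minimal |age gap|, ties by
  pool order. The matching algorithm behind published matched-control
  panels is never specified; greedy is deterministic and auditable. The
  age-gap tolerance is a free parameter (`max_age_gap`, default `Inf`).
* Tie-breaks are explicit everywhere (probe id order in probe selection,
  pool order in matching, adjusted-p/|Δβ|/id in signature ordering) so all
  outputs are deterministic.

# Problem sizes used in the shipped analyses

The scripted analyses and the acceptance checks run at 10,000 probes ×
29 samples for discovery (with a 208-sample validation batch), 10 seeds
for recovery statistics, 3 seeds × 10,000 probes for null calibration, and
population ≤ 12 for enumeration oracles — sizes chosen so the full suite
re-runs in well under a minute while keeping Monte-Carlo error far below
the margins being tested.

# Known limitations

* No batch/chip-effect modelling or surrogate-variable adjustment.
* The generator's annotation is synthetic; island/shore *fractions* differ
  from the real manifest (~22% island/shore here vs ~37% on the array), so
  enrichment results on synthetic data exercise the machinery, not the
  biology.
* Reproducing any published signature's exact probe list or per-patient
  scores requires the original (non-deposited) patient data and manifest;
  those quantities are out of scope by design.
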