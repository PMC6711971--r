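---
title: "Models and methods for crossover/crossback RE analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for crossover/crossback RE analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbackr)
```

## The study design and its estimand

A two-arm crossover/crossback trial samples every subject at three visits
(baseline, crossover, crossback). In the B₁HB₂ arm the exposure sequence
is background → high-DBP → background; in H₁BH₂ it is the mirror image.
Because condition is a function of arm × visit, a *transition* slope — the
expression change from one visit to the next within an arm — is the
natural per-feature estimand, and it is measured directly on the
normalized expression scale (RPKM for long-RNA elements, RPM for small
RNAs). The package deliberately models these normalized values with
linear (mixed) models rather than counts with a negative-binomial model:
the quantity thresholded downstream (10 RPKM / 5 RPM) lives on that scale,
and transforming to a count or log scale would change the estimand.

## The transition mixed model

For one arm and one transition, each feature is fit as

```
expression ~ visit_indicator + covariates + (1 | subject)
```

with `visit_indicator` equal to 1 at the later visit. The subject random
intercept absorbs the strong between-man baseline differences typical of
sperm RNA profiles and lets replicate libraries of the same visit enter as
genuine replicates. Fitting uses `lme4` with REML. The default covariate
set in the bundled pipeline is sequencing batch, BMI, and age; any
sample-sheet column can be supplied, mirroring adjustment for batch, time
on drug, BMI, seasonal warmth, smoking, age, amplification efficiency,
duplication rate, and alignment rate in a real analysis.

Degenerate features never abort a run: an all-constant feature reports
slope 0 and P 1; a feature whose mixed fit fails is refit by OLS with
subject effects absorbed (subject-mean centering) and flagged
`ols_fallback` in the tidy output.

## Empirical P-values by within-subject permutation

What exactly was resampled is genuinely open in this class of design; the
package's choice is the most structure-preserving one: permute the visit
(or condition) labels *within each subject*, leaving every covariate
attached to its sample, and recompute the slope under each permutation.
This preserves per-subject sample counts exactly and respects the
subject-level dependence the random intercept models. The P-value uses
the add-one estimator `p = (1 + #{|slope*| ≥ |slope|})/(B + 1)`, which can
never return 0; with B permutations the smallest attainable P is
1/(B + 1), so B must be at least 19 for calls at α = 0.05. When the
number of distinct within-subject arrangements is below B (few subjects),
the test enumerates all of them and becomes exact, with a warning.

Refitting a full mixed model per permutation is prohibitive for large
feature sets, so by default the permuted-label slope is the generalized
least squares solution with the variance components (subject and residual
variances) held at the observed REML fit. The permutation statistic is
still recomputed on every permuted dataset; only the variance weighting
is frozen, and under the null that weighting is essentially invariant to
the label permutation. `model_spec(perm_refit = "full")` switches to full
per-permutation `lme4` refits; the test suite checks both routes agree.
Two resampling policies are exposed: `per_feature` (default; each feature
has its own B permutations, drawn from a stream seeded by hashing the
feature id, so results are independent of iteration order) and
`pooled_null` (null slopes pooled across all features of a run — the
economical choice when hundreds of thousands of REs are tested, at the
price of assuming a common null slope scale).

Calibration is verified, not assumed: on a fully null synthetic arm
(20 subjects per arm, 500 features, subject and residual SD 5, B = 200)
the rejection rate at α = 0.05 must fall in [0.03, 0.07].

## Calling and the eight patterns

A transition call is `up` when `slope > +threshold` **and** `p < alpha`,
`down` for the mirror, else `ns`; both inequalities are strict ("exceeded
10 RPKM", "less than 0.05"). Thresholds are 10 RPKM (long) and 5 RPM
(small). The T1 × T2 call pair then maps onto eight response classes —
acute_up/down (changed then stable), recovery_up/down (stable then
changed), continuous_up/down (same direction twice), and
reversal_up_down/down_up (opposite directions). The last pair completes
the taxonomy for an acute response followed by an opposite recovery; the
mapping is a bijection on the eight non-(ns, ns) combinations, with
(ns, ns) as `none`.

## Case-vs-control comparison and consensus

The external control cohort contributes one library per subject; study
subjects may have replicate libraries at a visit. Each of B resamples
draws one library per study subject uniformly at random and fits OLS
`expression ~ group + covariates`, with group coded so a positive slope
means higher expression in controls. Aggregation over resamples uses the
median slope and median P — robust, order-independent, and reproducible
under seeding; a subject bootstrap would be the natural alternative and
is noted as such. Median P-values are BH-adjusted across features, and a
feature counts as altered when `bh_p < 0.05` and `|slope| > 10` RPKM
(strict, consistent with the other thresholds). Features altered in the
same direction in at least two of the three per-visit comparisons are
retained; a 2-vs-1 conflicting triple is retained on the majority
direction and flagged.

## Repeat enrichment

With R = REs overlapping the repeat of interest and A = REs overlapping
*any* repeat (non-repeat REs never enter the universe), the statistic is

```
delta_ratio = R_expressed / A_expressed − R / A
```

where "expressed" means median RPKM at the visit ≥ 25 (inclusive: a
median of exactly 25 counts as expressed; the threshold is configurable).
Significance is a hypergeometric tail — drawing `A_expressed` REs from A
with R marked — one-sided in the direction of the delta-ratio's sign,
since enrichment and depletion are directional claims; a zero delta-ratio
returns P = 1 by convention. Across the repeats of one arm × visit sweep,
BH adjustment is applied (a choice this package makes for consistency
with its other corrections; raw P is reported alongside).

## Small RNAs

Small-RNA libraries need at least 50,000 input reads (inclusive boundary,
reading the threshold as a minimum); the per-arm model pools all visits
of a condition (`expression ~ condition + covariates + (1 | subject)`)
because per-visit sample sizes are too small to model visits separately.
"Highly expressed" small RNAs have median RPM strictly above 50 across
all samples.

## RE annotation

Classes are assigned by interval overlap with deterministic priority:
exonic (≥ 1 bp exon overlap) > near-exon (gap to nearest exon ≤ the
window) > intronic (inside a gene body) > orphan. The near-exon window
defaults to 1,000 bp and is exposed rather than hard-coded, because the
upstream RE-discovery literature does not pin a single value. Strand is
ignored: ejaculated sperm RNA is extensively fragmented and no strand
rule would be defensible. A multi-gene overlap keeps all symbols. All
coordinates are 0-based half-open; abutting intervals do not overlap.

## The synthetic-data generator

The generator emulates the design, not the biology: arm sizes default to
16 (B₁HB₂) and 19 (H₁BH₂) subjects; visits are missing with probability
0.1 (settable per visit) and contribute a replicate library with
probability 0.15; expression is `baseline_mean + subject intercept +
covariate effects + planted visit offsets + Gaussian residual`, clipped
at zero. Baseline means are Gamma(shape 4, rate 0.1) (mean 40 RPKM, so
clipping is rare — the clipped fraction is reported and stays below 5% at
defaults); subject-intercept and residual SDs default to 5 RPKM.
Covariates use plausible ranges (age ~ N(35, 8) truncated at 18, BMI ~
N(27, 4), smoking ~ Bernoulli(0.2), warm season ~ Bernoulli(0.5), batch ~
3 levels, amplification efficiency ~ Beta(20, 5), duplication rate ~
Beta(2, 8), alignment rate ~ Beta(30, 3), input reads log-normal around
150k with σ_log 0.7 so a realistic minority of libraries fall under the
50k filter); only their role as adjustable confounders matters. Replicate
libraries re-draw the residual only, sharing the subject intercept and
planted effect — exactly the dependence the resampling steps must absorb.
Planted effects are cumulative: the crossover offset is `delta_t1` and
the crossback offset `delta_t1 + delta_t2`, so the two truth deltas *are*
the two transition effects.

What the generator does **not** emulate — count noise, mean–variance
coupling, RNA fragmentation, correlated features, batch-by-feature
interactions — bounds what green tests mean: they demonstrate that the
statistical machinery is correct and calibrated under the stated model,
not that the model captures every property of real sperm RNA-seq.
Gaussian residuals on the expression scale are an explicit assumption;
the residual structure of the real analysis is not documented anywhere
and this is the simplest choice consistent with modeling RPKM directly.

## Numerical choices and problem sizes

Seeding fans a single master seed out per stage, and per feature by a
31-bit string hash of the feature id, so results are independent of
iteration order and thread count; identical config + seed gives
byte-identical output TSVs. Ties in the permutation null count as
extreme (`≥`), the conservative convention. The bundled verification
runs use 20 subjects per arm, 200–500 features, and B = 200–500
permutations — sizes chosen so the planted-truth checks (slope recovery
within 10%, ≥ 90% pattern recovery, null calibration within the binomial
band) are well-powered while a full run stays within a coffee break on a
single CPU.

## Limitations

- The per-feature mixed model assumes a common slope across subjects; a
  random-slope extension is out of scope.
- The GLS permutation shortcut holds variance components at the observed
  fit; with very few subjects prefer `perm_refit = "full"` (or rely on
  the automatic exact enumeration).
- The delta-ratio universe is repeat-associated REs only, as defined;
  repeats never seen in the annotation are silently absent.
- The annotation classifier is a simplified overlap rule; it does not
  re-discover REs from alignments.
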