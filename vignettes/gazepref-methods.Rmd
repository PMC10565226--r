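---
title: "Methods: gaze processing, curation and the heteroscedastic mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze processing, curation and the heteroscedastic mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the
generative model behind the synthetic studies, the gaze-processing and
curation rules, the mixed model and its inference, and the numerical and
design choices made where more than one defensible option existed.

## The experimental design being modelled

A participant views 40 experimental slides for 5 s each (plus one
practise slide, always first and always discarded). Every slide shows
the same snake twice on a neutral background: once in a threatening
display and once relaxed, one on each side of the screen. Twenty species
contribute one slide each, in two horizontally mirrored versions (threat
left / threat right), and fall into three morphotypes: 8 cobras, 8
vipers and 4 others (2 pythons, 2 colubrids). Slides are shown in one of
four orders: order 1 is a semi-random sequence in which ten species (4
cobras, 4 vipers, 1 python, 1 colubrid) appear — both versions — before
the other ten; order 2 is order 1 reversed; orders 3 and 4 mirror every
slide of orders 1 and 2. An eye tracker records both eyes at ~30 Hz in
screen pixels (1366 × 768, viewed from ~60 cm).

The scientific question is lateralised: does the threatening posture
hold more gaze than the relaxed one, and does this depend on snake
morphotype and on the participant's population (Somali vs Czech)?

## Gaze processing

**Binocular averaging.** Analyses use the cyclopean (mean binocular)
stream. When both eyes are valid the midpoint is taken; when exactly one
is valid, that eye is used alone (configurable to a strict both-eyes
mode); when neither is valid the sample stays in the timeline as an
invalid sample. Averaging first and grouping afterwards is a design
choice: the alternative (per-eye grouping, then averaging metrics) is
not distinguishable from the stated definitions, and averaging first is
both simpler and less noisy.

**Fixation detection.** A single forward scan implements the lead-sample
dispersion rule: the first valid sample is the lead; each subsequent
valid sample within 23 px (Euclidean, ≤) of the lead joins the group;
the first sample farther away closes the group and becomes the new
lead. Three deliberate rulings on ambiguities:

* an invalid-sample gap closes the current group — "consecutive sample
  measurements" is read temporally, so a blink ends a fixation;
* a sample that re-enters the old lead's radius after an excursion does
  not rejoin the old group (strictly sequential grouping, no rejoin);
* groups need ≥ 2 samples to count as fixations; smaller groups are not
  fixations but their samples still count toward dwell time.

Duration is `(last − first member time) + one sample interval`, so an
n-sample fixation at rate r lasts exactly n/r — a fixation spanning a
whole 150-sample trial lasts 5000 ms. Each fixation is assigned to the
AOI containing its **centroid** (more robust than the lead when a
fixation sits on an AOI boundary).

**AOIs.** The design states only area fractions (37% per
lateral AOI, 1% central) and disjointness. The package constructs left
and right AOIs as full-height rectangles at the screen edges of width
`round(0.37 · width)` and a central square of side
`round(sqrt(0.01 · width · height))` centred on the fixation-cross
location. Boundary-inclusion rules are chosen so the right AOI is the
exact set-image of the left under the pixel mirror `x → width − 1 − x`
(left closed-open, right open-closed, central closed and symmetric about
`(width − 1)/2`). This makes AOI labels — and therefore every downstream
metric — strictly equivariant under horizontal mirroring, which the test
suite exercises end to end. For laterally placed stimuli the exact
rectangle shapes do not affect side-level metrics.

**Dwell time** is sample-based: valid samples whose position lies in the
AOI × the sample interval, not the sum of fixation durations. The
quality-control cut (below) operates on raw gaze time, and sub-threshold
gaze should count toward it; the two definitions are kept deliberately
distinct.

## Curation

Experimental trials whose combined left+right dwell is **under 2000 ms**
are excluded; the boundary is strict, so a trial at exactly 2000 ms is
kept (configurable). Surviving trials are collapsed per participant ×
species: threat-side metrics are read off according to each version's
`side_of_threat`; if both mirror versions survived, the four raw metrics
(fixations/dwell × threat/relaxed) are averaged and the observation gets
weight 2, otherwise the single version's metrics are used with weight 1.
Averaging the raw metrics and then differencing is algebraically the
same as averaging the differences; the raw-metric route is used because
it also yields the per-trial totals reported alongside. Fractional
fixation counts after averaging are kept as-is — the responses are means,
not counts. The difference responses are `diff_fix` and `diff_dwell_ms`,
threat minus relaxed, so positive = more attention to threat.

The demographic age comparison uses a from-scratch Mann-Whitney U with
the tie-corrected normal approximation and no continuity correction
(matching the reporting style of a Z value with a two-sided p); it is
cross-checked in the tests against `wilcox.test(exact = FALSE,
correct = FALSE)` and against exact enumeration at small n.

## The mixed model

For response \(y_{ij}\) (participant i, observation j):

\[
y_{ij} = x_{ij}'\beta + b_i + \varepsilon_{ij},\qquad
b_i \sim N(0,\sigma_b^2),\qquad
\varepsilon_{ij} \sim N\!\big(0,\ \sigma^2\, e^{2\delta_{g(i)}} / w_{ij}\big),
\]

with \(\delta = 0\) in the reference nationality (first factor level) —
the multiplicative combination of a group-specific variance scale with
fixed precision weights. Fixed effects in the full model: morphotype,
nationality, gender, age, morphotype × nationality and gender ×
nationality; the participant identity is the single random effect.

**Fitting.** The likelihood is profiled over \(\beta\) (GLS) and
\(\sigma^2\), leaving \((\lambda, \delta)\) with
\(\lambda = \sigma_b^2/\sigma^2\). All quantities are computed blockwise
per participant with the Woodbury identity — no dense n × n matrix is
formed, so a 2800-observation fit costs milliseconds per likelihood
evaluation. The optimiser is L-BFGS-B on \((\log\lambda, \delta)\) with
bounds \([-15, 15] \times [-5, 5]\), convergence factor `factr = 1e3`
(≈ 1e-12 relative), started from the fixed 3 × 3 grid
\(\log\lambda \in \{-2, 0, 2\}\), \(\delta_1 \in \{-0.5, 0, 0.5\}\); the
best converged start wins (ties broken by first-found, so fits are fully
deterministic). \(\log\lambda\) at the lower bound is reported as the
boundary estimate \(\sigma_b^2 = 0\), not an error. REML is used for all
reported coefficients, EMMs and F tests; ML for likelihood-ratio and
AIC comparison, with AIC = −2ℓ + 2(p fixed + 2 + #δ).

**Denominator degrees of freedom** follow a two-level inner–outer rule:
a term whose design columns are constant within every participant is
"between" and tested on \(m - p_b\) df; a term varying within
participants is "within" and tested on \(N - m - p_w\) df, where m is
the number of participants, N the number of observations and
\(p_b, p_w\) the non-intercept parameter counts at each level. With the
study-scale dimensions (m = 142, N = 2737) this bookkeeping yields the
familiar df values 138 and 141 (between, depending on the retained
terms) and 2591/2593 (within). `nlme`'s `anova.lme` subtracts one
further between-level slot for the intercept; that convention is
available via `nlme_convention = TRUE`, but the default is the variant
that matches the df values the design's reporting style prints.
Kenward–Roger or Satterthwaite adjustments are out of scope.

**Backward reduction** refits by REML, computes marginal (drop-one) Wald
F tests for every currently *eliminable* term — interactions are
eliminable before their main effects; a main effect is protected while
any retained interaction contains it — and drops the term with the
largest p ≥ α (default 0.05), repeating until everything retained is
significant or protected. Marginal rather than sequential tests are used
because single-term reporting at each elimination step is the target
output; the elimination order is then invariant to how the formula lists
the terms, which the tests verify.

**Estimated marginal means** for focal factors average the model matrix
with equal weight over non-focal factor levels, holding covariates (age)
at the sample mean. Cell tests against zero use the focal term's
denominator df ("within" if any focal factor varies within
participants); nationality contrasts use the between-participant df.
Confidence intervals are t-based.

## The synthetic-data generator

The generator is a first-class module: it defines the conditions every
downstream stage is validated under.

**Roster.** 71 + 71 participants, 25 women / 46 men per nationality,
integer ages from truncated normals (Somali: mean 22.4, sd 3.5, range
19–39; Czech: mean 24.6, sd 4.5, range 18–44 — matching the reported
means and ranges), presentation orders assigned uniformly.

**Trial streams.** A trial alternates fixation episodes with
single-sample saccade transits until the 150-sample budget (exactly
30 Hz, t = 0, 33.3, …) is filled. An episode targets the fixation cross
with probability 0.13 (duration 133 ms), otherwise a lateral AOI,
picking the threat side with probability
\(\mathrm{logit}^{-1}(b_m + a_i)\): \(b_m\) is the morphotype's
orienting bias and \(a_i \sim N(0, 0.15)\) a participant-level offset —
the between-participant heterogeneity the model's random intercept
recovers. Lateral durations are truncated normal (mean 224 ms, sd 70 ms,
minimum 2 samples), multiplied on the threat side by a maintenance
factor \(\kappa_{m,\mathrm{nat}}\). Samples scatter around the episode's
fixation point (uniform inside the AOI with a 35 px margin) with 5 px
Gaussian jitter — well under the 23 px dispersion radius — and each eye
adds 1.5 px of independent noise. Fixation-duration noise is scaled 1.25×
for Somali participants, giving the nationality variance stratum
something real to estimate. With probability 0.0734 a contiguous block
of 65–95% of the trial is invalidated, which reliably pushes the trial
under the 2000 ms dwell cut — so the per-trial dropout probability is
also the expected exclusion fraction.

**Calibration.** The bias parameters are set in closed form from the
study-level targets: ≈18.07 lateral fixations and ≈4368 ms lateral dwell
per trial, fixation-count differences of 1.85 / 0.46 / 0.28
(cobra/viper/other), and dwell differences of 584.7 / 15.4 / 148.8 ms
(Somali) and 475.3 / 300.2 / 334.5 ms (Czech). With n lateral fixations
per trial, total dwell T, threat probability p and duration multiplier
κ, first-order expectations are \(E[\Delta\mathrm{fix}] = n(2p-1)\) and
\(E[\Delta\mathrm{dwell}] = T\,(p\kappa - (1-p))/(p\kappa + 1 - p)\).
Two detector-level corrections enter the inversion:

* *jitter splits*: a sample drifting beyond the radius splits a fixation
  in two, with per-sample probability
  \(\exp(-r^2/4\sigma_j^2) \approx 0.005\); longer (threat-side)
  fixations split more often, adding \(q\,E[\Delta\mathrm{dwell}]/\Delta t\)
  to the count difference;
* *same-side transits*: the transit sample between two fixations in the
  same (convex) AOI lies inside it and counts toward dwell, adding
  \(n(1-c)(2p-1)\) samples to the dwell difference.

Both terms are removed before inverting. The trial-time budget couples
the remaining knobs: mean episode length and the central-episode
fraction were solved so the realised per-trial marginals sit on the
targets (verified by simulation during calibration, before any
downstream fitting). Two bias components are necessary: a single
side-choice bias cannot produce fixation differences without a
nationality effect *and* dwell differences with one, which is exactly
the reported pattern — orienting (where the next fixation goes) is
shared across populations, maintenance (how long threat displays hold
gaze) differs.

**What the generator does not emulate:** calibration drift, smooth
pursuit, pupillometry, saccade kinematics (transits are single
interpolated samples), spatially structured tracking loss, and any
dependence of gaze on image content beyond the threat/relaxed side
assignment. Passing recovery tests therefore demonstrates that the
pipeline's statistics are correct under the assumed generative
structure, not that the model is adequate for any particular real
recording.

## Problem sizes and test design

The test suite validates each stage against independent oracles: a
literal re-scan implementation of the grouping rule (500 random-walk
streams), a dense multivariate-normal likelihood (datasets with n ≤ 50,
agreement to 1e-8), closed-form balanced-ANOVA REML components (1e-6),
`nlme` with the matching `varComb(varIdent, varFixed)` structure, and
the `emmeans` package on that `nlme` fit. Parameter-recovery runs use
100 replicate studies of 16 participants with a reduced 6-species
catalogue (the generator's expectation is estimated by a separate
2200-trial Monte-Carlo per morphotype, since the realised expectation
includes the detector-level corrections above), plus 40 zero-bias
replicates for coverage of zero, and one full-scale study (142 × 40)
checked against the calibration targets. These sizes keep the whole
suite within a few minutes on one CPU while leaving the Monte-Carlo
error well below the tolerances being asserted.

## Known limitations

* The residual-variance structure supports one grouping factor plus
  fixed weights; no general variance functions.
* Random intercepts only — no random slopes or crossed random effects;
  Gaussian responses only.
* The inner–outer df rule is exact bookkeeping, not an approximation to
  the sampling distribution; for strongly unbalanced designs
  Satterthwaite-type df would differ.
* Fixation detection is dispersion-based by design; velocity-based
  (I-VT) detection is out of scope.
* The a-priori power analysis of the original design is not
  reimplemented (its software settings are underdetermined).
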