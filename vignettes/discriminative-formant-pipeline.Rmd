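---
title: "Modeling paradigmatic uncertainty and formant trajectories with discform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling paradigmatic uncertainty and formant trajectories with discform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`discform` studies a representational question in speech-production
modeling: when a simple two-layer error-driven network is used to derive a
measure of the uncertainty associated with the inflectional functions of
German word-final [ɐ], should those functions be placed on the *output*
side of the network (the network learns to predict them from context) or
on the *input* side (they act as cognitive cues that help predict the
articulatory gesture)? The package implements both structures, derives
activation-based uncertainty measures from each, and asks which measure
better predicts the F1/F2 trajectories of the vowel — exercised end to end
on a synthetic language whose ground truth is known, so that the whole
pipeline can be validated by parameter recovery rather than by eyeballing.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic tests do and do
not establish.

## 1. Learning events and the two network structures

Events are built from a five-word sliding window (`window_size = 5`,
odd, truncated at utterance boundaries — windows never cross utterances,
and a single `#` boundary symbol marks each edge of the concatenated
window string). Per window the cue inventory is:

* **word cues** (`w:`): the lower-cased word forms of the non-center
  window words. The target word form itself is never a cue in either
  structure; this avoids a direct identity mapping from input to output.
* **diphone cues** (`d:`): all adjacent phone pairs of the concatenated
  window phones, boundary symbols included, deduplicated within the
  window. Phones are single-character symbols so diphones are two-character
  strings (`"5"` is the schwa vowel).
* **function cues** (`f:`, functional-input structure only): the
  inflectional-function labels of a schwa-final target. The ablation
  switch `include_function_cues = FALSE` removes these, and nothing else.

In the **functional output** structure the outcomes are the target's
function labels (`fn:`), or a single placeholder `ph:NoFunction` for
targets without functions — the placeholder keeps cue competition alive on
the majority of events. In the **functional input** structure the
outcomes are the target's word form (`o:`) plus the gestural placeholder
`g:ER` whenever the target is schwa-final.

Two genuinely open points were settled as follows. First, the worked
examples in the source material are internally inconsistent about whether
the center word form is an input in the output structure; we follow the
prose rule (never an input) in both structures, which also keeps the two
structures maximally comparable. Second, whether diphone cues are
deduplicated within a window is not documented anywhere we could find; we
deduplicate, because cues form sets under the learning rule in any case.

## 2. The Rescorla–Wagner learner and its oracle

For each event, with V(o) the summed weight from the present cues to
outcome o (computed before any update of that event):

* present outcome: `Δw(c,o) = eta_present · (lambda_max − V(o))`
* absent outcome: `Δw(c,o) = eta_absent · (0 − V(o))`

applied to every present cue c; absent cues are untouched. Defaults are
`lambda_max = 1`, `eta_present = eta_absent = 0.01` — conventional
naive-discriminative-learning rates; the original analysis does not print
its rates, so the tests check qualitative robustness across
`eta ∈ {0.001, 0.01, 0.1}` rather than pinning one value. Training is a
single pass in corpus order (the implied schedule of incremental
learning); multiple passes are available for equilibrium studies.

Two universes for absent-outcome updates are nominally supported
(`declared`: all outcomes registered in the stream; `seen_so_far`). With
zero-initialized weights they coincide: an outcome that has never been
present has V(o) = 0 and target 0, hence a zero update. We therefore
pre-scan the stream for the registries and document the flag as
informational.

All summations (V(o), activations) run in lexicographic label order, so
training is bit-reproducible, and the test suite holds the learner to
*exact* floating-point equality against an independently coded
brute-force updater. `danks_equilibrium` solves the least-squares normal
equations on cue co-occurrence frequencies (pseudo-inverse for singular
systems) — the expected fixed point of the update when the two rates are
equal — and the suite verifies convergence to it under repeated shuffled
passes with a small rate. A note on that test's conditions: the
stochastic ripple of the final weights scales like √eta and the
convergence bias like exp(−eta·N·λmin(C)), so the equilibrium checks use
eta around 2–5·10⁻⁴ with enough events for several time constants; at
eta = 0.01 the ripple alone exceeds the 0.01 tolerance band.

The **activation** of a schwa token is the summed weight from its window
cues to the structure-appropriate outcome set: the token's function
labels (functional output) or `g:ER` alone (functional input). Summation
— not averaging — across multiple function labels is the default, matching
the verbal definition of the measure; a mean variant is available via
`aggregate = "mean"` for sensitivity analysis.

## 3. Formant preparation

Exclusions, in a fixed precedence that the filter report mirrors without
double counting: (1) vowels shorter than 0.018 s; (2) individual samples
with F1 outside 250–1000 Hz or F2 outside 1000–2000 Hz; (3) tokens left
with fewer than 3 samples. The source text is ambiguous about whether
range violations removed samples or whole tokens; dropping samples first
and then thin tokens covers both readings, and
`min_samples_per_token` exposes the boundary. F1 is multiplied by −1
(so higher values mean a higher tongue position), then −F1 and F2 are
each centered and scaled to unit variance *within speaker and dimension*
(per-dimension scaling keeps the two formants comparable after
normalization — "normalized by speaker" alone does not fix this choice).
Negation is applied before z-scoring; the two orders are equivalent up to
sign conventions and this one is fixed for reproducibility. Per-token
time is mapped affinely to [0, 1].

## 4. The trajectory-regression engine

`fit_model` is a structural analog of a GAMM smoother, not a re-export of
one: B-splines with difference penalties replace thin-plate bases, and
smoothing parameters maximize the exact Gaussian log marginal likelihood
(coefficients integrated out under the penalty prior, σ² profiled).
Numerical choices that matter:

* **Bases**: clamped (repeated-boundary-knot) B-splines with equally
  spaced interior knots; with `n_basis = degree + 1` this is the
  Bernstein basis, and rows always sum to one. Defaults: 10 basis
  functions for univariate smooths, 5 per tensor margin, 5 for factor
  smooths — chosen so the ladder's largest model stays in the hundreds of
  coefficients at the simulation sizes below.
* **Penalties**: second-order *divided* differences with respect to the
  Greville abscissae, so the penalty null space is exactly the straight
  line in the covariate and the λ→∞ limit of a penalized smooth is the
  OLS line (the suite checks both limits, λ = 0 against unpenalized least
  squares at 10⁻⁸ and λ→∞ against the line).
* **Tensor terms**: row-wise Kronecker products with each marginal
  penalty Kronecker-expanded; the interaction-only version (`ti` analog)
  removes the span of {1, marginal bases} through exact orthogonality
  constraints absorbed by QR reparameterization.
* **Identifiability**: every by-factor smooth is sum-to-zero constrained
  per level; factor intercepts live in the fixed effects.
* **Random factor smooths**: per-level spline deviations (first-order
  difference penalty shared across levels) plus a ridge penalty on the
  whole block, giving a proper random effect with no unpenalized
  directions. Speaker smooths are always included; by-place-of-articulation
  smooths are not fitted on synthetic data because the generator has no
  coarticulatory structure for them to absorb.
* **AR1**: residual autocorrelation within a token-by-dimension series is
  handled by pre-whitening at a *fixed* ρ (default 0.8, the value used in
  the original analysis); the first sample of each series is scaled by
  √(1−ρ²). ρ is not estimated.
* **Optimization**: Nelder–Mead over log λ (Brent for one-dimensional
  problems) from a deterministic start plus seeded random restarts; one λ
  per marginal penalty, shared across by-factor levels, keeps the search
  space at 4–7 dimensions for the ladder models. Ladder models are
  additionally warm-started from the baseline's optimum, and the baseline
  is then re-optimized from each model's shared-λ prefix — the comparison
  below is only meaningful if no model is under-optimized relative to
  another, and the feedback step removes the one systematic failure mode
  we observed (the baseline stuck in a worse λ basin than its
  extensions).
* **Effective degrees of freedom** are the trace of each term's block of
  the influence matrix. They are an analog of, not a match to, the
  reference degrees of freedom printed by other GAMM software, and are
  reported as such.

The **ladder** fits m0 (dimension-by-class intercepts + a time ×
log-duration tensor per dbc level + speaker factor smooths per dimension),
then m1–m4 adding the activation smooth by dimension, by dbc, and the
time × activation interaction tensor by dimension or dbc. ΔML =
ml(m0) − ml(mk), positive = better. Because the exact marginal likelihood
integrates each model's own penalty prior, adding a term that shrinks to
its null space still shifts the score by a structural constant (typically
a few units here, negative); a null predictor therefore produces small or
negative ΔML, not exactly zero, and the null-calibration test checks
ΔML ≤ 2 rather than |ΔML| ≈ 0. `trim_and_refit` removes rows with
standardized whitened residuals beyond 2.5 sd exactly once and refits;
`predict_percentile_trajectories` returns population-level (random smooths
excluded) F1/F2 trajectories on a 100-point time grid at percentiles
10/30/50/70/90 of a chosen covariate, other covariates held at medians and
factors at the modal word class. A word-class collapse check
(`collapse_classes = TRUE`) refits the baseline with each pair of classes
merged and reports the ML change.

## 5. The duration model

Log vowel duration is regressed on activation with local speaking rate
and segment count as controls and crossed random intercepts for speaker
and word. The fitter profiles the two variance ratios over a coarse
log-scale grid followed by Nelder–Mead, with GLS for the fixed effects at
each candidate via Woodbury identities; ML is the default (matching the
ML-based comparisons elsewhere in the pipeline) and REML is a flag. The
suite cross-checks coefficients, variance components and the ML
log-likelihood against `lme4` on simulated data, and verifies that zero
variance ratios reproduce OLS exactly.

## 6. The synthetic language and what it does (not) show

The generator's defaults are the package's study conditions, fixed once:

* 80 word types, 25% schwa-final, Zipf exponent 1, 3000 tokens, 6
  speakers, utterances of geometric length (mean 8). These sizes give
  roughly 700–900 schwa tokens and a model table of ~10⁴ rows — large
  enough for the ladder contrasts to stabilize, small enough that the
  full 10-seed recovery experiments run on one CPU in minutes.
* a 60-label function inventory assembled from grammatical-class ×
  number × gender × case pools; each schwa type carries a bundle of 1–3
  labels, and bundles are *shared* across types (about one bundle per 2.5
  schwa types), reproducing the many-types-to-few-functions structure
  that makes function cues informative beyond word identity.
* word classes allocated 0.48/0.09/0.43 (content / complex-function /
  simple-function), the composition of the corpus the analysis design
  comes from.
* `context_predictivity = 0.3`: the word before a schwa target is drawn
  from a bundle-specific signal set with probability 0.3, so context is
  partially — not fully — informative about the functions. This is the
  lever that separates the two network structures: the input network
  reads the functions directly, the output network must infer them from
  this noisy context.
* tracks: class-specific u-shaped quadratics in normalized time (inside
  F1 350–900 Hz, F2 1100–1900 Hz before noise), sampled at 100 Hz
  (minimum 3 samples), plus `delta_duration`·(log dur − log 0.06 s) and a
  per-speaker offset (drawn N(0, 30 Hz) per experiment), plus AR1 noise
  (ρ = 0.6, stationary sd 25 Hz). Log-normal durations (median 60 ms,
  σ_log = 0.45, scaled by speaking rate) keep ≥95% of tokens above the
  18 ms exclusion threshold.
* the **latent predictability axis** u is the standardized log token
  frequency of each token's function bundle; `delta_uncertainty` (default
  40 Hz per SD) is *added* to F1 and *subtracted* from F2, i.e. frequent,
  well-supported bundles are realized lower and more retracted. After the
  −1 × F1 inversion and z-scoring, both prepped dimensions move with
  −sign(delta_uncertainty) — the sign convention the recovery tests use.
  The pipeline never reads u; it must recover it through the trained
  activations (empirically, functional-input activation correlates with u
  at r ≈ 0.4–0.5 under the defaults, the ablation lower, the
  functional-output activation near zero), which is what makes the
  recovery test non-circular. Ground-truth effect sizes are stated in Hz
  on the raw tracks rather than z-units, since normalization happens
  downstream and only the sign survives it exactly.

What passing tests show: the event coding is exact; the learner is
exactly the stated update; the spline engine reproduces its analytic
limits and recovers known curves; the full pipeline recovers the sign of
a planted uncertainty effect and ranks the input structure above the
output structure when the generating process matches the input structure's
assumptions. What they do not show: anything about real speech — the
generator has no coarticulation, no segment-level phonology beyond the
schwa-final convention, no audio, and its context predictivity is a
single global parameter rather than grammar; conclusions about the real
corpus analysis this design mirrors require the real corpus.

## 7. Known limitations

* ML scores from the exact integrated likelihood are comparable across
  the ladder's models but not across different data subsets (trimming
  changes n); `trim_and_refit` therefore reports n_used.
* edf values are engine-specific analogs; do not compare them numerically
  with other GAMM software.
* The λ search is derivative-free; with 7 smoothing parameters the
  optimizer occasionally lands a few score units short of the optimum,
  which is why the ladder feeds optima between nested models. Residual
  under-optimization on the order of 1–3 units is possible and is below
  every decision threshold used in the tests.
* The duration model supports exactly two crossed random-intercept
  factors (speakers, words) — no random slopes, matching the analysis it
  implements.
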