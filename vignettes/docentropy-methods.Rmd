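---
title: "Nonlinear EEG entropy analysis for disorders of consciousness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear EEG entropy analysis for disorders of consciousness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(docentropy)
```

## The problem

Patients surviving severe brain injury may remain in unresponsive
wakefulness syndrome (UWS, also called vegetative state) or a minimally
conscious state (MCS). Predicting which of them will improve is clinically
consequential and hard. One quantitative approach scores the *irregularity*
of the resting and stimulus-evoked EEG: more complex cortical dynamics, and
a larger complexity increase under painful stimulation, indicate residual
cortical function. `docentropy` implements that analysis end to end:
approximate entropy (ApEn) per channel, cross-approximate entropy (C-ApEn)
between a central electrode and its neighbours, group statistics, and a
prognostic regression of 12-month outcome — together with a synthetic cohort
generator so the whole pipeline is testable without patient data.

## Entropy statistics

For a series $u$ of length $N$, embedding dimension $m$ and tolerance $r$,
ApEn is $\Phi^m(r) - \Phi^{m+1}(r)$, where $\Phi^m$ is the mean of
$\ln C_i^m(r)$ and $C_i^m(r)$ is the fraction of length-$m$ templates
within Chebyshev distance $r$ of template $i$ (self-match included,
comparison $\le r$). Higher values mean less predictable dynamics.
Defaults are the canonical EEG settings: $m = 2$, $r = 0.2\,\mathrm{SD}(u)$,
$N = 32768$ samples (65.536 s at 500 Hz). Because $r$ scales with the SD,
ApEn is invariant to amplitude rescaling.

C-ApEn applies the same machinery with templates from one series and
targets from another, measuring the *asynchrony* of two channels; lower
values mean more similar dynamics. Conventions the literature leaves open,
fixed here:

* both series are z-scored before matching and $r$ is taken relative to
  unit SD — required because cross-channel amplitudes differ;
* templates always come from the central electrode (`C_A`/`C_U`), the first
  element of every designated pair, since C-ApEn is asymmetric;
* templates with no match within $r$ (possible without self-matches) are
  excluded from each level's average and counted; results with more than
  10% exclusions are flagged unreliable rather than floored, because a
  count floor biases short-series values;
* `capen(u, u)` equals `apen` of the standardized series exactly, a useful
  identity test.

The production implementation sorts template starts by value so only a
window of candidates is scanned per template (box-assisted counting, exact,
not approximate); a transparent double-loop implementation (`apen_naive`,
`capen_naive`) is retained and the test suite requires agreement to 1e-12.

## Preprocessing and montage

Recordings are 16-channel 10–20 EEG at 500 Hz, bandwidth 0.3–100 Hz
(treated as an acquisition property and not re-applied). Software applies
only a zero-phase second-order 50 Hz notch (Q = 30). The analysis epoch is
the earliest run of 32768 consecutive samples in which no channel exceeds
100 µV absolute — an automated, configurable proxy for the visual
artifact-free selection done clinically; it is a stand-in, not a
reproduction, of expert judgement.

Channels are relabeled from left/right to affected/unaffected
(`FP_A … PT_U`, with AT/MT/PT from F7/F8, T3/T4, T5/T6 — inferred from
standard 10–20 nomenclature). The affected hemisphere comes from imaging
when available; otherwise the hemisphere with the lower mean eyes-closed
ApEn over its 8 channels is labeled affected (lower complexity = more
severe impairment), with an exact tie going to the left and logged.

## Synthetic cohorts

Public recordings rarely accompany this kind of study, so the generator is a
first-class module. Each channel is
$(1-\lambda)\,\mathrm{osc} + \lambda\,\mathrm{noise}$ — a quasi-periodic
component (random delta- and alpha-band tones) plus band-limited
(0.3–100 Hz) Gaussian noise — the simplest family in which ApEn is a
controlled, monotone function of a single irregularity parameter
$\lambda$. Group, condition and hemisphere structure enter through
$\lambda$:

* baselines $\lambda_{UWS} = 0.155$, $\lambda_{MCS} = 0.190$, chosen once
  so eyes-closed ApEn means land near the clinically reported scale
  (≈ 0.60 vs ≈ 0.68) with between-subject SD near 0.1 (subject-level SD
  0.038 shared across channels, per-channel SD 0.028);
* fixed per-region offsets reproduce the anterior–posterior complexity
  gradient (frontal-polar lowest, temporal highest);
* pain adds +0.024 (UWS) / +0.042 (MCS) to unaffected-hemisphere
  irregularity and −0.012 to the affected side in both groups, with
  subject- and channel-level response noise — yielding positive unaffected
  responses that are larger in MCS and near-zero affected responses, the
  clinical sign pattern;
* pain is modelled as one bilateral-stimulation epoch; an optional
  two-epoch mode exists but is not the default, since hemisphere effects
  enter through channel grouping rather than separate stimulations.

Coupling deserves a note. C-ApEn is computed over all template/target
position pairs, so it is insensitive to sample-level correlation between
two series with identical dynamics — sharing a Gaussian source, even
completely, leaves it essentially unchanged (we verified this directly).
What C-ApEn does detect is a *mismatch of dynamics* between the pair. The
coupling weight therefore acts by shrinking the idiosyncratic per-channel
irregularity dispersion within a hemisphere: strongly coupled cortical
areas share a dynamical state and score low pair C-ApEn, decoupled
functional islands drift apart in complexity and score high. Defaults
(UWS 0.5, MCS 0.3) make UWS hemispheres more uniform — consistent with
fewer independent functional islands — while the MCS > UWS level difference
in C-ApEn is carried by the complexity difference itself.

CRS-R scores are integers 0–23 from group-shifted truncated normals
(UWS mean 5, MCS mean 9.5; the exact clinical distribution is not
published). The 12-month outcome follows a linear-probability model:
improvement probability `intercept + Σ coef × feature` over named
predictors (CRS-R and latent entropy responses), clamped to [0, 1] with
clamping counted. Improved/non-improved subjects then draw an mGOS
category from upgrade profiles consistent with their baseline (a UWS
baseline is VS; death occurs only as a non-improvement). Default
coefficients (intercept −0.23, CRS-R 0.087, plus small weights on `P_A`
and `C_U-MT_U` responses) were calibrated once so that large simulated
cohorts improve at ≈ 26% (UWS) and ≈ 66% (MCS), the clinically reported rates; the CRS-R weight that achieves this is,
reassuringly, of a clinically plausible magnitude.

Reproducibility: one master seed; per-subject streams derived by a
counter-based split, so a subject's data are a function of (seed, index)
only and cohorts are bit-identical across reruns.

What the generator does *not* emulate: volume conduction and a forward
head model, 1/f spectral calibration, artifacts (beyond an optional spike
injector used to test epoch selection), nonstationarity, and real CRS-R
psychometrics. Passing tests therefore demonstrate that the pipeline's
statistics behave correctly on signals with controlled complexity
structure — not that the clinical effect sizes themselves are reproduced
from real EEG.

## Group statistics

Per-measure comparisons are Welch two-sample t tests (pooled variance
available behind a flag; Welch chosen for robustness since the original
analysis does not specify). Multiple comparisons over channel blocks are
corrected with two-sample Hotelling $T^2$ tests,
$F = \frac{n_1+n_2-k-1}{k(n_1+n_2-2)} T^2$ on $(k, n_1+n_2-k-1)$ df,
over four blocks: 8 affected channels, 8 unaffected channels, 5 affected
pairs, 5 unaffected pairs. Both $T^2$ and $F$ are reported because
reported "test statistics" for such tables are not always labelled with
their scaling; no claim is made to match any particular printed statistic.
No further multiplicity correction is applied beyond the blocks.
Comparison tables print mean ± SD per group with the clinical star
convention (*, **, *** at p < 0.1, 0.05, 0.01).

## Prognostic regression

Improvement is a strict upgrade of the 12-month mGOS category (ordinal
scale death < VS < MCS < severe < moderate < good) over the baseline
category (VS for UWS, MCS for MCS). The model is ordinary least squares of
the 0/1 indicator — a linear probability model, matching the
OLS-style summary (residual SE, R², F) such analyses report; a logistic
variant is available behind a flag. Four designs share the covariates
sex (male = 1), age, duration, diagnosis dummies, CRS-R total, plus one
entropy block: 8 affected or unaffected channels (ApEn models, 15
parameters, residual df 147 at n = 162) or 5 affected or unaffected pairs
(C-ApEn models, 12 parameters, residual df 150).

Two genuinely open design points and the choices made:

* Diagnosis coding: a cohort described as exhaustively TBI/stroke cannot
  support both dummies plus an intercept, yet the reported df structure
  estimates all of them. The generator therefore includes a small "other"
  diagnosis category (5%) and the dummies are coded against that
  reference, which reproduces that df structure; exhaustive coding raises a
  rank-deficiency error naming the aliased columns.
* Entropy predictors default to pain-minus-rest differences (the quantity
  interpreted as activation under pain); raw pain-condition levels are
  available via `entropy_source = "pain_level"`. "Affected side" is read
  as the hemisphere of the channels, not the stimulated leg.

## Verification design and problem sizes

The statistical checks run at sizes chosen to keep the full suite fast
while leaving each test adequately powered: oracle equivalence on 100
series of 20–200 samples; null calibration of Welch t and Hotelling $T^2$
with 1000 replicates at n = 30/group (acceptance band 3–7% at α = 0.05);
the qualitative group pattern on ten replicate cohorts of 30 + 30 subjects
with 8192-sample epochs (the full 32768-sample default changes estimates
by ~0.01 and only slows the suite); and outcome-model recovery over 50
replicates at n = 500. In the recovery study the nonzero generating
coefficients are confined to one design (affected-ApEn) so that the fitted
model is correctly specified; each nonzero coefficient must fall inside
its 95% CI in ≥ 90% of replicates, and the zeroed coefficients are
assessed by their pooled non-significance rate across replicates ×
coefficients (a per-coefficient threshold on eleven null coefficients
would fail by binomial noise alone about half the time even for a correct
implementation). The affected-side "non-significance" in the pattern check
is assessed at the block level with the Hotelling test — the same
instrument the analysis itself uses for multiplicity.

## Numerical notes and limitations

* Distances use strict `<= r`; self-matches are included in ApEn
  (classical definition), which is what makes the `capen(u,u)` identity
  exact. Sample-entropy-style exclusion is deliberately not used.
* Constant series return ApEn 0 with a warning; C-ApEn on a constant
  series is an error (standardization is undefined).
* The notch filter is applied forward-backward, so its effective magnitude
  response is squared; it is idempotent only up to the skirt of the notch
  (a few percent on broadband signals).
* EDF output quantizes to 16-bit integers; round trips are exact only to
  the per-channel quantization step. The CSV dialect is lossless to
  double-precision printing.
* Single-CPU sequential execution is the correctness contract; nothing in
  the pipeline depends on execution order beyond the seed.
* The linear probability model can predict outside [0, 1]; that is
  inherent to the published model class, and the logistic flag exists for
  users who prefer calibrated probabilities.
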