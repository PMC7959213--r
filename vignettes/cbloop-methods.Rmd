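---
title: "cbloop: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cbloop: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cbloop` simulates a closed-loop EEG brain–computer interface (BCI)
experiment in which introspective reports are probed with occasionally
deceptive feedback. This vignette is the package's own account of the
science: the generative models, what every tunable parameter means, how the
frozen defaults were calibrated, and what a passing test does and does not
establish. No empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The stimulus representation

Both visual streams are abstracted to 1-D drives with one value per sample
(256 samples/s): `y_face` and `y_spiral`, oscillating at `f0 = 1.875` Hz in
temporal phase opposition. The published stimuli swept through phase
scrambling; the exact waveform of that periodic drive is not printed
anywhere, so the default realization is the minimal faithful choice — a
pure sinusoid, face at phase 0, spiral at phase π (pointwise negation). A
periodic sawtooth "sweep profile" is available via
`make_templates(waveform = "sweep")`; it carries the same fundamental and
half-period opposition (correlation −1/2 rather than −1). Only the
opposition and the fundamental matter to the decoder, and both choices are
explicit and configurable.

Durations are generally a non-integer number of cycles (5 s × 1.875 Hz =
9.375), so the spectral peak falls between raw FFT bins; peak frequency is
estimated by zero-padded FFT with parabolic interpolation
(`template_peak_frequency()`), a standard estimator accurate to ~1e-3 Hz
here. The sampled sawtooth carries a half-sample phase offset so that both
waveforms are exactly zero-mean over integer cycles.

## 2. The EEG generator (forward model)

Each trial has a latent attention trace: an initial state (face/spiral,
equiprobable), at most one switch (probability `switch_prob`, uniform
switch time), and a per-trial attention *strength* `q ~ Beta(1.3, 1)` on
[0, 1]. The 1-D source is

    s(t) = g_att(q) * y_attended(t) + g_unatt(q) * y_unattended(t)

where `q` scales the attended/unattended gain contrast around its midpoint:
`g_att = m + q·h`, `g_unatt = m − q·h` with `m = (g_a+g_u)/2`,
`h = (g_a−g_u)/2` (defaults `g_a = 1`, `g_u = 0.4`). `q = 1` is full
attentional modulation; `q = 0` makes the trial undecodable *and* leaves
the participant with no introspective evidence — this coupling is what
produces choice-blindness episodes on weak trials. The source is projected
through one fixed random spatial mixing vector per participant
(`N(0, 1/n_channels)`, drawn from `mixing_seed`; the across-participant
variation in mixing norm produces realistic heterogeneity in decoding
accuracy), optionally jittered per channel by 0–100 ms to exercise the
decoder's lag structure, and embedded in white Gaussian noise of standard
deviation `noise_sd` (an approximate 1/f spectrum is available via
`noise_spectrum = "one_over_f"`; white is the default because the decoding
band is narrow and the flat spectrum is much cheaper at session scale).

Trials are simulated with a `lead_in_s = 2` s stretch of continued
stimulation before the 5 s decision phase. In the experiment the
stimulation is continuous across trials, and two consumers depend on that
context: score windows ending early in the trial's final 3 s reach back
before trial onset (the consistency metric needs 12 windows there), and
the causal 1 Hz high-pass needs ~1–2 s to settle. A standalone 5 s trial
would make the consistency metric's precondition unsatisfiable.

What the generator does **not** emulate: biophysical head geometry, eye
movements and artifacts, non-stationary noise, electrode drift, or any
hardware timing. A green test therefore establishes that the *pipeline* is
correct and calibrated on data satisfying its own assumptions — not that
the pipeline would reach the same numbers on arbitrary real EEG.

## 3. The decoding chain

The online chain is: downsample 2048 → 256 Hz, band-pass 1–30 Hz with a
**one-pass** (causal, forward-only) Butterworth filter of order 6, common
average reference. "One-pass" is read as causal filtering — required for a
real-time system; zero-phase two-pass filtering is deliberately not used.
The anti-alias filter for downsampling is unspecified in the source design;
the default is a causal order-8 Butterworth low-pass at `0.4 · fs_out`.
Filters are designed in-package (analog prototype → pre-warped bilinear
transform → second-order sections) because no DSP package is available in
the supported dependency set; the design is verified in the tests against
the analytic Butterworth magnitude response, and filtering is a C++ cascade
with state carried across a whole trial (equivalent to streaming updates
with carried state, reset at trial boundaries).

The backward model reconstructs `Yhat_t = Σ_{c,k} w_ck R_{t+τ_k,c}` using
*future* EEG relative to stimulus time (positive lags), mirroring how a
stimulus at time *t* influences EEG at `t + τ`. Only valid samples are
produced — no zero padding, so a window's reconstruction is `max(τ)`
samples shorter than the window. Weights solve a ridge-regularized least
squares of the attended template on lagged EEG pooled over training trials.
The penalty is trace-normalized (`λ_abs = λ · tr(X'X)/p`), making weights
invariant to trial duplication. Defaults: lags 0–500 ms every 62.5 ms
(9 lags × 64 channels = 576 features) and `λ = 0.01`. The published lag
set is not printed; 0–500 ms is the convention for backward models of this
family, and the 62.5 ms spacing keeps leave-one-trial-out training
tractable at desk scale (the dense 129-lag variant is configurable but
needs ~0.5 GB Gram matrices). Cross-validation is leave-one-trial-out with
per-trial Gram caching; an inner-loop λ search runs when `ridge_grid` has
several values.

Scoring emits one `(c_F, c_S)` Pearson pair per 250 ms over the trailing
3 s; the decision averages the last 6 pairs and takes the larger mean, with
exact ties resolved to face (a measure-zero event that must still be
defined; it is logged when it happens).

## 4. Trial-level metrics

Internal evidence is `signed_ie = Σ (c_F − c_S)` over the last 6 pairs and
`ie = |signed_ie|`. The consistency index is `ie` divided by the
bootstrapped variance of the 12 score differences spanning the last 3 s —
the numerator and denominator windows deliberately differ (1.5 s vs 3 s),
exactly as stated in the source design; both are configurable rather than
"fixed". The bootstrap summary is the mean of resampled variances
(`boot_stat = "mean_var"`); the variance-of-resampled-means reading is
available behind the switch. A zero-variance denominator (reachable in
noiseless tests) is floored at `ε = 1e-8` and logged.

Report accuracy compares the report with the *decoded* item — the latent
attended state is unobservable in the real experiment. On deceptive trials
only, accuracy identifies the mechanism: correct → genuine introspection,
incorrect → confabulation.

## 5. The observer model

The observer integrates two cues into a decision variable:

    L = w_int · z + w_cue · cue / (|z| + κ) + ε,   ε ~ N(0, σ²)

* `z` is her *own* readout of the latent attention state:
  `q × (signed attended fraction over the final 0.65 s)`. The BCI measures
  the same latent state through 4.5 s of noisy EEG; the observer reads only
  the trial's end ("what was I attending just before the feedback?"). A
  late attention switch therefore decouples strong introspective evidence
  from the decoded item — the same late-decision-change sensitivity the
  real decoder has. An alternative wiring (`observer_evidence =
  "decoded"`) feeds her the decoder's z-scored evidence instead; it is not
  the default because an observer who reads the decoder's own signal can
  never confidently contradict it, making confident confabulation — the
  phenomenon of interest — impossible (we verified this by exhaustive
  search over the fixed-weight observer family).
* The cue weight is *reliability-scaled*: `w_cue/(|z| + κ)` grows as
  internal evidence weakens, implementing integration of external cues in
  inverse proportion to internal-evidence availability. The plain linear
  form is available via `cue_weighting = "fixed"`.
* Report = face iff `L ≥ 0` (ties → face, logged).
* Confidence reads out `C = |L| + w_conf · cue · sign(L)`: congruence of
  the cue with the emerging report boosts confidence, conflict dampens it
  (decision-congruent evidence weighting). Ratings 1–4 are `1 +` the number
  of thresholds `(θ1, θ2, θ3)` below `C`. With `w_conf = 0` this reduces to
  a pure `|L|` readout; that readout alone cannot jointly reproduce the
  four behavioural cells (informative/deceptive × overall/high-confidence)
  because it cannot raise confidence for cue-consistent reports without
  also raising it for cue-inconsistent ones.

Identifiability: from reports alone the model is known only up to scale, so
`fit_observer()` estimates `(w_int, w_cue, σ)` by maximum likelihood from
reports *and* confidences with the thresholds, `κ` and `w_conf` treated as
known; each (report, confidence) pair pins `L` into a signed interval and
the likelihood is a difference of normal CDFs.

## 6. Calibration of the frozen defaults

The published study reports behavioural outcomes, not generator parameters,
so the package's defaults were calibrated **once** during development and
then frozen; no test or acceptance threshold was adjusted afterwards.

* `noise_sd = 14.5`: grid search so that leave-one-trial-out decoding on a
  simulated 30-trial training phase (no switches, instructed attention)
  averages 78.3% over 20 seeds — the published decoder benchmark (78.1%).
* `q ~ Beta(1.3, 1)`, `switch_prob = 0.55`, introspection window 0.65 s:
  chosen so the main-phase joint distribution of (introspective evidence,
  decoded item) has both enough weak-evidence trials and enough
  strong-evidence decoder–introspection disagreements (late switches).
  `switch_prob` does not affect the training-phase benchmark above.
* Observer `w_int = 2.57`, `w_cue = 0.11`, `κ = 0.05`, `σ = 1`,
  `w_conf = 0.39`, thresholds `(0.54, 1.08, 1.83)`: fitted by random
  search + Nelder–Mead against the four published cell means (informative
  0.71, deceptive 0.57, informative-high 0.80, deceptive-high 0.46) using
  closed-form probit cell probabilities on a simulated evidence sample,
  then verified by full simulation.

The calibrated world reproduces, without being fitted to them, several
qualitative signatures: accuracy rising with IE percentile, the
confidence–accuracy inversion under deception, higher confidence for
confabulations than genuine introspection, and low-confidence deceptive
accuracy *above* low-confidence informative accuracy (a set-composition
effect: on deceptive trials strong-evidence reports are demoted to low
confidence by cue conflict; on informative trials they graduate to high).

## 7. Numerical and degenerate-input choices

* Exact decision ties → face; zero-variance reconstructions score 0; both
  logged via classed conditions (`cbl_tie`, `cbl_degenerate`).
* Consistency denominator floored at `1e-8` with a logged warning.
* Degenerate all-equal inputs to `quartile_bin()` go to quartile 1 with a
  warning; ties otherwise break by stable first-occurrence rank.
* The logistic fit is IRLS (tolerance 1e-8, ≤ 100 iterations); suspected
  separation (failed factorization or coefficients above 15) triggers a
  small ridge (`1e-4·n`, intercept unpenalized) and is flagged. The
  mixed-effects models of the original analysis are out of scope; the tidy
  per-trial CSV lets users refit them externally.
* Every random stage derives its seed from one global seed and a stage tag
  (`derive_seed()`), all below 2^31; reruns are byte-identical. Bulk noise
  uses an own xoshiro256++/polar-Gaussian C++ stream (base R's RNG is an
  order of magnitude too slow for 30 × 480 trials of 7 s × 64-channel ×
  2048 Hz data at desk scale); its seeds are explicit arguments.
* Schedules realize counts exactly (shuffled fixed counts, balanced within
  blocks of 160), not by per-trial coin flips, so 120 deceptive / 120
  informative reports hold in every session.

## 8. Known limitations

* The forward model is instantaneous linear mixing; the decoder's lags only
  help by filtering noise unless per-channel jitter is enabled.
* Calibration targets are across-participant means; the simulated
  between-participant variance comes only from mixing-vector geometry and
  trial sampling, and is somewhat smaller than in the real cohort.
* The observer's evidence is noise-free given `(q, trace)`; all report
  noise is lumped into `ε`. Confidence is a thresholded statistic, not a
  posterior probability (an alternative noted but not implemented).
* Only single mid-trial switches are generated by default; real attention
  presumably wanders more continuously.
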