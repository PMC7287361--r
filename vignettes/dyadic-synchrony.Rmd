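---
title: "Dyadic physiological synchrony and observational threat learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic physiological synchrony and observational threat learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyadsync)
```

## The scientific question

In observational threat conditioning, an *observer* watches a
*demonstrator* receive electric shocks paired with one of two images (the
CS+; the other image, the CS−, is never paired with shock). The observer
is later shown both images alone, under the belief that they will now
receive the shocks themselves. Larger skin conductance responses (SCRs)
to the CS+ than to the CS− in this testing phase — *CS differentiation* —
index socially acquired threat memory.

The hypothesis this package operationalises: the degree to which the
observer's and demonstrator's phasic electrodermal activity (EDA) become
*synchronised* during the learning phase predicts the strength of the
observer's CS differentiation afterwards. Synchrony is quantified by
cross-recurrence quantification analysis (CRQA) of the two phasic skin
conductance series, reduced to a single component by PCA, and related to
trial-level test responses with hierarchical regression. Specificity is
probed with a pseudo-dyad permutation test: re-pair observers with
demonstrators from *other* dyads and ask whether the effect survives.

Because the underlying human data are not deposited, the package is built
around a synthetic dyadic-EDA generator with a known ground-truth
coupling parameter, so that every stage — preprocessing, CRQA, PCA,
mixed-effects inference, permutation — can be exercised and validated
end to end.

## The experimental design encoded in the generator

One experiment has 69 same-sex dyads and 4 blocks. A block is:

* **Learning phase** — 6 CS+ and 6 CS− presentations, strictly
  alternating (first valence random), 6 s each, inter-trial intervals
  drawn uniformly from 10–16 s; 4 of the 6 CS+ presentations, chosen at
  random, co-terminate with a shock to the demonstrator.
* **Testing phase** — 7 presentations of each CS to the observer alone
  (alternating, first valence random); only the final CS+ presentation is
  shocked.

Roles reverse after block 2: the participant who observed in blocks 1–2
demonstrates in blocks 3–4. Each phase also begins with one lead-in
interval (drawn like an ITI) so that pre-stimulus baselines exist for the
first trial.

Strict alternation is an interpretive choice (the design description says
"alternating presentations" without stating whether alternation was
strict); it is implemented strictly and isolated in `make_schedule()`.

## The signal model

A participant's phasic EDA is modelled as a sum of:

1. **Event-locked SCRs.** Each CS onset and each shock elicits a response
   with the canonical Bateman shape — a peak-normalised difference of
   exponentials with rise constant 0.75 s, decay constant 2.5 s and 1 s
   latency — scaled by an event-type amplitude (shock 1.0 µS, CS+
   0.40 µS, CS− 0.35 µS) and a mean-one lognormal jitter (sdlog 0.4).
2. **Nonspecific SCRs** at 4 events/min, amplitude 0.25 µS.
3. **A slow arousal envelope** (smooth spline process, ~8 s knots) that
   multiplies response amplitudes (depth 0.5) and contributes an additive
   slow drive (SD 0.3 µS): the wandering background level of phasic
   sympathetic activity.
4. **Fast micro-fluctuations** (~0.3 s knots, SD 0.1 µS) — seconds-scale
   arousal transients.
5. **Gaussian measurement noise** (SD 0.005 µS).

Each participant additionally carries stable **individual traits**:
lognormal multipliers (sdlog 0.6) on event amplitude, slow-drive strength
and micro-fluctuation strength, and their own SCR shape constants
(lognormal jitter, sdlog 0.15, around the canonical values). These
create the between-person differences in signal character that real EDA
shows.

## The coupling model

The dyad's coupling strength `kappa` in [0, 1] (drawn uniformly per dyad
by default) controls how much of the observer's learning-phase activity
is inherited from the demonstrator:

* Each demonstrator response (CS-locked or nonspecific) is **mirrored**
  by the observer with probability `kappa` — same realised amplitude,
  delayed by 1 s, with Gaussian timing jitter of SD
  `(1 − kappa) × 2.5 s` — and is otherwise replaced by an independent
  response with the observer's own amplitude at a random time. The
  expected observer drive is therefore
  `kappa × demonstrator + (1 − kappa) × own`, while the event count and
  amplitude distribution are `kappa`-invariant.
* The slow envelope and micro-fluctuation drives mix as
  `kappa × demonstrator + sqrt(1 − kappa²) × own` (variance preserving).
* Responses to the social UCS (watching the demonstrator get shocked)
  are always time-locked — every observer reacts to a shock — with
  amplitude `0.6 × (kappa × demonstrator + (1 − kappa) × own)`.

At `kappa = 1` with shared kernels, zero lag and noise off, the observer
trace equals the demonstrator trace sample for sample; at `kappa = 0`
the learning-phase cross-correlation is near zero (the only shared events
are the four UCS responses).

**Threat learning.** The observer's testing-phase CS-onset response
amplitudes follow

```
a = beta0 + (beta_cs + gain * kappa) * cs_code * exp(-rho * (k - 1)) + e
```

with `cs_code = ±0.5` (deviation coded), `k` the within-CS presentation
number, `rho` the extinction rate (default 0.12/presentation, producing
the characteristic decline over unreinforced presentations), `beta0 =
0.4` µS, `beta_cs = 0.1` µS, and `e` a scaled mean-centred lognormal
(scale 0.15 µS); amplitudes are floored at 0. `gain` (default 0.5 µS per
unit kappa) is the ground-truth link between coupling and learning, so a
regression of generated CS differentiation on kappa recovers it — the
generator's parameter-recovery contract.

## Preprocessing

Learning-phase signals are reduced to 8 Hz by non-overlapping block
averaging (an anti-aliasing reduction, not decimation) and z-scored per
signal per phase. Trial responses are scored trough-to-peak: maximum in
0.5–4.5 s after onset minus the mean over the 1 s pre-onset baseline,
floored at zero, then `log(1 + x)` transformed. These windows and the
transform stand in for an unavailable original scoring protocol and are
conventional EDA practice; they are configurable in
`preprocess_config()`. Zero-variance traces raise an error rather than
silently scoring zero, so degenerate inputs are caught early.

## Cross-recurrence quantification

For each dyad-block learning phase:

1. **Delay** — smallest first local minimum of the average mutual
   information (histogram estimator, 10 equiprobable bins) over lags up
   to 40 samples, computed per signal; the dyad uses the maximum of the
   two. The AMI profile is 3-point smoothed first (fast micro-
   fluctuations otherwise plant shallow sub-sample dips that are not
   structural minima). For slowly drifting signals the profile often
   decays monotonically with no interior minimum; the fallback is then
   the standard 1/e-decay criterion (first lag with AMI below 1/e of its
   lag-zero value) rather than the profile's global minimum, which for a
   monotone profile degenerates to whatever the lag cap happens to be.
2. **Dimension** — smallest embedding dimension with a false-nearest-
   neighbour fraction ≤ 2% (Kennel criterion, inflation tolerance 10),
   up to 10; again the max over the two signals. One shared embedding
   must unfold both trajectories, hence the conservative max rule.
3. **Radius** — bisection between 0 and the maximum pairwise phase-space
   distance, targeting the midpoint of the 2–4% recurrence-rate band and
   stopping as soon as the achieved rate lies inside the band (≤ 60
   iterations). Pairs that cannot reach the band (e.g. constant signals)
   are excluded with a recorded reason.
4. **Metrics** — recurrence rate (RR), determinism (DET), laminarity
   (LAM), longest diagonal line (maxL) and the Shannon entropy of the
   diagonal line-length distribution (ENTR), with minimum counted line
   length 2 for DET/LAM/ENTR and any length for maxL. Euclidean norm in
   z-units; no Theiler window (the matrix compares two different
   people's signals, so near-zero index offsets are substantive).

The normalised entropy variant (ENTR divided by the log of the number of
distinct line lengths) is also computed and written out, but the
synchrony PCA uses the raw Shannon entropy: the normalising denominator
itself grows under strong coupling (long lines add distinct lengths),
which in synthetic data inverts the quantity's relation to coupling and
contradicts its intended reading as "complexity of the coupling".

All compiled kernels (distance matrices, line-run extraction, FNN,
bisection counting) are exact, and the line metrics are verified in the
test suite against a brute-force pure-R enumerator on hundreds of random
matrices.

## Synchrony component and alternative predictors

The four metrics (DET, LAM, maxL, ENTR) are pooled over all dyad-blocks,
standardised, and the first eigenvector of their correlation matrix gives
the synchrony component (PC1), sign-fixed so the loading sum is positive
and scores standardised. Three non-synchrony predictors are computed per
dyad-block from the same learning phases: the observer's mean UCS
response, the observer's learning-phase CS differentiation, and the best
time-lagged Pearson correlation between the two preprocessed series
(observer shifted later by 0–10 s; a maximum over lags, since the
original lag handling is unstated).

## Inference

Trial-level responses are modelled with lme4 (REML) as

```
amplitude_tx ~ cs_code * predictors + (1 + cs_code | observer_id)
```

with CS deviation coded ±0.5, continuous predictors standardised at fit
time, and a varying intercept and CS slope (with their correlation) per
observer. The returned contract is estimate, SE and Wald 95% interval
per fixed effect. The original analysis used Bayesian multilevel
regression; the restricted-likelihood backend returns the same contract
(point estimate, uncertainty, interval) and the package's inferential
weight rests on intervals plus the permutation test, not on Bayes
factors, whose prior specification is not reproducible from the
available description. The stability model adds CS×Block, CS×Role (both
±0.5) and CS×PC1×trial-number terms; the specificity model fits the four
predictors and their CS interactions jointly.

**Pseudo-dyad permutation.** Each permutation re-pairs every observer
with a demonstrator from a different dyad (random derangement of dyad
ids, block structure preserved), recomputes CRQA from scratch for every
pseudo-pair (radius recalibrated; per-signal delay/dimension selections
are cached, as they depend only on the individual signal), re-runs the
PCA and the trial-level model, and records the CS-by-synchrony estimate.
The p-value is add-one corrected: `(1 + #{null ≥ observed}) / (n + 1)`.

## Problem sizes used by the tests

The test suite exercises the full study design (69 dyads × 4 blocks) at
the 8 Hz analysis rate for the parameter-recovery and power checks, with
testing-phase redraws used for replicate simulations: the learning-phase
synchrony analysis is computed once and 50 conditional replicates redraw
only the response side (new trial noise, nonspecific activity and
measurement noise) under the strong-link and null-link scenarios. The
permutation checks run on reduced designs (69 dyads × 1 block with 3
presentations per CS for the active-coupling test; 10 dyads for the
calibration meta-replicates) so that CRQA can be recomputed for every
pseudo-pairing. Unit tests use miniature designs throughout.

## What the generator does and does not emulate

It emulates: the trial structure and timings; phasic event-related SCRs
with realistic kinetics and lognormal variability; nonspecific SCRs;
slow and fast shared arousal dynamics; individual differences in
amplitude, drive and response shape; vicarious UCS responses;
extinction across test presentations; and a tunable, recoverable link
from coupling to learning.

It does not emulate: tonic EDA or the raw-to-phasic decomposition,
movement artifacts, non-stationarity beyond the arousal envelope,
habituation of learning-phase responses, heart rate or any other
channel, or demographic structure.

## Known limitations

* **Line-ratio metrics are weakly sensitive to coupling in this signal
  family.** With the radius calibrated per pair to a fixed recurrence
  rate, DET and LAM behave as *intensive* properties of the two signals'
  processes: two smooth phasic-EDA-like signals produce high DET/LAM
  whether or not they are aligned, because chance co-dwelling in
  amplitude bands forms diagonal and vertical lines regardless. In the
  synthetic data the coupling signal is carried robustly by the
  *extensive* line statistics (maxL above all: its correlation with the
  generative coupling is ~0.5 across every configuration tested, and
  ~0.7 after log transform), while DET/LAM/ENTR carry correlations an
  order of magnitude smaller. The pooled first component consequently
  recovers the generative coupling only partially (typically r ≈ 0.1–0.3
  at the study size rather than comfortably above it), and downstream
  checks that condition on a strong synchrony-score–coupling link
  inherit this attenuation. With real data this limitation need not
  apply — between-dyad differences in signal character covary with
  coupling in humans — but conclusions from the synthetic pipeline about
  DET/LAM-borne effects should be read with this attenuation in mind.
* The embedding-parameter search is a major variance source: the
  selected delay/dimension pair explains most of the between-pair
  variance in DET/LAM/ENTR. The smoothed-AMI first-minimum rule with a
  1/e fallback (above) stabilises it considerably; it cannot remove the
  variance entirely.
* Wald intervals from REML fits are approximate; with 69–138 observers
  and 14 trials each they are accurate enough for the package's
  simulation checks, but a posterior-sampling backend would be the
  method of choice for final inference on real data.
* The permutation test recomputes CRQA per pseudo-pairing and is
  therefore expensive; at desk scale it runs on reduced designs, where
  the observed effect itself is small. Detecting real-pair specificity
  reliably requires the full design, which is computationally out of
  reach for a per-pairing recomputation at permutation counts in the
  hundreds.
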