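---
title: "Modelling passenger risk perception with hybrid Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling passenger risk perception with hybrid Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskbn)
```

## The scientific question

A passenger in an autonomous vehicle moving through a space shared with
pedestrians experiences risk through two channels: a deliberate,
reportable assessment (measured here with a continuous hand slider) and
an automatic physiological response (measured through electrodermal
activity, EDA). The analysis this package implements asks whether the
two channels are independent given the driving conditions, or whether
one drives the other. The driving conditions are two factors
manipulated per avoidance manoeuvre: the time-to-collision (TTC) when
the avoidance starts, and the lateral offset left between vehicle and
pedestrian at the closest point.

The question is cast as model selection over hybrid Bayesian networks
with four nodes — TTC, Offset, SA (a subjective indicator), SCR (an
electrodermal indicator) — where an edge between SA and SCR encodes a
dependence between the two risk-perception systems.

## The experimental plan and its synthetic twin

Each participant experiences 32 manoeuvres, 25 s apart. TTC has four
levels (2.0–3.5 s) and offset three (0.5–1.5 m), but only 8 of the 12
combinations are drivable in the simulator: the two smaller offsets are
only paired with the two larger TTCs. The offset 1.5 m row carries
frequency 0.5 and every observed cell frequency 0.125, so a 32-trial
session holds exactly 4 trials per cell of the restricted rows and 16
trials at offset 1.5 m. `build_design()` reproduces these counts
exactly and randomises trial order; walking direction and avoidance
side are balanced nuisance factors with no effect in the generative
model.

No human data is used anywhere: `make_ground_truth()` +
`simulate_indicators()` / `simulate_traces()` generate data with known
truth. The generator's defaults define the study conditions and were
fixed from the study's reported features before any testing:

* **SA cell means** follow the low/mid/high pattern of the study's
  condition analysis: 0.25 (slider units in [0, 1]) when TTC >= 3 s and
  offset >= 1 m, 0.45 when TTC = 2.5 s or offset = 0.5 m, 0.70 when
  TTC = 2 s; within-cell SD 0.15.
* **iSA** is the area of the trial's slider bump: peak times width,
  with 20% trial-to-trial width variability. Peak and area therefore
  share a trial's curve, as they do in the real instrument.
* **SCR events**: each manoeuvre's latent event count is Poisson with
  rate implied by a Tweedie law (`xi = 1.6`, `phi = 1.2`) whose mean is
  exponential in the trial's rated risk, `mu = exp(-5.66 + 8.3 mSA)`.
  The coefficients were solved, via the closed-form zero mass
  `exp(-mu^(2-xi)/(phi(2-xi)))`, so that the probability of a silent
  manoeuvre spans roughly 0.6 (calm trials) to 0.1 (critical trials)
  and averages about 46% — the zero share the study reports. `nSCR` is
  the matching gamma compound sum (hence marginally Tweedie); `mSCR`
  is the maximum of the per-event amplitudes, whose mean decreases with
  TTC (0.5 down to 0.2 uS across the four levels). Sharing the latent
  count enforces `nSCR = 0` iff `mSCR = 0`, the identity extraction
  produces. A consequence worth knowing: the amplitude indicator
  inherits the zero-mass dependence on SA, so on synthetic data the
  amplitude analyses may retain an SA edge where an analysis of the
  original recordings selected TTC alone.
* **Signals**: the 20 Hz slider trace is zero between manoeuvres with a
  piecewise-linear bump per manoeuvre (rise 3 s before the vehicle is
  level with the pedestrian, fall 2 s after; peak = the trial's mSA).
  The 625 Hz EDA trace is tonic level (random walk, 0.05 uS/min) +
  one Bateman response per event + white noise (SD 0.005 uS).

What the generator does **not** emulate: slider nonlinearities and
hesitations, motion or electrode artefacts, habituation across the
session, spontaneous (non-stimulus) SCRs, and inter-participant
differences in responsiveness beyond what per-participant scaling
removes. Passing tests therefore show the pipeline is correct and
well-calibrated under clean conditions, not that it is robust to every
artefact of real recordings.

## Signal processing and indicator extraction

Raw EDA is resampled to 78 Hz (linear interpolation), smoothed with a
1 s moving median (removes impulsive artefacts; reflection padding at
the edges) and low-passed at 1 Hz with a zero-phase 4th-order
Butterworth (applied forward and backward, so the designed magnitude
acts twice and no phase delay is introduced; the series is centred
first so the zero-state transient vanishes for constant signals).

The phasic/tonic split deconvolves against a Bateman impulse response
`exp(-t/tau2) - exp(-t/tau1)` normalised to unit peak (tau1 = 0.75 s,
tau2 = 2 s, standard electrodermal values; both configurable). The
tonic level is a smoothed rolling minimum; the residual is inverted by
non-negative least squares on the discretised convolution, yielding a
sparse driver of point masses (amplitudes, in uS). Numerical choices
that matter:

* the driver lives on a 10 Hz grid (0.1 s onset resolution) and is
  solved in 30 s chunks with a 10 s trailing overlap that is
  re-estimated by the next chunk — without the overlap, boundary
  columns absorb the leading edge of a response that onsets just past
  the chunk and create phantom detections at chunk boundaries;
* the deconvolution kernel is the Bateman response passed through the
  same zero-phase low-pass as the data. Zero-phase filtering spreads a
  rising edge backwards in time; deconvolving against the raw kernel
  systematically dates onsets ~0.25 s early, against the filtered
  kernel the bias is below the grid step;
* a response's onset is the mass-weighted time of its leading masses
  (the solution brackets a continuous onset between grid points), and
  its amplitude is its total driver mass — equal, for the unit-peak
  kernel, to the peak deflection of an isolated response. The peak of
  the reconvolved cluster is available as an alternative definition
  for overlapping responses.

Detection keeps clusters of driver mass above a 0.005 uS residue floor,
merges gaps under 0.4 s (responses 1 s apart stay separate), and
retains events above the 0.05 uS amplitude threshold. On the synthetic
benchmark (events >= 0.1 uS, noise SD 0.01 uS) recall and precision
both exceed 95%.

Indicators per manoeuvre: `mSA` is the slider maximum and `iSA` the
trapezoidal area over the manoeuvre's window (the positive excursion
bracketing the moment the vehicle is level with the pedestrian,
including its bounding zeros, so the quadrature closes); an SCR belongs
to a manoeuvre when its onset falls in `[t_level - w_start,
t_level + w_end)` — closed left, open right, a convention the data
source leaves open. `w_start` is the participant's mean slider
anticipation over responsive manoeuvres (silent manoeuvres carry no
defined delay and are excluded rather than averaged as zero);
`w_end = 3` s from the electrodermal literature.

## Normalisation

Subjective indicators are right-skewed; a square root (mSA) and cube
root (iSA) symmetrise them, after which values are centred and scaled
within participant to make distributions comparable across
participants. With 20 participants of 32 trials, per-participant
z-scoring forces the pooled unbiased SD of all 640 values to
`sqrt(620/639) = 0.98502` — printed as 0.985 — *whatever the data*; the
package uses the unbiased (n-1) estimator throughout, which is what
makes this identity hold. SCR indicators are scaled per participant but
never centred: centring would destroy the exact zeros that the Tweedie
node models. Note that on synthetic data the pooled transformed
indicator is a three-component mixture (one per condition band) and the
fixed exponents — chosen for the real recordings — slightly overcorrect
the generator's milder skew, so the transformed indicators come out
roughly symmetric with a high but not near-1 Shapiro–Wilk statistic.
The Gaussian node models conditional (within-cell) distributions, which
the generator makes exactly Gaussian, so this pooled-shape mismatch
does not touch the network scoring.

## The Tweedie compound-Poisson engine

About 46% of manoeuvres produce no SCR, so the SCR node needs a
distribution that is continuous on the positive axis with an atom at
zero. A Tweedie exponential-dispersion model with index `xi` in (1, 2)
is exactly that: a Poisson(`lambda`) number of gamma summands with
`lambda = mu^(2-xi)/(phi(2-xi))`, shape `(2-xi)/(xi-1)` and scale
`phi(xi-1)mu^(xi-1)`; variance `phi mu^xi`; `P(Y=0) = exp(-lambda)`.

The log-density for `y > 0` is an infinite series over the latent
count. It is evaluated directly as `sum_N Poisson(N) Gamma(y; ...)` on
a window of `N` centred at the dominating index
(`~ y^(2-xi)/(phi(2-xi))`), widened until the boundary terms fall
`1e-12` below the running log-sum (the series starts at `N = 1`, where
a dominant first term is legitimate). The suite cross-checks the
series against an independent implementation (`mgcv::ldTweedie`) to
`1e-10` and verifies normalisation by quadrature on a 27-point
parameter grid.

The GLM uses a log link: `beta` by iteratively reweighted least squares
(weights `mu^(2-xi)`, independent of `phi`), then `phi` by 1-D profile
maximum likelihood (not a moment estimator, so node log-likelihoods are
exact and BIC-coherent), then `xi` by profile likelihood over a grid in
(1.05, 1.95) with golden-section refinement. Standard errors come from
the weighted Fisher information at the optimum. The BIC parameter count
for a Tweedie node is `length(beta) + 2` — dispersion and index
parameter are counted as estimated; the count is visible in the fit
object for anyone preferring a different accounting. For the large
replicate studies (structure recovery) a coarse three-point `xi` grid
without refinement is used: all 48 candidates are treated identically
and the BIC ordering is insensitive to the residual `xi`
discretisation, while fits stay ~5x cheaper.

## Network scoring

Candidate structures vary the factor parents of SA (any subset of
{TTC, Offset}), the factor parents of SCR, and the inter-indicator edge
(none, SA to SCR, SCR to SA): 4 x 4 x 3 = 48 acyclic DAGs, of which 16
carry no SA–SCR edge. Factors are roots with distributions fixed at the
design frequencies — zero free parameters and a constant
log-likelihood, included so totals are absolute (the two factors are
dependent by design, since four cells are undrivable; with no edge
allowed between roots each factor carries its marginal frequencies, and
this constant cancels in every comparison). Node families:

* Gaussian SA with factor parents: one mean and one SD per *observed*
  parent cell (`2 x cells` parameters); unobserved factor combinations
  are skipped, never imputed.
* Tweedie SCR with factor parents: log-link cell means with shared
  `phi` and `xi` (per-cell dispersions are not identifiable at 80
  trials per cell).
* A continuous parent adds exactly one common slope on top of the
  per-cell intercepts (and, for Gaussian, per-cell variances), fitted
  by iteratively reweighted least squares. Making the continuous parent
  a strict one-parameter extension is essential: an additive
  pooled-variance regression can *undercut* the per-cell factor model's
  parameter count, and the BIC then prefers a spurious SA–SCR edge on
  independent data purely through parsimony of the additive form.

Each node contributes `-2 loglik + p log(n)`; by the factorisation of a
Bayesian network's joint likelihood the node sum equals the monolithic
criterion, which the tests verify to `1e-8` by recomputing the joint
log-likelihood row by row from the fitted parameters. Ranking uses the
Raftery thresholds (2/6/10); everything within 2 of the best is
reported as indistinguishable. Exact ties order by the structure label
for determinism. At four nodes exhaustive scoring is trivial (16
distinct node fits serve all 48 structures via a cache), so no greedy
search is needed.

Structure recovery under the study conditions (20 x 32 rows, generative
structure: SA Gaussian on both factors, SCR Tweedie on SA): the true
structure is within the indistinguishability band of the winner in 50
of 50 replicates, and under independent generation the winner carries
no SA–SCR edge in 50 of 50.

## Condition clustering

Whether the 8 observed conditions induce genuinely different indicator
distributions is answered exhaustively: all 4140 set partitions (Bell
number of 8, enumerated as restricted growth strings) are scored as
Gaussian block models. Each block carries its own mean and SD
(`2 x blocks` parameters) — a grouping claims the conditions in a block
share a *distribution*, not merely a location. The pooled-SD variant
(`blocks + 1` parameters) is available behind a flag but is not the
default: with 4139 competing partitions and only `log(n)` per extra
mean, the pooled variant's selection noise picks a spurious split on
null data almost half the time, while the per-block model with
selection of the most parsimonious partition within the
positive-evidence band (gap < 2) keeps the null single-block rate at
~95% and recovers well-separated groupings exactly. Blocks are labelled
low/mid/high by ascending mean. Scoring all 4140 partitions uses
per-condition sufficient statistics (counts, sums, sums of squares), so
a full sweep is milliseconds.

## Reproducibility and problem sizes

Every stochastic step is seeded; seeds derive from a single master so
the pipeline, the tests and the acceptance script are bit-reproducible.
The replicate studies run at the study's own size (640 rows); the
signal-chain tests use sessions of 8–10 manoeuvres and a 420 s
detection benchmark with 32 events, sizes at which the deconvolution
(the only expensive step, ~10 s per 400 s of signal) stays comfortable
on one core. Known limitations: the deconvolution is a simplified
stand-in for full continuous decomposition analysis (fixed kernel, no
optimisation of its time constants); the per-event amplitude definition
for heavily overlapping SCRs is a convention (driver mass by default);
and the generator's clean-signal assumptions listed above bound what
green tests can claim about real recordings.
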