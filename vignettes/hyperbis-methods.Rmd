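---
title: "Inter-brain bispectral synchrony: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-brain bispectral synchrony: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
# Code chunks are shown for exposition and not evaluated when building:
# every empirical statement in this document is computed by the test suite
# (tests/testthat/) or by scripts/acceptance.R.
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hyperscanning records EEG simultaneously from several interacting people —
here, the emulated setting is three musicians improvising together on stage,
joining one at a time so that every pair (dyad) of participants passes
through *passive-passive*, *passive-active* and *active-active* performance
conditions. The scientific question is whether, and where on the scalp, the
participants' brain signals become synchronized, and how that synchrony
behaves around annotated moments of synchronized (SP) and desynchronized
(DP) performance.

`hyperbis` quantifies inter-brain synchrony with the **diagonal
cross-bispectrum**, a third-order spectral statistic. For two channels — one
from participant $a$, one from participant $b$ — windowed into $L$
four-second segments with spectra $X_l(f)$, the estimator is

$$
B(f) \;=\; \Bigl|\tfrac{1}{L}\sum_{l=1}^{L}
X_{a,l}(f)\, X_{b,l}(f)\, X^{*}_{b,l}(2f)\Bigr|,
\qquad f = 1.00, 1.25, \dots, 50.00\ \mathrm{Hz}.
$$

The bispectrum detects **quadratic phase coupling**: if the phase at $2f$
equals twice the phase at $f$, the summands share a common phase
($\varphi + \varphi - 2\varphi = 0$) and accumulate coherently across
windows, while for jointly Gaussian (hence phase-incoherent) signals the sum
vanishes as $1/\sqrt{L}$. Both properties are verified by the test suite
(triple-product oracle to $10^{-10}$ relative; log–log decay slope
$-0.5 \pm 0.1$ over $L \in \{10, 100, 1000\}$).

### The factor-assignment convention

The defining sum does not dictate which participant contributes which
factor. We fix: participant $a$ contributes the single factor at $f$,
participant $b$ the factor at $f$ and the conjugated factor at $2f$ — one
factor for the "sender", the nonlinear closure on the "receiver". Two
consequences are deliberate, documented and tested:

* the statistic is **asymmetric**: $B_{a \to b} \ne B_{b \to a}$, and the
  discovery scan therefore runs over *ordered* channel combinations;
* scaling $a$'s channel by $\alpha$ scales $B$ by $\alpha$, scaling $b$'s by
  $\beta$ scales it by $\beta^2$.

The alternative closure (on participant $a$) is a one-line change and could
give different channel rankings; nothing in the estimator prefers one
reading, so the choice is declared rather than inferred.

## Normalization, bands, grids

Segment representations average the windowed products over all four-second
windows of a five-minute segment (division by $L$, so intervals of different
lengths are comparable). They are normalized to the pre-trial eyes-open
(EO) rest block of the same channel combination:

$$
BS_N = \frac{BS_{Seg} - BS_{EO}}{BS_{EO}},
$$

a dimensionless relative change (0 when segment equals rest; 0.3 when the
segment runs 30% above rest). Bins whose baseline magnitude falls below
$10^{-12}\times$ the median baseline are flagged invalid rather than
divided.

Windows are 4 s long, advanced in 1-s steps (75% overlap), rectangular
(no taper — the literal reading of the defining sum; a taper would trade
leakage against main-lobe width and is intentionally not applied). At
250 Hz this gives 0.25 Hz native resolution and 197 diagonal bins from 1 to
50 Hz. Canonical bands are collected over fixed half-open sampling
intervals:

| band  | nominal (Hz) | sampling interval | native bins |
|-------|--------------|-------------------|-------------|
| delta | 1–4          | [1, 5)            | 16          |
| theta | 4–7          | [4, 8)            | 16          |
| alpha | 8–12         | [8, 13)           | 20          |
| beta  | 13–29        | [13, 30)          | 68          |
| gamma | 30–50        | [29.75, 50.25)    | 82          |

These are the unique half-open readings that produce the per-band sample
counts 16/16/20/68/82 on the native grid; the implied delta/theta and
beta/gamma edge overlaps are accepted as part of that definition. A 50-bin
1-Hz summary grid (bin $k$ averages native bins with $\lfloor f\rfloor =
k$) is provided for display.

## Statistical discovery

For each (trial, segment, dyad, band) family, one right-tailed Wilcoxon
signed-rank test per ordered channel combination compares the segment's
per-bin band values against the rest baseline's, paired by bin. The
Bonferroni family is the set of combinations within one family —
$60^2 = 3600$ at the full montage, $\alpha_{corr} = 0.05/3600$ — matching a
per-segment scan correction; over 3 trials × 3 segments × 3 dyads × 5
bands the design totals 486 000 tests. Zero differences are dropped per the
standard signed-rank convention; an all-zero comparison returns $p = 1$
with a degeneracy flag. The normal approximation with continuity
correction is used (band sizes 16–82).

Which 4 of the 64 recorded cap channels are excluded from analysis is a
montage-dialect question: here `TP9`, `TP10`, `PO9`, `PO10` are repurposed
as EOG electrodes (kinds are carried as metadata, never inferred from
labels), leaving 60 scalp analysis channels. The exclusion set is
configuration, not hard-coded.

## Event-locked analysis

Temporal traces take one value per sliding window: the single-window
($L = 1$) representation, normalized to rest, band-averaged. Around each
annotated SP/DP event, a −60…+60 s trace (121 points at the 1-s window
step) is cut with the annotation at 0 s, and the mean over [−60, 0) is
subtracted (baseline correction; idempotent by construction). SP and DP
groups are compared per timepoint.

Two deliberate deviations from a literal reading of the source procedure:

* the SP-vs-DP comparison uses an **unpaired rank-sum test**: the two
  groups have different sizes by construction, so a signed-rank (paired)
  test is not defined for them;
* "earliest significant timepoint" is operationalized as the onset of the
  earliest run of **at least 5 consecutive** pointwise-significant seconds.
  With pointwise $\alpha = 0.05$ over 121 timepoints, isolated false
  positives are near-certain under any effect size, and the 4-s analysis
  window correlates neighboring points; a sustained run at the smoothing
  scale plus one separates a genuine onset from that noise. The value 5 was
  fixed from the smoothing scale before any recovery experiment was run.

No correction across the 121 timepoints is applied (the pointwise reading);
a cluster-extent option exists but defaults off.

## Regions of interest

Thirteen scalp regions (AF, LFC, MFC, RFC, LCP, MCP, RCP, LPO, MPO, RPO,
LT, RT, O) partition the 60 analysis channels by geometric sector; the
membership table ships as an editable CSV
(`extdata/roi_membership.csv`) because no published per-electrode listing
was available to copy — the default is a reproducible, overridable choice.
Significant combinations increment region-pair cells (undirected pooling;
within-region on the diagonal); shading is count over maximum count, and
cell sums equal the number of aggregated combinations by construction.

## The synthetic session generator

No public ground-truth hyperscanning corpus exists at desk scale, so the
generator is first-class, tested code. It emulates the study design: pre
and post EO/EC baselines (60 s each), three trials of three five-minute
segments with rotating staggered entry, annotations in the trial-anchored
`mm:ss` dialect, and a missing-data mask facility.

Signals are built from three layers:

1. **Background**: independent $1/f$ noise per channel (spectral shaping of
   white Gaussian noise), 20 µV SD — the test suite checks the log–log
   periodogram slope.
2. **Ocular artifacts** (optional): Poisson-scheduled ~300 ms biphasic
   blink templates on the EOG channels, mixed into EEG channels through a
   frontal-weighted vector; the mixing is returned as ground truth so the
   H∞ stage can be scored against it.
3. **Coupling**: quadratic phase coupling between one channel of each dyad
   member. Per ~4 s epoch, a carrier phase $\varphi_l$ is drawn; the
   sender receives $\cos(2\pi f_0 t + \varphi_l)$, the receiver the same
   carrier plus its harmonic at $2 f_0$ with phase $2\varphi_l$. The
   coherent pair is mixed with amplitude-matched incoherent copies as
   $\rho \cdot \text{coh} + \sqrt{1-\rho^2} \cdot \text{inc}$ — the
   power-complement weights keep injected variance independent of $\rho$,
   so the bispectrum's $\rho^2$ coherent term is the only
   $\rho$-dependence and the mean response is monotone in $\rho$ (a
   $(1-\rho)$ control weight, though superficially natural, makes injected
   power dip at mid-$\rho$ and breaks monotonicity).

With `bandwidth > 0` the single carrier becomes a **comb** of all 0.25-Hz
grid carriers within $f_0 \pm \text{bandwidth}/2$, each at amplitude
$\text{amp}/\sqrt{n_\text{carriers}}$ with its own epoch phase. This is
what makes *band-level* detection testable: a pure tone excites exactly one
native bin out of 82, which a rank test across bins cannot see, and a
single randomly-jittered carrier leaves most band bins unexcited at
desk-scale window counts.

Component amplitude defaults to 6.3 µV per sinusoid against the 20 µV
background — injected variance at most 10% of background variance, a
realistic artifact-free SNR ceiling. Since no published coupling magnitudes
exist, the calibration of $\rho$ against the observed 0–0.3 normalized
range is heuristic and documented as such.

**SP/DP events** step $\rho$ by a configurable delta beginning
`lead_time_s` (default 3 s) *before* the annotated time — emulating
anticipatory coupling — and simultaneously scale the injected component
amplitude by $(1 + \Delta\rho)$. The amplitude component of the event
signature is a considered deviation from a pure-$\rho$ step: the $L = 1$
temporal estimator is a product of spectral *magnitudes* and is provably
blind to phase coherence alone (for the power-matched mixture,
$\mathbb{E}\lvert\rho + (1-\rho)e^{i\theta}\rvert$ is not even monotone in
$\rho$), so a pure coherence step produces no trace response at any effect
size. Amplitude is the physical signature the temporal trace detects; the
$\rho$ step remains what the segment-level statistics detect.

## Preprocessing

Fixed order, logged in the session provenance: resample → bandpass →
line-noise removal → robust average reference → H∞ ocular cancellation.
The order (filtering after resampling) and zero-phase filtering (which a
causal filter would break the −3 s anticipatory timing analysis) are
declared choices.

* **Resampling**: zero-phase Butterworth anti-alias at 80% of the target
  Nyquist, integer-factor decimation (1000 → 250 Hz).
* **Bandpass** 0.1–100 Hz: cascade of a 4th-order high-pass and 4th-order
  low-pass, each applied forward–backward. A direct 8-pole bandpass with a
  normalized cutoff of $10^{-4}$ is numerically unstable in double
  precision, which is why the edges are realized separately.
* **Line noise**: per-chunk (4 s) least-squares regression of sine/cosine
  pairs at the line frequency and harmonics, subtracted — ≥ 20 dB notch
  with neighbors (±2 Hz) changed < 5%. This replaces a published
  multi-stage cleaning pipeline that is out of scope here.
* **Reference**: per-sample *median* across EEG channels — an
  approximation to a robust "true" average reference; EOG channels are
  excluded.
* **H∞ adaptive noise cancelling**: per EEG channel, a weight vector over
  [EOG references + constant bias] follows the time-varying H∞ recursion
  (γ = 1.15 bounds worst-case error-energy amplification; q = 10⁻¹⁰ lets
  weights drift). The Riccati update depends only on the references, so
  gains are computed once and shared across channels. Admissibility
  ($P^{-1} - \gamma^{-2} r r^\top \succ 0$) is checked each sample via the
  rank-one condition and violation aborts naming the first failing sample.
  Numerical choices: initial covariance $p_0 = 10^{-5}$ (large enough to
  converge within seconds, small enough to remain admissible at blink
  amplitudes), and the constant regressor is scaled to the median absolute
  reference amplitude so its effective learning rate matches the EOG terms
  (pure conditioning; the fitted offset is scale × weight). On synthetic
  ground truth the stage removes ≥ 90% of post-convergence blink-band
  power while retaining a co-present 10 Hz rhythm within 5%.

Bad-channel interpolation, artifact-subspace reconstruction (ASR, typical
κ = 15) and ICA component rejection are intentionally *not* implemented:
they are established external tools. Run them outside and ingest the
result, then skip the overlapping stages (`hinf = NULL`).

## Problem sizes used by tests and the acceptance script

Full-scale sessions (3 × 64 channels at 1000 Hz for ~50 min) are the
generator's defaults but are not what the automated checks run; the checks
use reduced problem sizes chosen once:

* **Detection power**: 2 participants, the 16-channel desk montage,
  one 60-s active-active segment, coupling $\rho = 0.8$ on 5 known channel
  pairs (35 ± 5 Hz comb). The 60-s segment matches the rest block's window
  count ($L = 57$ both): the $\lvert\text{complex mean}\rvert$ estimator's
  null floor scales as $1/\sqrt{L}$, so comparing a 300-s segment against a
  60-s baseline is conservatively biased (segment floor *below* rest
  floor). That bias is a real property of the full-scale design and is
  inherited by any study comparing unequal-length intervals with this
  estimator; matched lengths isolate the coupling effect.
* **Null calibration**: same layout, $\rho = 0$ everywhere (no injection at
  all), 20 seeds, gamma family: family-wise rejections are counted per
  seed and pooled.
* **Event recovery**: 2 participants, 4 channels, one ~21-min
  active-active segment with 16 SP and 12 DP events 45 s apart, base
  $\rho = 0.1$, SP $+0.7$, DP $-0.1$, lead 3 s.
* **Monotonicity**: 100 realizations per $\rho$ level of 256 aligned 1-s
  windows — the mean response is provably non-monotone near $\rho = 0$
  when $L \lesssim 130$ (the incoherent floor term $(1-\rho^2)/L$ initially
  falls faster than $\rho^4$ grows), so the property is tested at a window
  count where the expectation is monotone.

## What passing tests do and do not show

The generator produces stationary $1/f$ noise with additive sinusoidal
coupling and stereotyped blinks. Real EEG adds non-stationary rhythms,
1/f-slope drift, muscle and movement artifacts, volume conduction between
nearby electrodes, and genuinely shared acoustic stimulation — none of
which are modeled (volume conduction and audio are explicit non-goals).
Passing the recovery suites therefore shows that the *estimators and
decision procedures* behave as designed on signals with known ground
truth; it does not certify sensitivity or specificity on real recordings.

Known limitations worth stating plainly:

* $\lvert B\rvert$ is unnormalized (no bicoherence): a channel that
  genuinely carries $f$ + $2f$ harmonic structure elevates *every*
  combination it enters as receiver, so power and coupling are partially
  confounded. In the detection scenario this surfaces as extra significant
  combinations sharing a planted receiver channel. Bicoherence
  normalization is a non-goal by design.
* The diagonal restriction sees only $f$-with-$2f$ coupling; off-diagonal
  bifrequency structure is invisible.
* The $L = 1$ temporal trace is a magnitude product and cannot separate
  phase-coherence changes from power changes (see the event-signature
  discussion above).
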