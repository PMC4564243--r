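---
title: "Methods: synthesis, measurement and categorisation of killer whale calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesis, measurement and categorisation of killer whale calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcacall)
```

# The analysis problem

Delphinid repertoire studies describe three sound classes. *Whistles* are
continuous frequency-modulated tonal sounds: a fundamental contour, sometimes
with harmonic overtones at integer multiples of it. *Burst-pulse sounds* are
trains of rapidly repeated broadband pulses; on a spectrogram they appear as a
contour with many evenly spaced sidebands, whose spacing equals the pulse
repetition rate. *Clicks* are sub-millisecond broadband echolocation pulses,
emitted in trains that can accelerate into a buzz. Some calls mix the first
two classes: whistles pulsed only in the middle, and calls whose first half is
pulsed and second half tonal (or vice versa).

The quantitative workflow is: compute spectrograms, trace each call's
fundamental (or lowest strong) contour, measure a fixed set of parameters per
call, assemble the parameters into feature vectors, and categorise calls into
types by k-means. This package implements that workflow end to end, together
with a synthetic-signal module that generates each sound class with known
ground truth, so every stage is testable without access to field recordings.

# Signal models in the synthesis module

**Whistles** are generated by phase integration: given an instantaneous
frequency contour $f(t)$ (piecewise-linear or cubic breakpoint
interpolation), the signal is $\sin\!\big(2\pi \int_0^t f(\tau)\,d\tau\big)$.
Integrating the phase avoids the discontinuities that concatenated tone
segments would introduce, so the synthesized instantaneous frequency is exactly
the contour — the property the recovery tests rely on. Harmonic $m$ (the
$(m-1)$-th overtone) is added at $m f(t)$, attenuated by
$(m-1)\times$ `harmonic_rolloff` dB.

**Burst-pulse sounds** are a tonal carrier at the call's contour, amplitude
modulated by a rectangular pulse train at rate $r$. This is the minimal
generator with the defining spectrographic structure: sidebands at
$f_0 \pm k r$, i.e. spacing equal to the pulse repetition rate. The default
duty cycle is 0.3: with duty $d$, sideband $k$ lies
$20 \log_{10} |\operatorname{sinc}(k d)|$ dB below the carrier, and at
$d = 0.5$ every even-order sideband vanishes, which would make the measured
*adjacent*-sideband spacing read $1.5r$ rather than $r$ and is also not what
the dense-sideband spectrograms of real burst-pulses look like. At $d = 0.3$
the first three orders sit at roughly $-1$, $-6$ and $-19$ dB, giving the
dense flanking contours the class is defined by, while the carrier remains
the strongest ridge. Restricting the modulation to a time window produces
pulsed-middle calls (middle third) and transitions (one half).

**Clicks** are Gabor pulses — Gaussian-windowed cosines — with negative
polarity by default, matching the reported on-axis click waveform.
`click_duration` is defined as the −3 dB width of the envelope
($1.66\,\sigma$). Trains place clicks at a constant inter-click interval
(ICI) or a geometrically shrinking one (a train speeding up into a buzz), and
an optional reflection appends an attenuated copy of each click at a fixed
delay.

**Noise.** `add_noise()` adds white Gaussian noise scaled so that the
signal-to-noise ratio *integrated over the call's frequency band* equals the
requested value; out-of-band noise is present as in a real recording. All
generators are deterministic given (spec, sample rate, seed), and seeding
never touches the global RNG state.

The default synthesis rate is 96 kHz, the primary recorder rate in the study
conditions this package emulates; 192 kHz input is equally supported. No
absolute sound-pressure calibration is modelled — synthesized amplitudes are
normalized, spectrogram power is relative to its maximum, and no
level-dependent behaviour is claimed anywhere.

# Spectrograms

`compute_spectrogram()` uses a Hamming window with 50% overlap (both fixed
conventions of the workflow this package reproduces), no zero padding, no
detrending. Frame $k$ (0-based) covers samples $[k h, k h + N)$ with
$h = N(1-\text{overlap})$, and carries the time stamp of its window *centre*
— so a call's measured duration equals the first-to-last frame-centre
difference, biased by at most one hop against the true duration. The default
$N = 512$ at 96 kHz (187.5 Hz bins, 2.67 ms hop) follows the most common
parameterization in the source material; published figures also used 700,
1024, 1600 and 3200 with no stated selection rule, so $N$ is plain
configuration here. Power is kept both linearly (for SNR arithmetic) and in
dB re the spectrogram maximum (for thresholding and display).

# Contour extraction

The tracker implements ridge following with explicit, conventional choices
(the original analysis traced contours in interactive software without
documenting an algorithm, so this component is a reconstruction and only
range-level agreement with published measurements is ever claimed):

- *Candidate peaks* per frame are local spectral maxima at least 6 dB above
  the frame's noise floor, defined as the median level of the frame — a
  conventional margin consistent with keeping only calls of good SNR.
  Candidates must also lie within 25 dB of the frame maximum
  (`dyn_range_db`): in a clean recording the Hamming sidelobes of a strong
  tone exceed the noise floor, and the dynamic-range gate is what rejects
  them.
- *Continuity*: from the most prominent candidate, the ridge is extended
  frame by frame, allowing at most 3 bins of jump; up to 2 consecutive
  frames without a qualifying candidate are bridged by linear interpolation
  (counted in `gaps_bridged`). Whistles are continuous by definition, so
  longer gaps terminate the ridge.
- *Stickiness*: among admissible candidates the tracker maximises level minus
  3 dB per bin of jump. Burst-pulse first-order sidebands can sit within
  ~1 dB of the carrier; without the penalty the ridge occasionally hops
  carrier → sideband → carrier, which fabricates slope reversals.
- *Persistence*: a finished ridge is kept only if it spans at least 0.04 s
  (just under the shortest published call duration, 0.05 s) and its median
  prominence exceeds the threshold by 3 dB. Chains of marginal noise peaks
  hover just above the 6 dB acceptance line, while genuine ridges in this
  package's test conditions sit 15–30 dB above it; the persistence rule is
  what makes pure noise yield an *empty trace* rather than a spurious call.
- Peak frequencies are refined by parabolic interpolation of the dB spectrum
  (standard quadratic peak interpolation), reducing bin quantization to a
  small fraction of a bin; this matters for stable slope estimates
  downstream.

Harmonic overtones are declared at multiple $m$ when the spectrum within ±3%
of $m f_0$ (bin quantization at small NFFT motivates the tolerance) clears
the detection margin in at least half the frames. Sidebands are distinguished
from harmonics by the integer-multiple test: a parallel contour at $g$ is
harmonic when $g/f_0$ is within tolerance of an integer, and pulsed structure
requires at least two parallel *non-harmonic* contours in a frame. Sideband
spacing is the median over frames of the median adjacent-peak difference
among those parallel contours, and is *absent* — never zero — for tonal
calls.

Call classes are assigned from the per-frame pulsed/tonal pattern: whistle
below 20% pulsed frames, burst-pulse above 80%, pulsed-middle when the pulsed
run is confined to the middle third with tonal ends, transition when one half
is pulsed and the other tonal. The published study classified calls visually;
these thresholds are this package's operational definition, stated here
because they are design choices, not reproductions.

# The ten parameters

Counting extrema and inflections on a sampled, estimated contour needs two
defences against spurious sign changes, and both are explicit parameters:

- The trace is median-filtered then moving-averaged (5 frames each by
  default) before measurement.
- Extrema are counted by hysteresis: a reversal counts only if the excursion
  reaches the prominence threshold (default 2 frequency bins) on both sides.
  Endpoints are never counted, since the slope is undefined at the
  boundaries. Inflections apply the same hysteresis to the slope sequence
  (median-filtered over 5 frames; frame-to-frame estimation jitter otherwise
  survives plain hysteresis), with the slope threshold expressed as the
  prominence over a 50 ms horizon.
- Published counts follow the pattern inflections ≈ extrema − 1, which is
  also a theorem for smooth contours: between two consecutive extrema the
  slope crosses zero through a local extremum, so the curvature changes sign
  at least once. The reported inflection count is therefore
  $\max(\text{counted}, n_\text{extrema} - 1)$ — the bound is enforced
  mathematically rather than left to threshold behaviour.

The identities $\Delta f = \text{Max} f - \text{Min} f$ and
$\text{FM rate} = n_\text{inflections} / \text{duration}$ hold *exactly* in
every output row, by construction. For pulsed-middle and transition calls the
frequency extremes are measured off the tonal (whistle) frames, duration and
counts off the entire call, and sideband spacing off the pulsed section only
— the convention the published tables state for those call types. One
consequence, visible in the published BC08 row (start frequencies above the
fundamental's maximum), is that $\text{Min} f \le \text{Start} f \le
\text{Max} f$ need not hold for those classes; the package's range-validation
test therefore skips start/end containment for BC08.

# Click statistics

Detection band-passes (Butterworth order 4, default 5–40 kHz, bracketing the
reported 12–24 kHz click peak-energy band), rectifies, smooths over 0.2 ms,
and thresholds at the envelope median plus 8 MADs with a 5%-of-maximum floor
— making detection invariant to overall amplitude and inert on noise-only
input. A 2 ms filter-settling margin at each end is excluded. Candidate peaks
closer than a third of the refractory window are merged; a weaker candidate
within the refractory window (default 1 ms) of a stronger one is attributed
as that click's *reflection*, not a click. The 1 ms default sits between the
reported reflection delays (0.4–0.5 ms) and the reported buzz ICI (2.5 ms),
so buzz clicks separate while reflections fold into their parents. Where the
source material's body text and figure captions disagree (buzz ICI 2.5 vs
2 ms; reflection delay 0.5 vs 0.4 ms; peak band 12–24 vs 12–23 kHz), the
body-text values are used as defaults throughout and no claim is made about
which measurement is correct. Click duration is the −3 dB width of the
analytic (Hilbert) envelope around each detected peak; the spectral peak is
the argmax of a 2 ms Hamming-windowed spectrum, in-band.

# Categorisation

Feature vectors contain the ten parameters plus the harmonic flag (0/1),
sideband spacing with absent → 0, and a pulsed-class indicator (0/1). The
published analysis states only that the measured parameters "made up a
feature vector"; the two indicator encodings and the absent → 0 rule are this
package's choices, as is z-scoring every column before clustering — without
standardization, kHz-scale features would dominate the counts, so raw-unit
clustering is documented as a known deviation risk rather than offered as a
default. Constant columns are dropped with a warning.

The k-means implementation is Lloyd's algorithm with k-means++
initialization, best-of-restarts by within-cluster sum of squares, ties in
nearest-centroid assignment broken toward the lowest centroid index, and
empty clusters repaired by reassigning the point farthest from its centroid.
Rows are canonically sorted before any seeded draw, making results invariant
to input row order under the same seed. Within-SS is recorded per iteration
and is non-increasing — asserted in tests, along with exact agreement with an
exhaustive-bipartition oracle on all small instances and with an independent
k-means implementation on separated data.

Both modes of choosing the number of call types are supported, because the
original workflow does not state whether nine groups were fixed a priori or
validated: fixed `k` (default 9) and silhouette selection (`select_k()`,
mean silhouette width under Euclidean distance, ties to the smaller k).

`sample_feature_vectors()` draws labelled vectors per call type from
independent truncated Gaussians centred at each parameter's published range
midpoint with sd = `spread` × range width. Midpoint-centred (rather than
uniform) sampling reflects that published ranges are extremes over few calls;
uniform draws would overlap neighbouring types far more than the real calls
do. The harmonic flag is set per class (overtones are described for the
whistle, pulsed-middle and transition types, not the plain burst-pulses).
Because parameters are drawn independently, sampled vectors need not satisfy
the within-call identities (e.g. delta = max − min); they emulate
feature-space geometry for clustering studies, not physical calls — the
group-call generator below is the physical emulation.

# The group-call generator

`synth_group_call()` renders a whole call in the style of one catalogued call
type: a piecewise-linear fundamental that starts and ends strictly inside the
type's frequency extremes, oscillates between the Min f and Max f range
midpoints with `floor(midpoint of the extrema range)` interior extrema, and
is rendered as a whistle (one overtone, when it fits below the aliasing
guard), a fully pulsed call at the midpoint sideband spacing, a
pulsed-middle call, or a transition, according to the type's class. Using the
floor rather than rounding of the extrema midpoint keeps the implied FM rate
(≈ extrema count / midpoint duration) inside every type's published FM-rate
range — with rounding, one type (BC07) would land outside its own printed
range, an internal consistency constraint of the tables themselves. The
package's range-validation test synthesizes one call per type and requires
every measured parameter to land inside the published range within one bin
(frequencies) or two hops (durations).

# What the synthetic tests do and do not show

Passing the recovery suites demonstrates that the measurement chain is
correct on signals that *obey its model*: clean FM contours, stationary AM
pulsing, Gabor clicks, white noise. Real recordings add propagation effects
(multipath other than single discrete reflections, frequency-dependent
absorption), overlapping simultaneous callers, non-white and non-stationary
noise, clipping, and surface motion — none of which are modelled, and
several of which (notably overlapping calls, which the single-ridge tracker
does not attempt to separate) are explicitly out of scope. Agreement with the
published per-call-type tables is therefore claimed only at the level of
range consistency of synthetic surrogates, never per-call equality.

# Problem sizes and runtime choices

The validation suites are sized to run comfortably on one CPU: one synthetic
call per call type (nine calls, the longest 7.6 s of 96 kHz audio) for the
range-validation test, 20 vectors per type (180 total) for clustering
recovery and silhouette selection, 50-click buzzes for the click suite,
100 random instances of up to 8 points for the exhaustive k-means oracle, and
two pipeline runs of 18 calls for the determinism check. These sizes were
chosen once as representative of the published study's scale (142 analysed
calls across nine types).

# Known limitations

- The contour tracker follows a single ridge; simultaneous overlapping calls
  in one annotation will yield the dominant one.
- Extrema/inflection counts depend on the smoothing and prominence settings;
  the published analysis did not state its own, so count comparability across
  software is approximate by nature.
- Classification thresholds (20% / 80% / middle-third / halves) are
  operational definitions of this package.
- WAV support is deliberately minimal: integer PCM, 16- or 24-bit, mono
  preferred (channel 1 of multi-channel files, with a warning); no
  proprietary recorder metadata.
- Sampling-rate support is governed by the aliasing guard
  (rate ≥ 2.5 × highest synthesized frequency); no resampling is provided.
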