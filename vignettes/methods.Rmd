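---
title: "Auscultatory blood pressure from Korotkoff sounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auscultatory blood pressure from Korotkoff sounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

During a cuff deflation, arterial sounds (Korotkoff sounds, K-sounds)
become audible when the cuff pressure falls below the systolic pressure
(SBP) and disappear again near the diastolic pressure (DBP). The
auscultatory method reads the cuff pressure at those two moments. This
package automates that reading from two synchronized traces sampled at
2560 Hz: the cuff pressure (mmHg) and a stethoscope microphone signal
(Pa). Rather than thresholding sound amplitude — which breaks down as
soon as the recording contains ambient noise — each beat is assigned a
*probability* of being an audible K-sound by a convolutional network, and
the SBP/DBP are decided by matching the whole probability sequence
against a response template.

## Pipeline

1. **Beat detection.** The cuff trace is linearly detrended and
   band-passed to 4–6.67 Hz (the upper edge is the maximum physiologic
   pulse rate, 400/min). Local maxima of this oscillation are the beats;
   each is paired with the raw cuff pressure at its time.
2. **Per-beat representation.** A 0.4 s sound segment centered at each
   beat (1024 samples) is filtered through 50 contiguous band-pass
   filters of 10 Hz bandwidth (25–35 Hz up to 515–525 Hz) and the
   filtered *waveforms* are stacked into a 50 × 1024 image. Unlike a
   spectrogram (a 0.04 s frame would give only 25 Hz resolution), the
   stack has 10 Hz frequency resolution and preserves phase. Each stack
   is divided by the RMS of its raw segment.
3. **Probability model.** An 18-layer residual CNN adapted to this input
   (single channel, single sigmoid output) maps each stack to a
   probability.
4. **Decision.** The per-beat probabilities, ordered in time, are
   compared with a piecewise-linear human-response template; the
   best-matching onset and offset positions give SBP and DBP.

## The human-response label curve

Listeners tend to react up to a second late at the systolic onset, and up
to a second early or late at the diastolic offset. Training labels
therefore come from the piecewise-linear curve

$$
y(t) \;=\;
\begin{cases}
0, & t < t_\mathrm{SBP} - 1 \text{ or } t > t_\mathrm{DBP} + 1\\
t - (t_\mathrm{SBP} - 1), & t_\mathrm{SBP} - 1 \le t \le t_\mathrm{SBP}\\
1, & t_\mathrm{SBP} < t < t_\mathrm{DBP} - 1\\
-0.5\,\{t - (t_\mathrm{DBP} + 1)\}, & t_\mathrm{DBP} - 1 \le t \le t_\mathrm{DBP} + 1
\end{cases}
$$

evaluated at each beat time. The whole curve equals
`min(onset ramp, offset ramp)` clamped to [0, 1]; this single expression
also defines the degenerate case $t_\mathrm{DBP} - t_\mathrm{SBP} < 1$
(empty plateau) as the pointwise minimum of the two ramps, which keeps
the curve continuous and bounded. Where the two printed cases overlap on
$(t_\mathrm{DBP}-1, t_\mathrm{DBP}+1)$, the offset ramp governs — the
min-form makes that choice automatically.

## Training

The network minimizes binary cross-entropy (fractional labels are valid
targets) with Adam and decoupled weight decay, while the validation
*mean squared error* is monitored; the checkpoint with the smallest
validation MSE is returned and training stops after a patience window
without improvement (50 epochs at full scale; desk-scale runs use
smaller caps so the whole suite stays in minutes). Optimizer choice is
ours: only the learning rate, batch size and weight decay are treated as
searchable; `random_search()` draws the learning rate log-uniformly from
[1e-5, 1e-2] and the weight decay from [1e-6, 1e-3]. The batch-size
range is not reliably documented for the original experiment; we use
powers of two in [16, 128], a conventional span for inputs of this size.

Three augmentations are applied to every training stack (never at
inference), in fixed order: additive white noise with RMS drawn
uniformly in 0–0.1 of the segment RMS (1.0 on the normalized stack
scale), a circular time shift of up to ±97.7 ms (±250 samples), and a
cutout — a 15 × 307 rectangle (30% per axis, floored) placed uniformly
inside the stack and filled with 0.05. The cutout rectangle does not
wrap across the time seam. Noise is added to the stack rather than the
raw waveform because the normalization that defines its scale lives on
the stack.

## The decision rule

Predicted probabilities are clipped at 0.9 and the template scaled by
0.9; saturated predictions otherwise dominate the match. For each
candidate beat $n$ the systolic profile averages the squared differences
between the clipped probabilities and the scaled template positioned at
$t_\mathrm{SBP} = t_n$ over the ten-beat window $n' = -5..4$, with
$t_\mathrm{DBP}$ pinned to $t_N$ so that only the onset shape matters;
window indices outside $1..N$ are dropped and the mean is taken over the
remaining terms (we apply the same exclusion above $N$ as below 1, by
symmetry). The diastolic profile mirrors this with $t_\mathrm{SBP}$
pinned to $t_1$. One printed form of the diastolic sum omits the $1/10$
normalizer; we treat that as typographical and use the mean in both —
the decision is invariant to any common positive scaling of a profile,
so nothing can depend on it. The two argmins are taken separately with
the ordering constraint $n_\mathrm{SBP} < n_\mathrm{DBP}$; if the
unconstrained argmins conflict, the ordered pair minimizing the sum of
the two profiles is chosen. Ties break toward the earlier beat (higher
cuff pressure) for SBP and the later beat for DBP — a conservative
choice toward a wider audible span, ours rather than prescribed. The
cuff pressures at the selected beats are the reported SBP/DBP.

Why this is robust: an isolated high probability, or a short spurious
run, matches the template badly over the full ten-beat window, so it
cannot capture the argmin the way a single threshold crossing captures
the consecutive-beat rule. The limit of that robustness is geometric: a
spurious run *within* the matching half-window (five beats) of the true
onset trades off against genuine onset ambiguity and can pull the
decision by up to the run length; well-separated spikes are rejected
essentially always.

## The baseline comparison method

The comparison method classifies each beat from a 60 × 116 dB-scale
spectrogram (1 s of sound resampled to 2 kHz; 60 ms Hann frames, 16.7 Hz
resolution; hop fixed at 16 samples and the frame sequence end-trimmed
to exactly 116 frames, since a literal 87% overlap does not yield an
integer hop; lowest 60 bins; dB re 1 Pa, floor −120 dB). A small conv
stack (three 3 × 3 layers of 8/16/32 channels, rectifier before each
pooling) produces binary calls at a 0.5 threshold; the published
description fixes the input geometry and the rectifier-before-pooling
detail but not the layer widths, so the stack is configurable. Because
this classifier has no normalization layers, its forward pass first maps
the dB inputs to roughly unit scale with the fixed affine
$(x + 60)/30$; absolute level information is preserved. Decision rule:
the SBP is the cuff pressure at the first beat of the first run of at
least two consecutive K-calls; the DBP at the last beat of the last such
run — the moment after which beats no longer appear, with isolated
single calls ignored. Its sensitivity to call runs created by noise is
precisely the failure mode the template-matching rule is designed to
avoid, and the test suite reproduces that contrast.

## The synthetic-data generator

No subject recordings are distributed with the original study, so the
package ships a generator that defines the study conditions for every
test:

* linear deflation (default 3 mmHg/s, a typical clinical rate) from
  40 mmHg above the true SBP to 40 mmHg below the true DBP;
* a raised-cosine oscillometric pulse (0.25 s) per beat on the cuff
  trace, amplitude bell-shaped over the deflation with a 2 mmHg peak
  (cuff oscillations are typically under 3 mmHg) plus a 0.25 mmHg floor
  so pulses exist outside the SBP–DBP range, as they do in practice;
* beats at a physiologic rate (default 75/min, jitter 2%);
* one damped three-sinusoid burst per beat with energy in 25–200 Hz
  (inside the filter bank's coverage), envelope ramping up around
  t_SBP (default ±0.5 s) and down around t_DBP (default ±1 s), exactly
  zero outside the ramps — mirroring the ±1 s response tolerances the
  label curve encodes;
* an optional auscultatory gap: the 2nd–4th audible beats attenuated
  ×0.05, the known early-systole failure mode;
* calibrated white noise (below).

Durations are rounded up to 0.1 s so trace lengths are multiples of 256
samples; highly composite lengths keep the spectral filtering fast.

What the generator does **not** emulate: subject-specific K-sound
spectra and their evolution across the deflation phases, clothing and
sensor-contact acoustics, nonstationary environmental noise, arrhythmia,
and observer disagreement in the reference values. Passing tests
therefore demonstrate that the pipeline recovers known ground truth
under controlled, statistically plausible conditions — not clinical
accuracy on human data.

## SNR: definition and closed loop

The per-recording SNR is defined as 20·log10 of the ratio between the
RMS of per-beat K-sound peak amplitudes between t_SBP and t_DBP and the
RMS of the pre-systolic sound (the first second, which may contain the
inflation transient, is excluded). "Peak amplitude" is measured on the
smoothed envelope of the 25–200 Hz band (rectified band-passed signal,
20 Hz zero-phase low-pass), with beats located from the cuff channel.
The band-limited envelope matters: if peaks were taken as raw per-beat
maxima of the broadband signal, the maximum of ~1000 Gaussian noise
samples (≈ 3.3 σ) would floor the measurable SNR near +10 dB, and
reported values as low as −2.9 dB would be unreachable by any additive
noise. With the envelope definition the floor sits near −8 dB and the
full observed range (−2.9 to 18.5 dB) is attainable. `inject_noise()`
calibrates the white-noise scale against this estimator by 1-D root
finding, so requested and measured SNR agree within the root-finding
tolerance by construction.

## Numerical choices

* **Zero-phase filtering.** All band-passes multiply the FFT of the
  signal by the squared magnitude of a Butterworth band-pass — the exact
  magnitude response of forward–backward filtering with no transient,
  no peak-time shift, and no numerical trouble in the extremely narrow
  4–6.67 Hz band at fs = 2560 Hz, where a time-domain IIR in
  transfer-function form is ill-conditioned. Time-reversal symmetry and
  the Parseval-style energy bound hold exactly and are tested.
* **Cuff band edges.** The 4–6.67 Hz band is so narrow that sharp edges
  ring for several tenths of a second and create side-lobe maxima; the
  cuff filter therefore uses order-1 (gentle) edges, while the 50-band
  bank uses order-2. In-band/out-of-band requirements (5 Hz within 3 dB,
  deflation ramp −20 dB or more) hold for both.
* **Peak picking.** Candidates are local maxima; a candidate is dropped
  if a much larger (2.2×) candidate lies within ±0.3 s (filter side
  lobes sit ~0.2 s from their main peak at a third of its height), then
  a 60/400 s minimum separation keeps the larger of any remaining close
  pair, then a running-median prominence floor (25%) rejects ripple.
  Reliable for heart rates up to ~100/min; above ~120/min the second
  harmonic of the pulse enters the 4–6.67 Hz band and produces double
  peaks — a limitation inherent to that band choice.
* **Edge beats.** Segments reaching past either end of the recording are
  zero-padded, never discarded, so the beat count N seen by the decision
  rule is preserved.
* **Network details.** Batch norm uses batch statistics during training
  and running statistics at inference; convolution weights use He
  initialization; the first convolution strides 4 along time (the input
  is 20× wider than tall; parameter count is unchanged by a stride).
  Training is deterministic for a fixed seed on a fixed BLAS.
* **Desk scale.** The test suite trains the narrow variant
  (width_scale 0.125, base width 8) on 150 synthetic recordings
  (125 train / 25 validation, 8 beats sub-sampled per recording,
  ≤ 12 epochs) and evaluates on 50 held-out recordings; the acceptance
  script uses 50/10/20. `width_scale = 1` reproduces the canonical
  channel widths and its parameter count is checked against
  architecture arithmetic. The module-level unit tests use
  width_scale 0.0625 to keep individual tests in seconds.

## Known limitations

* On purely white-noise synthetic data the baseline classifier itself is
  nearly perfect, so the two methods' error dispersions come out
  comparable (and the baseline's diastolic reading carries a stable
  positive bias instead); the template rule's variance advantage over
  the consecutive-beat rule emerges under *structured* noise — spurious
  call runs and isolated spikes — which the decision-rule robustness
  tests model directly and the generator's white noise does not produce.
* The decision rule's ±1-beat guarantee degrades when spurious
  probability runs abut the true onset within the matching half-window
  (five beats); the displacement is bounded by the run length.
* Beat detection above ~120/min heart rate double-counts beats (second
  harmonic inside the 4–6.67 Hz band).
* The SNR estimator's floor (~−8 dB) depends on the envelope bandwidth;
  a different smoothing cutoff shifts it.
* All accuracy statements are about synthetic recordings; none of the
  human-subject error statistics of the original study are reproduced
  here, and the generator's simplifications listed above bound what the
  green suite can show about real data.
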