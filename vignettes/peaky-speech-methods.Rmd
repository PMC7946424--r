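---
title: "Peaky speech and deconvolved subcortical responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peaky speech and deconvolved subcortical responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakyspeech)
```

## The paradigm

The auditory brainstem response (ABR) is a sub-10 ms EEG waveform whose
component waves I, III and V index the auditory nerve, cochlear nucleus and
rostral brainstem. Classically it is measured with clicks or tone pips;
`peakyspeech` implements a paradigm that measures it with *continuous
narrated speech*. Two ideas make that possible:

1. **Peaky re-synthesis.** Voiced speech is a sum of harmonics of a
   time-varying fundamental $f_0(t)$. If a phase function $\varphi(t)$ is
   built that advances by exactly $2\pi$ between glottal pulses, then the
   re-synthesized harmonics
   $h_k(t) = A[t, (k+1)f_0(t)]\cos[(k+1)\varphi(t)]$ (with $A$ the
   spectrogram of the original audio) all peak simultaneously at every
   glottal pulse. The re-synthesized waveform is maximally impulse-like
   ("peaky") at known instants while its spectrogram — and thus its sound —
   is essentially unchanged.
2. **Deconvolution against the pulse train.** Treating the glottal-pulse
   train as the input to a linear system whose output is the EEG, the ABR
   is the system's impulse response,
   $$w = \mathcal{F}^{-1}\!\left\{\frac{\sum_i b_i\,
   \mathcal{F}\{x_i\}^*\mathcal{F}\{y_i\}}{\sum_i \tfrac1n
   \mathcal{F}\{x_i\}^*\mathcal{F}\{x_i\}}\right\},$$
   with inverse-variance epoch weights $b_i \propto 1/\sigma_i^2$ in the
   numerator and an equal-weighted regressor power spectrum in the
   denominator. Unit-impulse regressors need no regularization (their
   spectra are broadband) and leave the response in microvolts.

The multiband variant splits the speech into octave bands, each
re-synthesized from a *slightly shifted* fundamental
($f_\Delta = \sqrt{p}-1$ Hz for successive primes $p$, or random dynamic
shifts within $\pm 1$ Hz), so that the same EEG can be deconvolved per band
to obtain frequency-specific responses — the EEG equivalent of an
audiogram-style frequency series, collected during a single story.

## Module map

| Stage | Functions |
|---|---|
| Pulse trains | `pulse_train()`, `smooth_pulse_times()`, `segment_voiced()`, `build_mixer()` |
| Band filters | `design_band_filters()`, `apply_band_filter()`, `broadband_limit_filter()` |
| Re-synthesis | `make_phase_function()`, `build_spectrogram_sampler()`, `synthesize_peaky_voiced()`, `make_broadband_peaky()`, `make_multiband_peaky()`, `alternate_polarity()`, `prepare_epochs()` |
| Response derivation | `preprocess_eeg()`, `pulses_to_regressor()`, `epoch_weights()`, `deconvolve()`, `filter_response()`, `common_component()`, `subtract_common()`, `normalization_factor()` |
| Quality metrics | `spectral_coherence()`, `coherence_cutoff()`, `response_snr()`, `snr_per_minute()`, `time_to_0db()`, `cumulative_proportion()` |
| Latency model | `fit_power_law()`, `predict_latency()`, `pick_peak_latency()` |
| Synthetic data | `narrator_spec()`, `synth_speech_like()`, `make_abr_kernel()`, `simulate_eeg()` |
| Orchestration | `pipeline_config()`, `run_pipeline()`, `narrator_coherence_analysis()` |

## Pulse-train processing

Glottal pulse times (extracted upstream with a pitch tracker; this package
consumes them as plain text, one time in seconds per line) are cleaned with
10 Jacobi-style passes in which pulse $p_i$ is replaced by
$\mathrm{mean}(p_{i-1}, p_i, p_{i+1})$ only where the adjacent intervals
agree within a factor of 1.6, i.e.
$|\log_2(\Delta_1/\Delta_2)| < \log_2 1.6$. That criterion is the only
reading of the published rule under which the $\log_2 1.6$ threshold is
dimensionless; it leaves octave-jump pitch-tracking errors untouched, which
is the intent of the rule. Updating all pulses from the previous pass's
values makes the result independent of sweep order, and the local mean can
never leave the open interval between a pulse's neighbours, so
monotonicity is preserved by construction.

Pulses within 17 ms of one another (the period of a 60 Hz fundamental, the
lowest pitch expected in natural speech) form voiced segments. The *mixer*
function is 1 in unvoiced regions and 0 inside voiced ones, with half
raised-cosine transitions spanning exactly the first and last inter-pulse
interval of each segment; it crossfades unaltered speech against the
re-synthesized voiced speech. Degenerate one- and two-pulse segments are
kept voiced; a lone pulse receives a fixed 5 ms fade on each side so the
crossfade is click-free (the published rule presumes at least two pulses).

## Band filters

The octave filter bank is specified as *power* trapezoids on a fine FFT
grid (grid length: the next power of two above 2 s of samples, so corners
resolve to below 1 Hz). Each shared cutoff carries a roll-off of 0.5
octaves, linear in $\log_2 f$ in the power domain, so adjacent bands cross
at half power (amplitude $1/\sqrt2$) and designed powers sum to exactly 1;
the lowest band passes everything below its upper cutoff and the highest
band everything above its lower cutoff. Amplitude is the square root of
power; kernels are obtained by IFFT, centering, truncation to 5 ms and a
Nuttall window, and the realized magnitude is re-measured from the kernels.
Kernel lengths are rounded to the nearest odd sample count so that the
group delay is an integer and `apply_band_filter()` can re-align its output
exactly with the input.

One consequence worth knowing: because the bands are *power*-complementary,
coherently summing all band outputs of one signal does **not** reconstruct
it — the crossover regions carry $+3$ dB amplitude bumps (the band powers,
not amplitudes, partition the input). The bank is used with independently
re-synthesized per-band signals, where powers are the relevant quantity.

## Re-synthesis

Within each voiced segment the unshifted phase is the natural cubic spline
through $\varphi(p_i) = 2\pi i$, extrapolating linearly at the local
fundamental beyond the outermost pulses so the mixer's fade region still
sees a defined waveform. Static shifts add $2\pi f_\Delta t$; dynamic
shifts add $2\pi\int f_\Delta + \theta_\Delta$ with
$\theta_\Delta \sim U(0, 2\pi)$. The published description of the dynamic
variant fixes only "random shifts of up to $\pm1$ Hz"; here $f_\Delta(t)$
is white noise low-passed at 0.1 Hz, standardized to SD 0.5 Hz and clipped
to $\pm1$ Hz — slow enough that each band keeps a well-defined momentary
fundamental, seeded by contract (a dynamic request without a seed is an
error). Band regressor trains are the crossings of integer multiples of
$2\pi$ of each shifted phase, found by monotone interpolation of the
sampled phase; all trains therefore begin and end together at voiced
onsets/offsets, which is what produces the shared low-frequency "common
component" in the responses.

The spectrogram sampler uses a 1024-sample Hann window (about 23 ms at
44.1 kHz) with a 110-sample hop, scaled so that a unit-amplitude tone at a
bin center reads amplitude 1, and bilinear interpolation in time and
frequency. Harmonics are synthesized while $(k{+}1)f_0(t) < f_{\max}$
(default 12 kHz) and then band-limited by the bank, which keeps synthesis
below Nyquist while supporting both the 8 kHz (diotic) and 11.36 kHz
(dichotic) mixing limits. Fake pulse trains continue the
$\sqrt{\mathrm{prime}}-1$ sequence beyond the primes used for true bands,
half assigned below the original fundamental (negative shifts) and half
above the highest true shift.

Polarity alternation extracts the envelope with a causal first-order 6 Hz
low-pass of $|x|$, flips sign wherever the envelope falls below 1% of its
median, and smooths the $\pm1$ function with a causal first-order 10 kHz
low-pass. The envelope filter is warmed up on a mirrored lead-in so the
causal transient at the start of the file is not mistaken for silence.

## Response derivation

EEG preprocessing is a causal first-order 1 Hz Butterworth high-pass
followed by 5 Hz-wide second-order IIR notches at 60/180/300/420 Hz. Pulse
regressors are built by scaling each pulse time by the sound-card/EEG clock
ratio and placing a *unit* impulse at the nearest EEG sample — no
fractional-amplitude splatter. Epoch weights are inverse variances
normalized to sum to 1; variances are floored at $10^{-12}$ of the largest
epoch variance so a silent epoch cannot absorb all the weight, and the
variance is computed over the full epoch of the derived channel (no window
is published for it).

Deconvolution uses the epoch length itself as the FFT length (no zero
padding), preserving the circular formulation; the raw result carries lags
$[0, T/2]$ at its start and $[-T/2, 0]$ at its end and is rotated so the
lag axis runs $-T/2 \ldots T/2$ *before* any filtering, then trimmed to
$[-0.48, 0.5]$ s (covering the $-480\ldots-20$ ms noise window and all
reported components). Filter presets are causal Butterworth chains:
30–2000 Hz first-order band-pass (`abr_mlr`), plus a 150 Hz first-order
high-pass (`abr`), plus a 200 Hz *second-order* high-pass (`early_abr`,
which also suppresses the broad pre-stimulus component that nonlinear
cochlear processing leaks into pulse-train deconvolution), and a 1 Hz
high-pass/2000 Hz low-pass pair (`full_range`).

For half-wave rectified audio regressors, the positive part and the
*signed* negative part are deconvolved as two separate regressor streams
and their responses combined with equal weight during averaging. Keeping
the negative lobe's sign means both streams see the system with the same
polarity; pooling the two numerators inside one division instead would
cancel most of the response through the pos/neg cross-spectrum. Responses
from continuous regressors are not in microvolts, so
`normalization_factor()` computes $g = \bar\sigma_u/\bar\sigma_p$ from the
0–20 ms response SDs and `apply_normalization()` multiplies the
unaltered-speech responses by it, exactly as published; because the
published factor (0.26) implies the unaltered responses were already the
smaller ones, the application direction is configurable.

The common component is the equal-weight average of the responses to the
fake pulse trains; subtracting it from each band response yields the
frequency-specific waveforms (provenance is tracked and must match).

## Coherence and the cutoff

`spectral_coherence()` implements
$$C_{xy} = \frac{|E[\mathcal{F}\{x_i\}^*\mathcal{F}\{y_i\}]|}
{\sqrt{E[\mathcal{F}\{x_i\}^*\mathcal{F}\{x_i\}]\,
E[\mathcal{F}\{y_i\}^*\mathcal{F}\{y_i\}]}}$$
across non-overlapping, rectangular-windowed 1 s slices. The printed
denominator of the source formula lacks its square root (a typesetting
loss); the standard definition is used so that $C_{xx} = 1$, which any 0–1
coherence plot requires. The cutoff — the highest frequency at which any
pair exceeds 0.1 — is a property of the coherence *curve*: in frequency
bins where only a few slices carry power (the thin upper tail of the pitch
distribution), the magnitude-coherence estimator is biased upward by its
reduced effective slice count, and among tens of thousands of (pair, bin)
combinations isolated single-bin exceedances occur by chance.
`coherence_cutoff()` therefore passes each pair's spectrum through a 5-bin
running median before thresholding (`median_bins = 1` restores the raw
per-bin rule).

## SNR and acquisition time

$SNR_w = 10\log_{10}[(\sigma^2_{S+N}-\sigma^2_N)/\sigma^2_N]$, with the
noise variance estimated by tiling the $-480\ldots-20$ ms baseline into
consecutive segments of the signal-window length (partial tail segments
discarded) and averaging their variances. When the signal window does not
exceed the noise estimate the SNR is $-\infty$ — "no detectable response"
is a first-class outcome, not an error. $SNR_{60} = SNR_w +
10\log_{10}(60/t_w)$ rescales to one minute of recording and
$t_{0\,dB} = 60\times10^{-SNR_{60}/10}$ projects the acquisition time to
criterion; `cumulative_proportion()` turns per-subject times into the
group-level curves used to plan recording durations.

## Latency power law

Wave V latency versus band center frequency $f$ (kHz, normalized to 1 kHz)
follows $\tau(f) = a + bf^{-d}$ with $a = \tau_{synaptic} + \tau_{I-V}$,
$\tau_{synaptic} = 0.8$ ms, and $\tau_{I-V}$ taken per subject (group mean
fallback when wave I is unidentifiable). The fit is linear in the log–log
domain, $\log_{10}(\tau - a) = \log_{10}b - d\log_{10}f$, with
$b = 10^{\mathrm{intercept}}$. The source analysis used a linear
mixed-effects model with random subject and band terms whose exact
structure is ambiguous; this package fits the fixed-effects log–log
regression plus an optional two-stage per-subject variant (`per_subject =
TRUE`, which yields group means and SEs of the per-subject parameters).
Parameter recovery — exact on noiseless data, and within 2 SE in the large
majority of noisy replicates — does not require REML machinery, and
mixed-model inference is deliberately out of scope.

## The synthetic-data generator

`synth_speech_like()` emulates the two audiobook narrators at the level
that matters for the paradigm's stimulus statistics:

* **Segment durations.** Voiced segments are log-normal (median 250 ms
  male / 220 ms female, log-SD 0.5); unvoiced gaps are log-normal with a
  10% chance of a fixed 0.5 s sentence pause (pauses longer than that are
  truncated during stimulus preparation, so 0.5 s is the ceiling). The
  published material states only aggregate rates, so the unvoiced mean is
  *solved*, not tuned: with $V$ the mean voiced duration, $f_0$ the voiced
  rate, and $\approx f_0V + \tfrac12$ pulses per segment (first pulse at
  the segment start plus the integer part of the accumulated cycles), the
  expected gap satisfies
  $E[\mathrm{gap}] = (f_0V + \tfrac12)/r - V$ for target overall rate $r$,
  and the log-normal median follows. The male (69.1 pulses/s) and female
  (110.8 pulses/s) targets are then met by construction.
* **Pitch contour.** The narrator statistics (115.1 ± 6.7 Hz and
  198.1 ± 20 Hz) are means ± SDs *across 64 s segments*, in parallel with
  the "pulses per second over the entire 64 s" statistic — they are not
  the instantaneous pitch spread, which in read speech is far wider. The
  contour is therefore a two-timescale log-domain meander: a fast
  prosodic component (log-SD 0.18, roughly 3 semitones; correlation time
  0.4 s, the scale of accent movements) plus a slow across-segment drift
  (log-SD 0.05, correlation time 20 s), exponentiated around a median
  chosen so the arithmetic mean equals the narrator mean, and clipped to
  the published pitch bounds. A contour with the across-segment SD applied
  *instantaneously* would describe an implausibly monotone narrator — and
  its pulse trains would stay mutually coherent far above the narrator's
  pulse rate, because the static-shift drift alone decorrelates slowly
  (a $|\mathrm{sinc}(f/f_0)|$ tail).
* **Audio** (optional; pulse trains alone suffice for coherence and EEG
  work): the pulse train through three formant-like resonators, plus
  band-limited noise in unvoiced gaps, silent pauses, RMS scaled to 0.01 —
  the digital storage scale used for presentation.

What the generator does **not** emulate: formant dynamics,
coarticulation, amplitude prosody, narrator-specific voice quality, or any
nonlinearity of real cochlear transduction. Passing tests therefore
demonstrate the correctness of the *signal-processing chain* and the
stimulus statistics it depends on, not fidelity to any particular
recording.

`make_abr_kernel()` builds the linear-simulation kernel: Gabor-like bumps
(Gaussian-windowed cosines; FWHM 0.5/0.7/1.0 ms — artifact choices, since
the source used a measured average response) at wave latencies
3.23/5.51/7.22 ms with wave V dominant, zeroed before 1.6 ms (the start of
wave I), Hann-windowed over 0–16 ms, peak-normalized, and centered on a
$\pm16$ ms axis. `simulate_eeg()` convolves a regressor with the kernel
circularly and adds pink noise (plus optional 60 Hz-harmonic lines),
scaled to a requested per-epoch SNR; $-20$ dB is a realistic single-epoch
brainstem SNR. The published linear simulation does not state its noise
model; these are artifact choices.

## Numerical choices and degenerate inputs

* All stochastic operations take an explicit integer seed and restore the
  caller's RNG state; identical inputs and seeds give bit-identical
  outputs.
* Epoch variances are floored ($10^{-12}\times$ max) rather than rejected;
  an all-zero recording yields uniform weights with a warning.
* A regressor with near-zero total energy is rejected before the spectral
  division can blow up; two pulses mapping to one EEG sample produce
  amplitude 2 with a warning rather than silent splatter.
* Phase samples are made strictly increasing (cumulative max plus a
  $10^{-9}$ tie-break ramp) before inversion, and crossings landing
  exactly on a grid sample are kept via a $10^{-6}$ rad tolerance.
* Band edges at or above Nyquist, overlapping roll-offs, non-monotone
  pulse times, dynamic shifts without a seed, and infeasible narrator
  specs (target rate at or above the voiced fundamental, bounds that do
  not contain mean ± 2 SD) are all rejected with diagnostics.
* Filter presets applied to responses sampled below 4 kHz skip the
  2000 Hz edge (the response is already band-limited below it).

## Problem sizes used in the validation suite

The packaged checks run the coherence analysis at the study's own scale —
60 independent 64 s segments per narrator, i.e. 3840 one-second slices,
with the 10-train (45-comparison) static-shift design — and scale other
simulations to sizes where the properties under test are already stable:
kernel recovery uses 30 epochs of 64 s at $-20$ dB per-epoch SNR;
the additivity check (frequency-specific responses + common component vs.
broadband) uses 10 epochs of 32 s; power-law recovery uses 22 subjects ×
4 bands with 0.3 ms latency noise over 500 replicates. `scripts/acceptance.R`
re-runs the two coherence analyses end to end from a supplied seed.

## Known limitations

* Pulse *extraction* from audio is out of scope; pulse times are inputs.
* The mixed-effects latency model and cohort statistics on human data are
  out of scope (see above).
* The auditory-periphery EEG model used as a second validation route in
  the source work is out of scope; `simulate_eeg()` is the linear route.
* Spectrogram amplitude read-out uses bilinear interpolation of Hann-
  windowed STFT magnitudes; partials falling between analysis bins are
  read up to ~15% low. The re-synthesis inherits the same convention, so
  peaky and unaltered speech remain comparable.
* `coherence_cutoff()`'s median guard is a robustness device for sparse
  spectra; with raw per-bin thresholds, isolated estimation-noise bins can
  dominate the reported cutoff.
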