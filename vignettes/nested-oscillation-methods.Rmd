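---
title: "Detecting nested oscillations in MEA recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nested oscillations in MEA recordings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`meaosc` analyzes multi-electrode array (MEA) recordings of cultured neuronal
networks — for example hiPSC-derived excitatory/inhibitory co-cultures — whose
spontaneous activity organizes into slow network bursts (NBs, below 1 Hz) that
can carry faster "nested" oscillations in the delta (1–4 Hz), theta (4–8 Hz)
and alpha (8–13 Hz) bands. The package covers the full chain from raw spike
times to population-level statistics: signal construction, band-specific event
detection, spectral parameterization, burst metrics, and a marginal regression
model for how the fraction of oscillating wells evolves across weeks in
culture. A synthetic data generator with known ground truth backs every stage,
so the whole pipeline is testable without any recording hardware.

## From spikes to a population signal

Spike times from all 16 electrodes of a well are pooled and binned at 2 ms
(500 Hz). The binned counts are convolved with a causal double-exponential
kernel, $k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}$ with $\tau_r = 2$ ms and
$\tau_d = 25$ ms over a 300 ms window, mimicking the time course of a
glutamatergic postsynaptic response; the result is a continuous waveform that
plays the role of an LFP proxy built from spikes. The kernel is normalized to
unit peak. Because every detection threshold downstream is a percentile of the
signal's own envelope, the analysis is invariant to any positive rescaling of
the kernel, so this choice is cosmetic; it makes the delta response readable
(one spike contributes a bump of height 1). Convolution output is truncated to
the input length, preserving the sample-to-time mapping, and is causal — the
kernel models a response that follows each spike, so no centering is applied.

## Band-specific event detection

Per band, the signal is bandpass filtered with a Hamming windowed-sinc FIR
filter whose order spans three cycles of the band's lower edge (rounded to an
odd tap count); the linear-phase group delay is compensated exactly, so
filtering is zero-phase and event timing is preserved. The amplitude envelope
is the magnitude of the FFT-constructed analytic signal, then smoothed with a
Gaussian kernel whose width scales with the band:
$\sigma = c_1 / f_c + c_2 / B$ seconds, with $f_c$ the arithmetic band center,
$B$ the bandwidth, and $c_1 = c_2 = 0.25$ by default (0.104 s for theta). The
scaling rule is exposed as two parameters because only its qualitative form —
wider smoothing for slower, narrower bands — is fixed by the method; the
constants are a documented choice.

Detection uses dual percentile thresholds computed from the entire recording's
smoothed envelope, per well and band: candidates are maximal runs strictly
above the 50th percentile; candidates separated by a sub-threshold gap of at
most `gap_allowance_cycles / f_c` seconds (3/4/5 cycles for delta/theta/alpha)
are merged; merged candidates are kept if they exceed the 75th percentile at
least once and span at least the band's minimum cycle count (8/16/24 cycles of
$f_c$). Gap merging runs before the acceptance tests because the allowance
describes candidacy — brief amplitude dips inside one oscillatory episode —
not acceptance. "Exceeds" is strict, which settles the degenerate
constant-envelope case at zero events. Percentiles use R's default
linear-interpolation definition (type 7).

Two consequences of percentile thresholds are worth stating plainly. First,
detection is scale-free: multiplying the signal by any positive constant
leaves every event unchanged, which protects the analysis from differences in
firing-rate magnitude between wells. Second, the thresholds are *relative to
the recording itself*: the top half of the envelope is above the low threshold
by construction, so the detector reports the most band-active stretches of
every recording rather than testing band activity against an absolute noise
floor. On spike-derived signals the band-limited envelope grows with the
square root of the instantaneous firing rate, so any network burst — with or
without a coherent nested rhythm — elevates every band's envelope. Detected
events therefore mean "this is where the band's amplitude concentrates", and
the spectral parameterization below, not the detector, is what distinguishes
a genuine narrowband rhythm from broadband burst noise. The synthetic-data
tests make this explicit: amplitude-matched surrogate bursts without any
nested modulation are detected at a similar rate to modulated ones, while
their spectra lack the corresponding narrowband peak.

## Spectral parameterization

Events lasting at least one second are analyzed with Welch's method (Hann
taper, constant detrend, 4 s segments with 2 s overlap, 0.05–40 Hz). For
events shorter than one segment the effective segment shrinks to the event
duration with 50% overlap — the closest consistent reading of fixed-length
segments applied to 1–4 s events; the rule is exposed as configuration.

Each spectrum is decomposed, in log10 power, into an aperiodic component
$L(f) = \mathrm{offset} - \mathrm{exponent} \cdot \log_{10} f$ plus up to four
Gaussian peaks (peak width limits 1–8 Hz, minimum peak height 0.2, relative
threshold 1.5 SD of the flattened spectrum, fixed/no-knee aperiodic mode):

1. robust aperiodic fit — ordinary least squares, refit on the half of
   frequencies with the smallest signed residuals (peaks only push residuals
   upward, so the lower half is effectively peak-free);
2. iterative peak extraction on the flattened spectrum, each peak's width
   guessed from its half-height flank and bounded by the width limits
   (bandwidth = $2\sigma$);
3. joint multi-Gaussian least-squares refit (box-constrained quasi-Newton);
4. final aperiodic refit on the peak-removed spectrum.

Per band, peak frequency and power are read at the maximum of the flattened
spectrum restricted to the band, with ties resolved to the lower frequency and
"no peak" reported when the flattened maximum is not positive. On noise-free
synthetic spectra the aperiodic fit is exact to numerical precision, and with
0.05 log10-units of noise the exponent and offset are typically recovered
within 0.02 (see the acceptance script's output).

## Burst and network-burst metrics

Two vendor-style parameter sets are implemented over raw spike times. An
electrode is active at ≥ 5 spikes/min. ISI bursts are maximal runs of at least
5 spikes with every inter-spike interval ≤ 100 ms; ISI network bursts pool the
active electrodes' spikes (ties broken by electrode id) and require ≥ 10
spikes at pooled ISI ≤ 10 ms spanning ≥ 25% of active electrodes. Envelope
network bursts threshold the Gaussian-smoothed 10 ms firing-rate histogram at
twice the recording mean, merge candidates closer than 1 s, and grow
boundaries until 75% of the neighbourhood's spikes are inside; the vendor's
exact envelope and inclusion semantics are proprietary, so this is an explicit
approximation, and the same caveat applies to the weighted mean firing rate
(defined here as total spikes / (duration × active electrodes)) and the
synchrony index (pairwise count of cross-spike lags within ±20 ms, normalized
by the ±1 s correlogram mass — near 1 only for sparsely firing identical
trains, ~0.02 for independent ones).

The Poisson-surprise burst detector seeds candidates at runs of inter-spike
intervals below half the train mean, greedily extends the right edge and trims
the left edge while the surprise increases, and accepts at $S \ge 5$. Two
calibration choices depart from the textbook statistic, both aimed at making
the $S \ge 5$ threshold mean what users expect on background firing. The span
of a candidate runs from its first to last spike, so those two spikes are
certain given the candidate; we therefore score only the $n-2$ interior spikes
against the Poisson count law (otherwise any chance triple of near-coincident
spikes scores astronomically). And $S$ is reported in decimal-log units,
$S = -\log_{10} P(\ge n-2 \text{ spikes in } T)$, because the detector
maximizes over many candidate windows per train: in natural-log units the
maximum surprise of a purely Poisson 300-spike train exceeds 5 in roughly a
third of runs, while in decimal-log units ($P \le 10^{-5}$) false bursts are
essentially absent and a planted 20-spike/0.1 s burst still scores ~80.

Per-well, per-band summaries follow the field's conventions: event counts,
mean durations, occurrence rate (events/minute — the unit is our choice),
means of the spectral annotations, and the percentage of oscillatory network
bursts, where any positive overlap between an NB and an event of the band
counts. A well "oscillates" at a timepoint if it has at least one detected
event (the threshold is configurable); only wells that show network bursting
at the final week enter the occurrence denominators.

## The occurrence GEE

The fraction of oscillating wells per plate and week is a correlated binomial
outcome: plates are measured repeatedly, and wells within a plate share
culture conditions. We fit a marginal logistic model by generalized estimating
equations with an exchangeable within-plate working correlation and the
per-plate well count as an observation-level weight:

$$\mathrm{logit}(p_{ij}) = \beta_0 + \beta_1 t_{ij} + \beta_2 C_{80} +
\beta_3 C_{50} + \beta_4\, t_{ij} C_{80} + \beta_5\, t_{ij} C_{50},$$

with $t$ the centered week and $C_{80}, C_{50}$ indicators for the 80:20 and
50:50 excitatory:inhibitory compositions (excitatory-only as reference).
Estimation alternates Fisher scoring with a moment estimate of the
exchangeable correlation from within-cluster products of Pearson residuals,
degrees-of-freedom corrected and normalized by the estimated Pearson scale so
that the estimate is a genuine correlation even when the data are
overdispersed relative to the weighted binomial variance (the working
variance itself keeps the binomial scale fixed at 1, the standard convention).
Fitted probabilities are clamped away from 0/1 to keep the working covariance
invertible near separation. Standard errors are robust (sandwich); Wald
$\chi^2$ statistics use one degree of freedom; odds ratios are exponentiated
coefficients with $\exp(\hat\beta \pm 1.96\,\mathrm{se})$ intervals. With
singleton clusters the estimating equations reduce exactly to weighted
logistic maximum likelihood, which the tests exploit as an oracle.

One estimand subtlety matters when validating against the synthetic generator:
the generator adds a Normal plate-level intercept on the logit scale, which
defines *conditional* coefficients, while the GEE estimates
*population-averaged* ones — attenuated by approximately
$\sqrt{1 + (16\sqrt{3}/(15\pi))^2 \sigma_u^2}$ (about 4% at
$\sigma_u = 0.5$). Recovery checks compare against the marginal target.

## The synthetic generator

`simulate_well()` draws NB onsets from a hard-core renewal process — a
candidate Poisson process (intensity `nb_rate`, default 0.35/s) thinned to a
minimum inter-onset interval — then gives each burst a half-sine firing-rate
envelope (smooth onset/offset avoids filter ringing) and Bernoulli electrode
participation. Participating electrodes fire as inhomogeneous Poisson
processes at the envelope modulated by
$1 + m \sin(2\pi f_{\mathrm{nested}} (t - t_{\mathrm{onset}}))$, on top of
homogeneous background firing, with a 2 ms refractory deletion matching the
histogram resolution. Every generator is a pure function of its configuration
including the seed.

The default conditions emulate a mature, strongly oscillatory culture:
3.0 s bursts (Gamma-distributed, 10% CV, truncated at the next onset), 3.5 s
minimum inter-onset interval (realized NB rate ≈ 0.16/s), 40 spikes/s/electrode
peak rate, 0.5 spikes/s/electrode background, 90% participation, and a 5 Hz
modulation at depth 0.8. Burst length is the one parameter the detector
geometry genuinely constrains: a theta event must span 16 cycles of the 6 Hz
band center (2.67 s), so bursts must last about 3 s for a single burst to
carry a detectable event; a wall-to-wall 0.3–0.4 Hz burst regime with the
same detector would push every event below the cycle minimum, because the
median-percentile threshold allots only about half of each inter-onset
interval to the above-threshold run. The generator reproduces the statistical
structure the analysis assumes — it is validation scaffolding, not a
biophysical model: no conductances, no synaptic dynamics, no astrocyte or
pharmacology effects, and Poisson (not history-dependent) spiking.

`simulate_psd()` generates spectra directly from the aperiodic + Gaussian
model with iid log-power noise; `simulate_occurrence()` generates the
plate-level binomial tables described above.

## Problem sizes and numerical choices

The shipped tests run the detector-versus-oracle comparison on 200 random
envelopes and 400 random spike trains, spectral recovery on 100 simulated
spectra, end-to-end recovery on 20 modulated plus 20 surrogate wells of 300 s,
GEE recovery on 100 replicates of ~200 plates with a 1000-replicate null
study, and the surprise false-positive study on 100 Poisson trains — sizes
chosen to give stable proportions while keeping a full run in a few minutes.
`scripts/acceptance.R` recomputes scaled-down versions (6 wells, 50 spectra,
200 null replicates) from scratch at a caller-supplied seed. Fisher scoring
converges at `max |Δβ| < 1e-8` (cap 100 iterations); Gaussian refits use
box-constrained L-BFGS-B from data-driven starts; envelope smoothing uses
reflect padding; FFT round-off in the nonnegative convolution output is
clipped at $-10^{-9}$.

## Known limitations

* The dual-percentile detector has no absolute reference, so it cannot by
  itself separate coherent nested rhythms from broadband burst-noise
  elevations (see above); narrowband evidence comes from the flattened
  spectrum.
* Vendor metric definitions (envelope network bursts, burst inclusion,
  synchrony index, WMFR) are approximations with documented semantics, not
  bit-level reproductions.
* The spectral model is fixed-mode only (no aperiodic knee) and stationary
  within an event (no spectrogram parameterization).
* Cycle counts use the arithmetic band center, not instantaneous frequency.
* GEE small-sample corrections and alternative working correlations are out
  of scope; with few clusters the robust Wald test runs slightly liberal.
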