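---
title: "Methods: burst detection, cross-frequency coupling, and intrinsic properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, cross-frequency coupling, and intrinsic properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicephys)
```

slicephys packages the analysis chain used to characterize spontaneous
epileptiform activity and neuronal excitability in neocortical brain-slice
recordings: burst detection in local field potentials (LFPs),
phase-amplitude cross-frequency coupling (PAC) with surrogate
significance, inter-layer propagation lag, postsynaptic-current (PSC)
event analysis, and intrinsic membrane properties from current-clamp step
protocols.  This vignette explains each model, the tunable parameters and
their defaults, the numerical choices that were genuinely open, and what
the synthetic-data generator does and does not emulate.

## Burst detection

The detection trace is built in four steps: a zero-phase FIR band-pass at
4--6 Hz, squaring, convolution with a unit-sum Gaussian kernel
(200-sample aperture, $\sigma$ = aperture/6), and an upper envelope.
Onsets and terminations are the crossings of 10% of the envelope's
per-recording maximum; intervals are half-open `[onset, offset)`, events
closer than 0.1 s are merged and events shorter than 0.1 s are discarded
(both configurable), and peak-to-trough amplitude is read from the raw
trace.  Because the threshold is a fraction of the per-recording maximum,
detection is scale-invariant.

Two numerical choices deserve emphasis.

**Envelope realization.**  The classical "magnitude of the analytic
signal" envelope is designed for oscillatory signals.  Applied to a
*nonnegative* smoothed power trace, the Hilbert transform of each power
bump contributes slowly decaying $\sim 1/t$ tails, and the 10% threshold
crossings land hundreds of milliseconds outside the true burst (we
measured ~0.75 s of smear on 0.7 s bursts).  The default is therefore a
peak envelope -- linear interpolation through the local maxima of the
smoothed power, which rides the ripple at twice the carrier frequency and
decays with the signal itself.  The analytic-signal variant remains
available (`power_envelope(method = "analytic")`) for comparison.

**Filter support.**  A narrow 4--6 Hz FIR is specified by its order in
*taps*, but its time-domain support -- which bounds how precisely a burst
edge can be localized -- is `order / fs` seconds.  The default order is
`round(fs / 2)` taps, a 0.5 s impulse response (equivalently, a
10,000-tap design at a 20 kHz acquisition rate) independent of the
sampling rate of the file at hand.  A 0.5 s support is the longest that
localizes sub-second bursts to within a few tens of milliseconds; on the
2 kHz synthetic fixtures the measured onset/offset error is ~20 ms at
amplitude SNR 5.  Passing `filter_order` explicitly restores any other
design.

Burst statistics report durations, onset-to-onset inter-burst intervals
(IBIs), and two rate estimators: `60 / median(IBI)` (the convention under
which a 26.2 s median IBI corresponds to 2.29 bursts/min) and a
count-based rate.  Duration and IBI distributions are summarized by
maximum-likelihood gamma fits (`MASS::fitdistr`) with a Wald confidence
interval on the shape.

## Time-frequency maps and the modulation index

Spectral analysis uses complex Morlet wavelets in the `cmor`
parameterization with bandwidth $B = 5$ and center frequency
$C = 0.8125$; the scale for target frequency $f$ is $C/f$ so the wavelet's
center frequency equals $f$.  Kernels carry the $(\pi B)^{-1/2}$ prefactor
and are normalized to unit gain at their center frequency; the envelope
SD in time is $1.28/f$ s, hence the 5 s analysis pad below.

Coupling between a slow phase frequency and a fast amplitude frequency is
quantified by the normalized Kullback-Leibler modulation index: the
instantaneous phase (argument of the slow-wavelet coefficients) is binned
into 18 intervals of 20 degrees, left-closed on $[-180^\circ, 180^\circ)$;
the amplitude (magnitude of the fast-wavelet coefficients) is averaged per
bin and normalized to sum to one; and

$$I_{CFC} = \frac{1}{\log 18} \sum_{j=1}^{18} A_j \log \frac{A_j}{1/18}
  \in [0, 1].$$

The implementation is vectorized over the whole comodulogram grid (phase
1--12 Hz in 0.5 Hz steps, amplitude 30--250 Hz in 5 Hz steps, both
configurable) but is tested for exact equality (to $10^{-12}$) against a
direct per-bin oracle.  The index is invariant to amplitude scaling and to
phase rotation by whole bins.

The comodulogram for a burst is estimated on a 10 s window centered on the
burst midpoint; wavelet coefficients are computed with a 5 s pad on each
side which is trimmed before binning, so filter edge effects cannot leak
into the estimate (a property test checks the padded estimate against a
longer extraction).

## Surrogate significance

Significance is assessed by recomputing the index after destroying the
phase-amplitude alignment: the phase series is partitioned into
consecutive blocks, the blocks are permuted at random (amplitude
untouched), and the observed index is z-scored against 100 such
surrogates; cells with $z > 3$ form the significance mask.

The block length is the one genuinely delicate parameter, and the default
departs deliberately from the fixed 10 ms (1% of the sampling rate)
blocks of the reference analysis:

* *Blocks must be longer than the amplitude autocorrelation time.*
  Wavelet amplitude series are smooth on the 15--100 ms scale.  With
  contiguous phase, each phase bin collects temporally clumped amplitude
  samples, whose means have high variance; tiny shuffle blocks scatter
  the bin membership, collapse that variance in the surrogates, and the
  null becomes far too narrow -- on null signals we measured ~15% of grid
  cells at $z > 3$ instead of the nominal fraction.
* *Blocks must not be a fixed multiple of a carrier period.*  A shuffle
  whose blocks hold an integer number of carrier cycles (including the
  limiting case of a circular time shift) merely rotates the phase, and
  the index is rotation-invariant: the test loses all power exactly where
  the coupling is.

Both constraints are met by drawing each block's length uniformly from
0.25--0.75 s.  On null signals (white noise, and carrier-with-uncoupled-
gamma) about 1% of grid cells exceed $z = 3$; on coupled fixtures the
injected pair stands at $z \approx 10\text{--}17$ for carriers at 4 or
5 Hz alike.  `block_frac = 0.01` reproduces the reference behavior when
fidelity to it matters more than calibration.

A second validity control follows the power-confound logic: across
bursts, wavelet power is correlated with the maximal index; a positive,
significant correlation suggests power-driven apparent coupling rather
than true PAC.

## Inter-layer lag

Two simultaneously recorded channels are each band-passed (zero-phase
Hamming FIR, default order 5000, auto-capped on short windows), and the
normalized cross-correlation is searched over $\pm$500 ms; the lag at the
global maximum of the absolute correlation is reported with its signed
correlation.  Positive lag means channel 2 lags channel 1.  Normalization
does not move the argmax but makes the peak interpretable; the bounded
search avoids side-lobe peaks from ringing.  Per-burst estimation windows
each detected burst $\pm$1 s.  Antisymmetry under channel exchange is
exact and tested.

## Postsynaptic currents

Voltage-clamp traces are decimated to 1 kHz (zero-phase anti-alias FIR,
cutoff at 0.475 of the target rate) and band-passed with a Kaiser-window
FIR designed to the template: stopband below 5 Hz at 60 dB, passband
15--150 Hz with 1 dB ripple, stopband above 200 Hz at 40 dB.  The design
attenuations are interpreted in dB (the standard unit for the named
design method).  Zero-phase application deepens the realized stopbands
(measured: ~0.02 dB at 80 Hz, 120 dB at 2 Hz, 208 dB at 300 Hz).

Detection runs on the filtered trace at 4 standard deviations of the
filtered signal, in the configured polarity (always an explicit flag,
never inferred); measurement runs on the raw trace: baseline is the mean
of the 10 ms before the crossing, the peak is the raw extremum within
100 ms after it, and amplitude is peak minus baseline.  The peak search
stops early at the next threshold crossing so closely spaced events are
not fused; events whose windows overlap are flagged.  Decay kinetics come
from a single-exponential fit from the peak toward baseline, starting
2 ms after the peak -- the rising phase still contaminates the first
couple of milliseconds, and skipping them reduces the noiseless bias on a
1 ms/5 ms biexponential kernel from ~14% to ~3%.

Amplitude and frequency distributions are compared as empirical CDFs
(the Kaplan-Meier estimate with no censoring reduces to the standard
ECDF; no censoring support is implemented).  Burst charge is the
trapezoidal integral of the baseline-subtracted current over a
caller-supplied window; the onset and high-frequency sub-windows of a
burst are caller-supplied as well, since no algorithmic delimitation of
those phases is defined.  Reversal potentials come from the least-squares
line of charge against holding potential, reported with the Spearman
correlation across points.  Evoked-response metrics (field EPSP
amplitude, population-spike amplitude, latency of the delayed negative
peak within 30--300 ms) exclude a 3 ms stimulus-artifact window and flag
traces with no deflection beyond three baseline SDs.

## Intrinsic properties

Spikes are local maxima above -10 mV with topographic prominence of at
least 20 mV and a 1 ms refractory.  AP threshold follows an onset
criterion -- the first point where dV/dt exceeds 20 mV/ms on the upstroke
-- with the literal maximum-dV/dt point available via `mode = "max_dvdt"`;
the onset criterion is the one that reproduces threshold values near
-41 mV on template spikes, whereas max-dV/dt lands mid-upstroke.
Amplitude is threshold to peak; half-width is measured at the voltage
halfway between threshold and peak with linear interpolation at both
crossings; AHP is threshold minus the post-peak minimum within 50 ms.

Passive properties: resting potential is the mean of the 50 ms before the
stimulus; input resistance is the slope of steady-state deflection vs
current over subthreshold steps; the time constant is a single-exponential
fit to the first 60 ms of the smallest hyperpolarizing response; note
that a sag conductance active in that window biases this fit low (about
8% at the default simulated cell), so exact recovery claims apply to
sag-free responses.  Sag is
steady state (mean of the last 100 ms of the step, the "return to steady
state" made concrete) minus the most negative deflection; rebound is the
most positive deflection within 500 ms after offset (a concrete reading of
"immediately following") minus the pre-stimulus mean, measured at the
-200 pA step.  The F-I curve counts spikes per 500 ms step (rates in Hz),
takes rheobase as the smallest firing current, re-indexes currents to one
increment below rheobase, and fits the slope over the shifted
non-negative currents -- so cells that reach threshold at different
absolute currents are compared on a common axis.

## The synthetic-data generator

Every analysis stage is exercised end-to-end against seeded generators
with machine-readable ground truth; all randomness goes through a single
seed per generator and fixed seeds give identical traces.

* **Coupled LFP**: 1/f background (white spectrum shaped by
  $f^{-\alpha/2}$, $\alpha = 1$), bursts carrying a cosine carrier at the
  center of the 4--6 Hz band plus a *band-limited-noise* fast component
  (75--85 Hz) whose amplitude follows
  $1 + d\cos\varphi_{\text{carrier}}$, with raised-cosine edge tapers.
  A pure fast tone was rejected: its discrete AM sidebands interact with
  the constant-Q wavelet passbands and systematically displace the
  comodulogram peak.  The default fast-band amplitude equals the
  background RMS -- an in-band gamma elevation of roughly an order of
  magnitude at the 80 Hz wavelet scale, a realistic epileptiform
  contrast.  With *no* background at all, the index's scale invariance
  makes the off-band (depth-amplified) leakage win and the argmax drifts
  above the band; peak-recovery claims therefore refer to the noisy
  conditions.
* **Lagged pair**: the burst component delayed by a whole number of
  samples (the realized lag is recorded), independent 1/f noise per
  channel.
* **PSC trace**: Poisson event times, biexponential kernels (1 ms rise,
  5 ms decay) with unit peak, lognormal amplitudes (mean 15 pA, sdlog
  0.4 -- right-skewed, as measured mEPSC amplitude distributions are),
  Gaussian noise of 1.5 pA.  The trace is exactly the sum of its kernels
  plus noise, and doubling the mean amplitude under the same seed doubles
  the event component exactly.
* **IV series**: charge linear in $(V - E_{\text{rev}})$ with Gaussian
  noise.
* **Step protocol**: RC responses
  $V = \text{RMP} + IR(1 - e^{-t/\tau})$ with optional sag and rebound
  components shaped as $(1 - e^{-t/\tau}) e^{-t/\tau_{\text{sag}}}$
  ($\tau_{\text{sag}}$ = 150 ms, in the range of slow Ih relaxation);
  their internal gains are solved numerically (by root finding on the
  noiseless composite trace) so the *measured* sag and rebound at
  -200 pA equal the programmed amplitudes exactly, and both scale with
  $|I|/200$ for hyperpolarizing steps.  Default membrane parameters are
  those of a knockout layer II/III pyramidal cell: RMP -73.62 mV, R_in
  143.03 MOhm, tau 21.25 ms, sag 2.57 mV, rebound 1.86 mV, rheobase
  100 pA, F-I gain 0.204 Hz/pA.  At and above rheobase, additive spike
  deflections are inserted at a rate linear in the current above one step
  below rheobase, so the shifted F-I fit recovers the programmed gain.

Defaults use 2 kHz sampling for LFP fixtures and 10 kHz for whole-cell
signals, so the pipeline's decimation to 1 kHz is genuinely exercised.

**What the generator does not emulate** -- and hence what passing tests do
not show about real data: electrode drift and movement artifacts;
non-stationary background spectra; bursts whose carrier frequency wanders
within an event; overlapping multi-compartment PSC kinetics and
series-resistance errors; channel noise correlated across contacts; and
any biophysically detailed conductance dynamics (the sag/rebound
components are phenomenological shapes, not an Ih model).

## Problem sizes and runtime choices

Monte-Carlo checks use 20 seeds (50 for gamma-fit recovery and the
statistical-calibration checks, which use 500 repetitions per test);
burst fixtures are 120 s at 2 kHz with 10 bursts; PAC fixtures 60 s with
a 10 s coupling epoch and 100 surrogates; the type-I control uses 20 null
signals of 25 s.  The test-calibration checks use unequal, coprime group
sizes (50 and 71): with equal sizes the two-sample KS statistic lives on
a coarse lattice and its discrete p-values cannot pass a continuous
uniformity check.  These sizes give stable estimates while keeping the
full suite and the acceptance script each within a few minutes on one
CPU.

## Known limitations

* The comodulogram peak's amplitude-frequency localization degrades as
  the in-band SNR of the coupled component grows without bound (see the
  generator notes above); this is a property of constant-Q wavelet PAC
  estimators, not of this implementation.
* The rate estimator `60 / median(IBI)` is upward-biased for strongly
  clustered bursts; the count-based estimator is reported alongside.
* Burst onset/offset confirmation is statistical, not visual; a
  `min_dur`/`merge_gap` pair suppresses chatter but no manual-review
  correction rule is implemented.
* Statistical comparisons treat cells and slices as independent; nested
  (cells-within-animal) structure is not modeled.
* Liquid-junction potentials are not corrected, so absolute voltages are
  convention-dependent.
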