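# slicephys

Analysis of neocortical hyperexcitability in brain-slice
electrophysiology: spontaneous-burst detection in local field potentials
(LFPs), phase-amplitude cross-frequency coupling (PAC) with surrogate
significance, inter-layer propagation lag, postsynaptic-current (PSC)
event analysis, and intrinsic membrane properties from current-clamp step
protocols — with a seeded synthetic-data generator so the entire pipeline
is testable against known ground truth.

It is written for slice electrophysiologists who record with extracellular
LFP electrodes and whole-cell patch clamp and want a scriptable,
reproducible version of the analyses usually spread across ad-hoc
Matlab/Clampfit workflows.

## The methods in brief

* **Burst detection** — band-pass 4–6 Hz (zero-phase FIR), square, smooth
  with a unit-sum Gaussian kernel, take the upper envelope, and threshold
  at 10% of the per-recording envelope maximum. Events get durations,
  onset-to-onset inter-burst intervals (IBIs), rates (`60 / median(IBI)`)
  and maximum-likelihood gamma fits of their distributions.
* **Cross-frequency coupling** — complex Morlet wavelets (`cmor`-style,
  bandwidth 5, center 0.8125) give instantaneous phase (1–12 Hz) and
  amplitude (30–250 Hz); coupling is the normalized Kullback–Leibler
  modulation index over 18 phase bins of 20°,

  I<sub>CFC</sub> = KL(A<sub>norm</sub> ‖ uniform) / log 18 ∈ [0, 1],

  estimated on a 10 s window around each burst with 5 s edge pads, and
  z-scored against 100 random block-shuffle surrogates of the phase
  series (significant where z > 3).
* **Lag** — zero-phase band-limited normalized cross-correlation between
  layer pairs, searched over ±500 ms; positive lag = channel 2 lags.
* **PSCs** — decimate to 1 kHz, Kaiser band-pass (stop 5 Hz/60 dB, pass
  15–150 Hz/1 dB, stop 200 Hz/40 dB), detect at 4 SD of the filtered
  trace, measure baseline-to-peak amplitude and single-exponential decay
  on the raw trace; ECDFs, burst charge (trapezoidal AUC), and reversal
  potentials from the linear charge–voltage fit.
* **Intrinsic properties** — RMP, input resistance, membrane time
  constant, sag and post-inhibitory rebound at −200 pA, rheobase, the
  F–I curve with its shift to one current step below rheobase, and AP
  features (onset-criterion threshold, amplitude, half-width, AHP).
* **Group statistics** — unpaired t, Wilcoxon rank-sum, two-sample KS,
  Bonferroni correction, Spearman/Pearson correlation with the
  conventional strength bands.

## A worked example

```r
library(slicephys)

# a 60 s synthetic LFP: 1/f background, three 0.7 s bursts whose 5 Hz
# phase modulates a 75-85 Hz band, plus ground truth
sim <- gen_coupled_lfp(coupled_lfp_spec(seed = 11))
events <- detect_bursts(sim$recording)
events
#> # A tibble: 3 × 4
#>   channel onset_s offset_s peak_to_trough_amp
#>   <chr>     <dbl>    <dbl>              <dbl>
#> 1 lfp        9.97     10.7               23.1
#> 2 lfp       30.0      30.7               26.1
#> 3 lfp       50.0      50.7               23.5
```

Three bursts are found within ~20 ms of the true onsets (10, 30, 50 s).
Coupling at one burst, with surrogate significance:

```r
sim2 <- gen_coupled_lfp(coupled_lfp_spec(
  duration_s = 60, burst_times_s = 25, burst_dur_s = 10, seed = 2))
pac <- comodulogram(sim2$recording, center_s = 30)
pac <- surrogate_significance(pac, n_surrogates = 100, seed = 2)
pac
#> <pac_result> 23 x 45 grid; peak MI 0.0371 at (5.0 Hz phase, 80 Hz amplitude)
#>   surrogate z at peak 15.40; 105 significant cell(s) (z > 3)
glance(pac)     # peak pair, peak MI, z, number of significant cells
autoplot(pac)   # comodulogram heatmap with significant cells outlined
```

The injected 5 Hz → 80 Hz coupling is recovered exactly at the grid peak
with z = 15.4, far above the 3-SD significance bound. Intrinsic
properties from a simulated step protocol:

```r
prot <- gen_step_protocol(step_protocol_spec())
mp <- membrane_props(prot$steps)
glance(mp)
#>   rmp_mV r_in_MOhm tau_ms sag_mV rebound_mV rheobase_pA fi_slope_Hz_per_pA ...
#>   -73.6      144.   19.5   2.57       1.86         100              0.206
```

The recovered input resistance (144 vs 143.03 MΩ programmed), sag
(2.57 mV), rebound (1.86 mV) and F–I slope (0.206 vs 0.204 Hz/pA) match
the generator's ground truth; the time constant reads 19.5 vs 21.25 ms
because the sag component overlaps the fitting window — on a sag-free
protocol the fit is exact (see the methods vignette).

There is also a command-line interface (installed under `exec/`) with
subcommands `simulate`, `detect-bursts`, `pac`, `lag`, `psc`,
`intrinsic`, and `stats`; flags mirror the function arguments and a YAML
config can stand in for any of them.

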