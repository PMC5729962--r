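# perfopt

Computational core of a dual-mode diffuse optical monitor for blood
perfusion in free tissue flaps. After reconstructive microsurgery a flap
lives on a single reconnected artery and vein; arterial or venous
thrombosis must be caught within hours for the flap to be salvageable.
`perfopt` implements, end to end and fully offline, the analysis chain of a
compact fiber-probe instrument that watches a flap with two complementary
modalities:

* **Diffuse correlation spectroscopy (DCS)** — blood flow. Coherent light
  multiply scattered by moving red cells forms speckle whose intensity
  decorrelates faster when flow is faster. From photon arrival time-tags the
  package computes the intensity autocorrelation
  `g2(tau) = <I(t) I(t+tau)> / <I>^2` (FFT, multitau, and brute-force direct
  estimators) and reduces each curve to the model-free half-decay lag
  **tau\_1/2**: the lag where g2 has fallen halfway between its top and
  bottom plateaus, estimated robustly as the mean over many candidate
  plateau-pair choices.
* **Diffuse reflectance spectroscopy (DRS)** — oxygenation and blood
  volume. A white-light reflectance spectrum is inverted against a Monte
  Carlo lookup table `R_model(lambda) = f_LUT(mua(lambda), musp(lambda))`
  with `musp(lambda) = A (lambda/lambda0)^-B` and
  `mua(lambda) = ln(10) [HbT] (StO2 eps_HbO2 + (1-StO2) eps_Hb)`,
  yielding tissue oxygen saturation **StO2** and total hemoglobin
  **[HbT]** by constrained least-percent-error fitting.

The decision layer combines the two: both failure modes slow flow
(tau\_1/2 rises) and desaturate the flap (StO2 falls); only the [HbT]
direction separates them — venous congestion pools blood ([HbT] up) while
arterial failure drains it ([HbT] down).

Because no instrument is attached, the package ships first-class synthetic
generators: photon streams with an exact analytic
`g2 = 1 + beta exp(-2 tau / tauc)` (complex Ornstein–Uhlenbeck intensity),
forward-model reflectance spectra, the stepped arterial clamp protocol, and
venous/arterial failure trajectories — so every stage is testable against
known truth.

## Worked example

Simulate a 10-s DCS measurement at 50 kHz with a 1-ms decorrelation time,
then recover the half-decay lag:

```r
library(perfopt)

spec   <- stream_spec(mean_rate_hz = 5e4, duration_s = 10,
                      tauc_s = 1e-3, beta = 1, seed = 42)
stream <- simulate_photon_stream(spec)
stream
#> <photon_stream> 499,068 photons, 10 s record (80 ns/tick), channel 'sim', mean rate 4.991e+04 Hz

trace <- bin_timetags(stream, bin_seconds = 2e-6)
curve <- log_downsample(g2_fft(trace, "linear", max_lag_bins = 25000), 15)
est   <- estimate_tau_half(curve)
est
#> <tau_half_estimate> tau_half = 0.0003582 s (spread 4.3e-06 s, 441 pairs, 0 failed)
```

The analytic half-decay of this generator is `tauc * ln(2) / 2 = 0.347 ms`;
the chain recovers 0.358 ms (+3%) from shot-noise-limited data. The 441
sub-values come from the plateau-pair enumeration (21 top x 21 bottom
windows); their spread (4.3 us) is the robustness diagnostic.

Feeding the classifier the per-parameter percent responses of a venous
occlusion (flow slowed, desaturated, hemoglobin pooled):

```r
classify_compromise(list(tau_half = 210, sto2 = -96.3, hbt = 163.3))
#> <compromise_call> venous (tau_half +210.0%, StO2 -96.3%, HbT +163.3%)
```

`run_occlusion_analysis()` does all of this per time point for a rendered
experiment (streams + spectra), computes baseline-referenced percent
changes with propagated uncertainty, and emits the classification; see the
vignette for the full pipeline including the Monte Carlo lookup table
(`build_lut()`), Mie calibration (`mie_properties()`), and spectral fitting
(`fit_spectrum()`).

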