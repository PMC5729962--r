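---
title: "Models and methods behind perfopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perfopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`perfopt` implements the computational chain of a dual-mode diffuse optical
perfusion monitor: diffuse correlation spectroscopy (DCS) for a model-free
blood-flow surrogate, and diffuse reflectance spectroscopy (DRS) for tissue
oxygen saturation and total hemoglobin. This vignette records the models,
the numerical conventions, and the design decisions a maintainer needs; the
README shows the user-facing workflow.

## Intensity autocorrelation estimators

The DCS primitive is a photon time-tag stream (integer ticks of an 80-ns
tagger clock). `bin_timetags()` converts it to an intensity vector over
half-open bins `[j b, (j+1) b)`; the bin width must be an exact integer
multiple of the tick so the lag grid never drifts against the clock, and a
trailing partial bin is discarded rather than padded (padding would bias the
last bin's rate). The default analysis bin is 13 ticks (~1.04 us).

Three estimators of `g2(tau)` are provided and agree by construction:

* `g2_fft(mode = "circular")` — the literal periodic Wiener–Khinchin
  estimator, `g2(k) = (1/N) sum_j I_j I_{j+k mod N} / <I>^2`.
* `g2_fft(mode = "linear")` — the default: zero-padded to at least `2N` so
  no wrap-around occurs, each lag normalized by its `N-k` overlapping terms.
  Wrap-around corrupts long lags on short records, which is why linear is
  the default and circular is retained for literal fidelity.
* `g2_direct()` — the brute-force time-domain loop with the linear
  conventions. It is the oracle: the test suite requires agreement with the
  FFT path to `1e-10` on random traces.

Normalization is fixed by the sanity case: a constant trace must give
exactly 1 at every lag (hence the `1/N` and `<I>^2` factors). Lag 0 — the
shot-noise self-term — is excluded everywhere, as is standard in photon
correlation. `g2_multitau()` implements the conventional multitau scheme
(`m = 16` base lags, pairwise bin doubling, `m/2` new lags per level) with
symmetric normalization by per-lag monitor means, so count scaling cancels
exactly.

Raw curves are smoothed by `log_downsample()`: lags are partitioned into
logarithmically spaced bins (default 15 per decade), the output lag is the
geometric mean and the output g2 the arithmetic mean of each bin's members.
A curve already at or below the target density passes through unchanged.

## The tau-half statistic

Fitting the correlation diffusion equation requires the medium's optical
properties, which are exactly what an occlusion changes; the package
therefore uses the model-free half-decay lag instead. Ideal curves have a
top plateau (short lags) and a bottom plateau (long lags); measured curves
often don't, so a single plateau choice is fragile. `estimate_tau_half()`
enumerates many candidate plateau ranges — by default all contiguous runs of
length 3, 4, 5 within the first 10 and last 10 points of the smoothed curve
(21 windows each side, 441 pairs) — computes a half-decay lag per retained
pair, and reports the mean as tau_1/2 with the standard deviation as the
spread. Decisions worth recording:

* A pair is retained only if `top_mean - bottom_mean` exceeds a contrast
  guard, by default 3 standard deviations of the bottom region (floored at
  a tiny positive value so noiseless curves pass). Flat curves therefore
  raise a classed no-decay error instead of returning a junk lag; the
  pipeline records such scans as missing.
* The crossing is the *first* downward crossing of the midpoint, because
  noisy curves can re-cross; interpolation is linear in g2 versus log(lag),
  which makes tau-half exactly equivariant under lag-axis scaling (a tested
  invariant).
* Pairs whose crossing search fails are dropped and counted, never imputed
  with sentinels, to avoid biasing the distribution.

For the generator's Siegert-form curve `g2 = 1 + beta exp(-2 tau / tauc)`
the analytic value is `tauc ln(2) / 2`; the acceptance suite verifies this
on noiseless grids (within one grid step) and through the full simulated
chain (within 10% at 50 kHz, 10 s, tauc = 1 ms, over 20 seeds).

## Monte Carlo forward model

`mc_reflectance()` is a compiled MCML-style photon-packet transport in a
semi-infinite homogeneous medium: exponential step sampling with
`mut = mua + mus`, weighted absorption, Russian roulette below a weight of
1e-4 with survival 0.1 (the conventional values), Henyey–Greenstein
deflection sampling, and unpolarized Fresnel reflection/refraction at the
surface. Launch is uniform over the source fiber footprint into the NA
acceptance cone (`n_tissue sin(theta) <= NA`); a photon is collected if it
exits within the detector footprint and the same NA condition.

Two deliberate choices:

* **Ring detection.** Sub-millimeter fibers make literal disc-hit scoring
  hopelessly noisy. By azimuthal symmetry of transport about the launch
  point, the escaping photon's azimuth is uniform on the circle of exit
  radius `d`; the detector therefore receives the deterministic arc
  fraction of that circle that overlaps the detector disc. This estimator
  is exact in expectation and cuts the variance by orders of magnitude.
* **Own RNG.** The kernel uses `std::mt19937_64` seeded directly from the
  caller, so tables are bit-reproducible for a given seed, independent of
  R's RNG state, and stable per platform.

The lookup table `build_lut()` is indexed by the *reduced* scattering
coefficient. The production grids are 12 absorption values (0.01, 0.5, then
1 to 19 in steps of 2 cm^-1) by 21 reduced-scattering values (0 to 40 in
steps of 2 cm^-1) — 252 cells; 0–40 cm^-1 is the physiological musp range,
and each cell simulates with `mus = musp / (1 - g)` at `g = 0.9`. The
`musp = 0` column is defined as zero reflectance so bilinear interpolation
stays well-defined. Tissue refractive index defaults to 1.4 with a fused
silica (1.457) fiber face above; both are configurable. Desk-scale work and
the test suite use 1e5 photons per cell; production tables can raise this
via `n_photons`. Each cell gets a decorrelated sub-seed derived from the
master seed, so tables are deterministic. The table stores a geometry hash
checked implicitly by `write_lut()`/`read_lut()` round trips; persistence is
a plain-text TSV with a JSON header — portable, diff-able, and
round-tripping at full double precision.

Two independent physics cross-checks guard the transport code: the sampled
Henyey–Greenstein first moment must equal `g`, and the radially resolved
pencil-beam reflectance (`mc_radial_reflectance()`) must agree with the
closed-form extrapolated-boundary diffusion dipole
(`diffusion_reflectance()`) in its validity regime (`musp >> mua`, a few
transport lengths from the source) within 20%. The Mie module
(`mie_efficiencies()`, Bohren–Huffman downward-recurrence logarithmic
derivative) supplies the calibration phantom's optical properties and is
checked against an independently coded reference implementation to four
significant figures.

## Spectral model and inversion

Absorption is modeled as hemoglobin-only — the dominant visible-band
chromophore in a skin flap — via
`mua(lambda) = ln(10) [HbT] (StO2 eps_HbO2 + (1 - StO2) eps_Hb)` with
`[HbT]` in molar units, and scattering by the tissue-optics power law
`musp(lambda) = A (lambda/lambda0)^-B` with `lambda0 = 600` nm (an interior
anchor of the fit window; any fixed reference works, it only reparametrizes
A). The default fit range is 500–650 nm: it covers hemoglobin's strong
visible features and stays inside the regime where the instrument class
this models can estimate optical properties. Preprocessing follows the
standard chain: `R = albedo_ref (raw - dark) / (reference - dark)` against
a 50% reflectance standard, then a centered moving average whose edges
shrink symmetrically (constants are preserved exactly).

The extinction library shipped with the package
(`synthetic_hemoglobin_extinction()`) is an explicitly synthetic
compilation: a coarse anchor table interpolated linearly, reproducing the
canonical features (the oxyhemoglobin 542/577 nm doublet, the single
deoxyhemoglobin 555 nm peak, isosbestic crossings, the large deoxy excess
beyond 600 nm) without claiming fidelity to any measured tabulation. Every
inversion in the package is self-consistent — the same table generates and
fits spectra — so this choice affects realism, not correctness; swap in a
measured table for real instruments.

`fit_spectrum()` minimizes the mean absolute percent error between the
scaled forward model and the measurement over the box
`[HbT] in [0, 100] uM, StO2 in [0, 1], A in [1, 40], B in [0, 3]`. The
objective is piecewise-smooth (the LUT is bilinear), so the optimizer is
layered: multi-start bounded quasi-Newton (`nlminb`, Latin-hypercube starts
plus the box center plus an optional warm start), followed by a
Nelder–Mead polish of the best solution (simplex steps cross bilinear
facet kinks that stall line searches) and a final bounded refinement.
Model evaluations outside the table hull are penalized so the optimum
stays inside. The instrument scaling ratio is a single scalar — the
least-squares ratio against a non-absorbing microsphere phantom whose
scattering comes from Mie theory (`calibrate_scale()`,
`model_phantom_spectrum()`).

The 4-parameter problem is only weakly identifiable from ~16 wavelengths at
1% noise: genuine local minima exist. Time-series analysis therefore
warm-starts each scan at the previous scan's estimate (tissue composition
drifts slowly between 7-s acquisitions), which in testing removed
essentially all outlier fits.

## Synthetic data: what it emulates, what it does not

`simulate_photon_stream()` builds the intensity as the squared magnitude of
a complex Ornstein–Uhlenbeck field (AR(1) on a grid of `tauc/50`), mixed
with a constant background at fraction `1 - sqrt(beta)` so the intercept is
exactly `beta`, then draws an inhomogeneous Poisson photon stream. The
point of this construction is an *exact analytic target*
`g2 = 1 + beta exp(-2 tau / tauc)`: every downstream claim can be tested
against closed form rather than against another estimator.

The remaining generators encode the experiment designs the analysis serves:

* `simulate_flow_series()` maps pump speed to decorrelation time as
  `tauc = k / speed` — the simplest mapping with the monotone decay/speed
  relation a flow phantom shows — making a -1 log-log slope of tau_1/2
  versus speed an analytic consequence the acceptance suite regresses for.
* `make_occlusion_protocol()` is the stepped arterial clamp schedule: 3.2 mm
  wide open for two minutes, -0.4 mm per minute to full occlusion (0.4 mm)
  at minute 8, a 2- or 4-minute hold (two protocol variants), symmetric
  reopening, ~20 minutes total.
* `simulate_failure_trajectory()` produces flow/[HbT]/StO2 time courses for
  normal, arterial-failure, and venous-failure scenarios at a 7-s cadence.
  Baselines sit at the healthy levels (19 uM, StO2 0.68); failure plateaus
  apply the reported effect directions and magnitudes (venous: [HbT]
  +163%, StO2 -96%; arterial: [HbT] -46%, StO2 -76%) with time constants of
  1 min (arterial, "immediate") versus 8 min (venous, "gradual"), plus 2%
  multiplicative jitter. `render_experiment()` turns a trajectory into raw
  data: per time point a photon stream with `tauc` scaled by
  `1/flow_factor` (floored at 0.05 so decays stay resolvable within a
  scan) and a forward-model spectrum with multiplicative Gaussian noise
  (default 1%).

What passing tests on these generators shows: the estimators are unbiased
and robust at realistic photon budgets, the inversion recovers parameters
the forward model can express, and the sign logic separates the failure
modes whenever the underlying physiology does. What it does not show:
performance under probe-tissue coupling drift, motion artifacts, multi-layer
tissue, chromophores beyond hemoglobin, afterpulsing/dead-time of real
detectors, or animal-to-animal variability. The generators match directions
and qualitative dynamics of in-vivo failure, not any animal's measured
values.

## Pipeline and classification

`percent_change()` implements the baseline-referenced response
`P = 100 (ybar - xbar) / xbar` with first-order propagation of error,
`sigma_P = 100 sqrt((s_y/xbar)^2 + (ybar s_x / xbar^2)^2)`, using the
*standard deviations* of the baseline and response scan sets (not standard
errors) — the spread of scans, not the precision of their mean, is the
instrument-relevant uncertainty here. Baselines follow two conventions:
the first and last two minutes (stepped clamp protocols, where the clamp is
open at both ends; the response window is then the two minutes around
mid-protocol, i.e. maximum occlusion) or the first three scans (failure
simulations; the response window is the final quarter of the record, where
the trajectories have plateaued).

`classify_compromise()` operationalizes the direction-of-change signature:
if tau_1/2 rose more than +50% and StO2 fell more than 20%, the [HbT]
direction decides venous (> +20%) versus arterial (< -20%); anything else
is `none` (all quiet) or `indeterminate`. The thresholds sit well inside
the reported failure effect sizes while rejecting normal fluctuation, and
are exposed as arguments. Scans whose tau-half estimation fails are
recorded as missing, excluded from means, and counted in the report.

## Problem sizes and tolerances

The test and acceptance runs use: 10-s, 50-kHz streams (20 seeds) for
end-to-end DCS recovery; 4-s streams for the five-speed flow sweep; a
reduced 5 x 6 lookup table (mua 0.01–8, musp 5–30 cm^-1) at 1e5 photons
per cell for inversion and classification work, with grids sized to contain
the failure trajectories' absorption excursions; 50 replicates at 1%
spectral noise for the noisy-recovery study; and 30 rendered runs (10 per
scenario, ~11 scans each at 1-s, 20-kHz streams) for classification
accuracy. Optimizer stopping is `rel.tol = 1e-10` with at most 500
iterations per start. These sizes were chosen as the smallest at which the
statistical claims are comfortably resolved.

## Known limitations

* The LUT is geometry-specific; using a table built for another probe is
  not detected beyond the stored geometry hash.
* The diffusion oracle uses the Groenhuis internal-reflection
  approximation; comparisons at strongly mismatched boundaries are looser
  than the matched-boundary check the suite runs.
* The multitau estimator truncates (with a warning) rather than erroring
  when a trace is too short for the requested levels.
* `fit_spectrum()` reports but does not enforce convergence; a
  `converged = FALSE` fit with a small objective is usually a benign
  optimizer status at a flat optimum.
* Venous-versus-arterial classification rests on the generator's premise
  that [HbT] direction separates the modes; pathologies that violate it
  (e.g. partial mixed compromise) will classify as indeterminate.
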