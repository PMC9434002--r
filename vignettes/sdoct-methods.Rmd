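---
title: "Models and methods behind sdoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sdoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdoct)
```

`sdoct` models a spectral-domain OCT scanner for gross pathology
specimens end to end: raw spectrometer fringes in, stitched en-face
images and performance figures out. This vignette explains the physics
the package implements, the conventions and defaults it fixes, the
numerical choices behind them, and what its synthetic tests do and do
not establish about real data.

## Signal model

A broadband source (default: Gaussian, center wavelength
$\lambda_0 = 850$ nm, FWHM bandwidth $\Delta\lambda = 100$ nm) feeds a
Michelson interferometer. A reflector at single-pass optical depth $z$
modulates the detected spectrum; with reference-arm power fraction
$\rho_R$ and amplitude reflectivities $r_i$, the camera sees

$$ I(k) = S(k)\Big[\rho_R + \sum_i 2\sqrt{\rho_R}\, r_i
   \cos\!\big(2 k z_i + \varphi_d(k)\big)\Big], $$

with $k = 2\pi/\lambda$ and $\varphi_d$ the sample–reference dispersion
mismatch. Sample–sample (auto-correlation) terms are off by default and
can be enabled to study their artifacts. Units are fixed package-wide:
$\lambda$ in nm, $k$ in rad/µm, $z$ in µm of optical path; with these
units the phase $2kz$ needs no conversion factors, and dispersion
coefficients $a_m$ (in rad/(rad/µm)$^m$) of a few units to a few tens
span the realistic range from mild to severe mismatch.

The spectrometer detects 750–930 nm on 2048 pixels, by default linear in
wavelength (grating convention); arbitrary strictly monotone pixel maps
are accepted. Detection applies, in order: Gaussian spectral blur of
configurable FWHM, boxcar integration across each pixel (simulated by
`oversample`-fold supersampling; `oversample = 1` disables pixel
integration), shot noise with variance equal to the counts (the Gaussian
approximation is accurate at camera count levels), additive read noise,
and quantization to the 12-bit full well. The reference background peaks
at $0.9\times$ full well ($\rho_R = 0.9$), i.e. shot-noise-limited
operation near saturation, which is how such systems are run.

Two detection parameters have no published values for this class of
instrument and were fixed once as study conditions: the spectral blur
FWHM defaults to 0.13 nm because, combined with pixel integration, the
closed-form envelope then reaches its $-6$ dB amplitude point near
1.1 mm — the sensitivity fall-off scale a pathology-grade 250 kHz
spectrometer achieves; and read noise defaults to 10 counts RMS, typical
for high-speed CMOS line cameras.

## Closed-form system figures

For a Gaussian source the package uses the conventions

* coherence length $\ell_c = \lambda_0^2/\Delta\lambda$ (7.225 µm at
  850/100 nm),
* axial PSF FWHM $\delta z = (2\ln 2/\pi)\,\lambda_0^2 /
  (n\,\Delta\lambda)$ (3.19 µm in air; the two quantities differ only by
  the $2\ln2/\pi$ factor, and both conventions appear in instrument
  specifications, so both are exposed),
* Nyquist (maximum) imaging depth $z_{max} = \pi/(2\,\delta k)$ with
  $\delta k$ the mean pitch of the uniform-$k$ grid — 1.983 mm for 2048
  pixels over 750–930 nm,
* lateral resolution $0.37\,\lambda_0/\mathrm{NA}$ (exposed for
  completeness; nothing in the package depends on it),
* roll-off envelope
  $E(z) = \mathrm{sinc}(z\,\delta k)\cdot\exp(-2\sigma_k^2 z^2)$, in
  amplitude decibels $20\log_{10}E$, normalized to 0 dB at $z=0$. At
  $z_{max}$ with zero blur this is $20\log_{10}(2/\pi) = -3.92$ dB, the
  textbook pixel-integration limit.

Decibels are amplitude throughout (a 6-dB point is where the *peak
magnitude* halves); intensity conventions would halve all dB figures.
Tissue-scaled resolutions divide by the group index; the package prints
both $n_t = 1.4$ (its configurable default, typical for fixed tissue)
and $n = 1.49$, because instrument reports commonly imply either.

## The five-step reconstruction

`reconstruct_ascan()` executes exactly, and in this order:

1. **Background subtraction** — the mean shutter-reference spectrum.
2. **Linear-k interpolation** — resampling at fractional pixel indices
   (`k_map`) that make the samples uniform in $k$. The map is built by
   inverting the monotone pixel-to-$k$ relation and is invariant to
   uniform scaling of the wavelength axis.
3. **Apodization** — Hann by default (sidelobes $\le -31$ dB at the cost
   of main-lobe width), Gaussian or rectangular selectable.
4. **Dispersion compensation** — multiplication of the *analytic signal*
   by $e^{-i\varphi_d(k)}$. The analytic signal (one-sided spectrum) is
   required for a real-valued fringe to acquire a genuine phase
   correction; multiplying the real fringe directly would create a
   conjugate artifact.
5. **Fourier transform** — unitary DFT; the positive-depth half is kept,
   complex-valued, with depth pitch $z_{max}/(N/2)$.

A golden-output regression test pins this order; permuting steps (e.g.
apodizing before resampling) measurably changes the output.

### Numerical choices

* **Resampling interpolator.** Cubic spline on a 4× FFT-zero-padded
  (band-limited upsampled) copy of the spectrum, falling back to plain
  linear interpolation as a fast option. Plain cubic interpolation
  attenuates and distorts fringes whose frequency approaches the sample
  rate — deep reflectors — measurably broadening their PSF; upsampling
  first removes most of that error. The choice is recorded in the
  calibration provenance.
* **Local aliasing bound.** On a wavelength-linear spectrometer the
  per-pixel $k$-pitch at the blue edge exceeds the mean pitch by ~24%,
  so depths beyond $\approx 0.8\,z_{max}$ are locally aliased at that
  edge and no interpolator can recover them. Recovery-quality tests
  therefore stay within $0.75\,z_{max}$; reconstruction itself remains
  defined (and localizes peaks correctly) all the way to $z_{max}$.
* **Depth grids.** An optional zero-pad factor interpolates the depth
  axis for sub-bin PSF metrology (the native depth pitch, 1.94 µm, is
  over half the 3.19 µm PSF width, too coarse to measure widths to a few
  percent). The A-scan contract — length $N/2$, pitch
  $z_{max}/(N/2)$ — holds at the default pad of 1.
* **PSF measurement.** Peak value and position are refined with a
  three-point parabola; half-maximum crossings are located by linear
  interpolation between straddling bins. Sub-2-bin widths are flagged
  resolution-limited.

## Calibration

The background is the per-pixel mean of shutter (sample-blocked) frames;
its RMS error obeys the $\sigma/\sqrt{M}$ standard-error bound, tested
by simulation. The $k$ map comes from the configured wavelength map (no
gas-cell self-calibration; out of scope).

The dispersion phase is estimated from a single-mirror fringe: resample
to uniform $k$, take the analytic-signal phase, unwrap, remove the
best-fit line (which encodes the mirror depth, not dispersion), and fit
a polynomial of order $m \ge 2$ (default 3) in $(k-k_0)$, $k_0$ fixed at
the grid center so the quadratic and cubic estimates decouple from the
removed linear term. Two robustness measures matter in practice and are
part of the design: the phase is extracted only where the fringe
envelope exceeds 10% of its peak (phase in the spectral tails is noise,
and a single spurious $2\pi$ unwrap jump there would bias the fit over
the whole grid), and the fit is weighted by the envelope. A fringe whose
second-highest peak comes within 6 dB of the main one is rejected as
"not a mirror fringe". `calibrate()` can average all columns of a
calibration tile first ("mean"), suppressing camera noise by
$\sqrt{B\cdot A}$ — the recommended mode, and the pipeline default.

Round-trip behavior, verified in the tests: for quadratic mismatch up to
the value that triples the uncompensated FWHM, the estimated $a_2$ is
within 5% (noiseless: within 0.2%) and compensation restores the PSF to
within 5% of the dispersion-free width.

## Mosaicking

`plan_snake_scan()` covers a requested extent (up to
10 cm × 10 cm) with $\lceil \mathrm{extent}/\mathrm{stride}\rceil$ tiles
per axis, stride = field of view − overlap, visiting tiles
serpentine-fashion from a configurable origin corner (default
lower-right, matching specimen placement at the lower-right cassette
corner). Row 1 is the bottom row and $x$ increases rightward; placement
depends only on the (row, col) index, so the origin corner permutes the
visit order without changing the mosaic — a tested invariant.

Stitching defaults to overlap 0 with plain abutment and no blending, and
supports positive overlap with either crop-to-center (trim half the
overlap from each inner tile edge) or averaging. Tiles share the depth
axis verbatim (no Z registration). Split-then-stitch is bit-exact, and a
provenance map records which tile produced every lateral position.

## Projections and export

`z_project()` computes maximum, sum, average, median, or standard
deviation over a depth window (default: full depth). The standard
deviation is the population form — the projection is a descriptive
statistic of the window, not an estimate from a sample. Projections
operate on linear magnitude by default; pass a log-compressed volume for
dB-domain projections (whether instruments project linear or log data
varies, so both are one call away). All five statistics are verified
exactly against an independent naive-loop oracle. Export rescales by
1–99% percentiles by default (min–max and no-rescale available) to 8-bit
PNG or 8/16-bit TIFF; a constant image falls back to mid-gray with a
warning.

## Performance metrics

`sensitivity_falloff()` measures what the roll-off envelope predicts:
identical mirrors are simulated and reconstructed across depth and the
peak decay $20\log_{10}(p(z)/p(z_1))$ is interpolated for its $-6$ dB
crossing. The curve is normalized at the shallowest measured depth, not
extrapolated to $z = 0$. Simulation and closed form agree within 5% when
the simulator uses the matching blur/pixel model. `measure_snr()` is
$20\log_{10}$(peak / sd of noise-floor magnitude); its noise-propagation
test uses read noise only (known $\sigma$), where the A-scan noise floor
is Rayleigh with sd $\sigma\sqrt{2}\sqrt{(4-\pi)/2}$ under the unitary
one-sided DFT.

## Problem sizes

Unit tests run on a 512-pixel spectrometer and small tiles (tens of
A-lines); the physics is pixel-count-invariant, and the quantities tied
to the printed 2048-pixel configuration (PSF width, Nyquist depth,
roll-off, dispersion round-trip) are exercised at the full 2048 pixels
in the acceptance tests and `scripts/acceptance.R`. The demo cassette is
2 × 2 tiles of 8 B-scans × 32 A-lines — enough to exercise every
pipeline stage and the determinism contract.

## What the synthetic tests do not show

The simulator emulates reflector and layered-scatterer phantoms with
per-column independent speckle phasors. It does not model confocal
gating or the lateral beam profile, polarization, multiple scattering,
or real tissue optics — so passing tests demonstrate the correctness of
the processing chain, not clinical image quality. The hardware figures a
real instrument of this class reports (e.g. 5.52 µm air resolution from
a non-Gaussian multiplexed-SLD spectrum, 95 dB SNR at 2 mW, a 3.00 mm
imaging range) depend on the physical source spectrum, spectrometer
optics and power, none of which are published in enough detail to
reproduce; the package reports its computed counterparts (3.19 µm
Gaussian resolution, 1.98 mm Nyquist depth) and treats those hardware
values as measurement procedures to implement, not numbers to match.
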