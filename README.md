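# sdoct

Spectral-domain OCT simulation, reconstruction, and large-field mosaicking
for gross-pathology imaging workflows.

## The problem

In spectral-domain optical coherence tomography (SD-OCT), depth is encoded
in the spectrum of a broadband interferometer and read out by a line-scan
spectrometer. Scanners built for pathology grossing raster a tissue
cassette tile by tile with a motorized stage in a serpentine (snake-scan)
pattern and stitch the per-tile volumes into one large-field image whose
en-face projections can be reviewed like a gross photograph — but with
depth-resolved, near-histology contrast.

Developing and validating the processing chain for such a scanner does not
require the scanner: every stage is a well-defined numerical transform of
the raw spectra. `sdoct` provides the full chain as testable R code:

* **system model** — the optical/acquisition parameter set and its
  closed-form consequences: coherence length `λ₀²/Δλ`, Gaussian axial
  resolution `(2 ln2/π)·λ₀²/(n·Δλ)`, Nyquist imaging depth `π/(2δk)`, and
  the pixel-integration × spectral-blur sensitivity roll-off envelope;
* **phantom simulator** — raw camera fringes
  `S(k)·[ρ_R + Σᵢ 2√ρ_R·rᵢ·cos(2kzᵢ + φ_d(k))]` for mirror and layered
  scattering phantoms, with spectral blur, pixel boxcar integration, shot
  noise (variance = counts), read noise and quantization, plus ground
  truth for every tile;
* **calibration** — background spectrum from shutter frames, the
  uniform-wavenumber (linear-k) resampling map, and the
  dispersion-compensation phase recovered from a mirror fringe by the
  analytic-signal method with a polynomial fit in `(k − k₀)`;
* **reconstruction** — the five-step A-scan chain, in order: background
  subtraction, linear-k interpolation, apodization, dispersion
  compensation on the analytic signal, Fourier transform;
* **mosaic** — serpentine scan planning over up to 10 cm × 10 cm and
  stitching (abutting by default; crop-to-center or averaging for
  overlapping plans);
* **projections** — the five en-face depth statistics (maximum, sum,
  average, median, population standard deviation), B-scan extraction, and
  PNG/TIFF export;
* **metrics** — axial PSF FWHM, sensitivity roll-off curve with its 6-dB
  depth, and SNR, measured on reconstructed data.

## Worked example

```r
library(sdoct)

spec <- system_spec()           # 850/100 nm source, 2048-px 750-930 nm camera
print(spec)
#> SD-OCT system spec
#>   source: 850 nm center, 100 nm FWHM (gaussian)
#>   spectrometer: 2048 px, 750-930 nm, blur 0.13 nm, 12-bit
#>   scan: 1024 A-lines/B-scan x 1024 B-scans, tile 5 x 5 mm

# simulate a mirror tile, calibrate from it, reconstruct, characterize
mirror <- phantom(reflectors = data.frame(z_um = 500, r = 0.05))
tile <- simulate_tile(mirror, spec, seed = 1, bscans = 2, alines = 16,
                      n_reference = 20)$tile
cal <- calibrate(tile, spec, dispersion_column = "mean")
asc <- reconstruct_ascan(tile$counts[1, 1, ], cal, window = "rect", pad = 4)

measure_peak_depth(asc)   # 500.02 um -- the mirror, within 0.02 um
measure_psf_fwhm(asc)     # 3.41 um   (Gaussian-source theory: 3.19 um)

performance_report(spec, seed = 1)
#> SD-OCT performance report
#>   axial FWHM: 3.383 um (air), 2.416 um (tissue n=1.4), 2.270 um (n=1.49)
#>   6-dB roll-off: 1.099 mm (theory 1.081 mm)
#>   SNR: 46.0 dB
```

The mirror localizes to a few hundredths of a micrometer; the measured
FWHM is ~6% above the Gaussian closed form because the 750–930 nm
spectrometer truncates the red tail of the 100 nm source (a real effect,
not an artifact); and with the default 0.13 nm spectral blur the measured
6-dB sensitivity roll-off lands at 1.1 mm.

A full cassette run (simulate → calibrate → reconstruct → stitch →
project → report, with an MD5 manifest of every artifact):

```r
manifest <- run_pipeline(demo_run_config("out/demo", seed = 1))
```

The same stages are scriptable from a shell via `inst/cli/sdoct.R`
(`run`, `simulate`, `calibrate`, `reconstruct`, `stitch`, `project`,
`report`, `spec-report`).

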