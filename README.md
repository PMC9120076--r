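# rspat

Simulation and analysis of **reversibly switchable photoacoustic tomography
(RS-PAT)**: differential imaging of near-infrared photoswitchable bacterial
phytochrome probes (BphP1) over a hemoglobin background.

## The problem

Photoacoustic tomography reconstructs optical absorption from
laser-induced ultrasound, but in tissue the absorption of hemoglobin
(millimolar) swamps that of any molecular probe (nano- to micromolar).
BphP1 photoswitches between a far-red-absorbing Pfr state ("ON" for
photoacoustics at 750 nm) and a red-absorbing Pr state ("OFF"). Cycling the
probe with 635 nm / 790 nm switching light and subtracting the OFF-state
image from the ON-state image pixelwise cancels everything that does not
switch — including blood — leaving the probe distribution:

- absorption: `mu_a(r) = ln(10)/10 * sum_i eps_i(lambda) * c_i(r)` (mm⁻¹),
  with probe concentration split between Pfr/Pr by the Pfr fraction `f`;
- kinetics: `df/dt = k_on (1 − f)` under 635 nm light; per-pulse
  multiplicative OFF kicks and a CW 790 nm decay during imaging;
- detection: ring array, circular-mean forward model with time derivative,
  Gaussian band-pass transducer (4 MHz, 80% bandwidth), Gaussian noise;
- reconstruction: universal back-projection `b(t) = 2p − 2t dp/dt`
  (delay-and-sum as an independent cross-check);
- differential pipeline: Hilbert envelope → 3×3 median → ON − OFF →
  average over cycles → 3σ one-sided display threshold.

The package contains the full chain: extinction-spectra handling,
photoswitching kinetics, deterministic digital phantom generators
(calibration tubes, mouse cross-section, embryo scenes), the acoustic
forward model, reconstruction, the differential pipeline, and
quantification (calibration curves, CNR, noise-equivalent sensitivity,
relative organ levels, a linear spectral-unmixing baseline).

## Worked example

```r
library(rspat)

lib <- load_spectra()
extinction(lib, "BphP1_Pfr", 750) / extinction(lib, "BphP1_Pr", 750)
#> [1] 8.073073   # ON/OFF spectral contrast at the imaging wavelength

cfg <- default_config(kind = "tubes", n_cycles = 4, noise_std = 2e-4, seed = 1)
cfg$phantom$concentrations <- c(5e-7, 2e-6)   # 0.5 and 2 uM tubes
cfg$phantom$tube_radius_mm <- 1.0
cfg$phantom$placement_radius_mm <- 3
cfg$phantom$n <- c(128L, 128L)

res <- run_pipeline(cfg)
res
#> <differential_result> 4 cycle(s), sigma_bg = 0.000734, mask = 1505 px
#>   region   mean_diff       cnr est_concentration_M sensitivity_M
#> 1 tube_1 0.004355782  5.792057                  NA            NA
#> 2 tube_2 0.021726062 29.458240                  NA            NA
```

The 2 µM tube reaches CNR ≈ 29 after four averaged cycles; passing a
`calibration_curve` from `fit_calibration()` fills in the estimated
concentrations and noise-equivalent sensitivities. `full_run()` performs
the same run from a YAML config and writes ON/OFF/differential images
(TIFF with JSON scale sidecars), a per-region report (CSV/JSON) and the
exact configuration used. A command-line front end is installed at
`system.file("cli", "rspat.R", package = "rspat")`.

See the vignette
(`vignettes/differential-photoswitching-pat.Rmd`) for the full model
description, parameter rationale and known limitations (notably the
band-limited interior suppression inherent to this class of instrument).

## Reproducing results

`scripts/acceptance.R` recomputes the headline figure of merit from
scratch — the ON/OFF amplitude ratio inside a 2 µM probe inclusion after
one full photoswitching cycle, noiseless, through the complete
forward-model + UBP + envelope pipeline:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
# t1 = 8.0706 (n = 664)
```

The result (`{"t1": {"value": 8.0706..., "n": 664}}`) exceeds the 5-fold
contrast expected for this probe system and is deterministic: the pipeline
is linear and the processing positively homogeneous, so the image-domain
fold ratio equals the underlying absorption ratio. The acceptance test
suite (`tests/testthat/test-acceptance.R`) additionally verifies
sensitivity arithmetic, hemoglobin-background suppression, reconstruction
accuracy against oracles, kinetics recovery, the 1/√n averaging law, 3σ
threshold calibration, end-to-end linearity over 50 nM–5 µM, and that the
differential map beats two-wavelength linear unmixing under
depth-attenuated, spectrally coloured fluence.
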