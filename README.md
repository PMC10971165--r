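# psdcal

Calibration and characterization computations for plastic scintillation
detectors (PSDs) used for in vivo dosimetry in Ir-192 HDR brachytherapy.
The package is aimed at medical physicists commissioning a PSD system:
it implements the reference dose engine, the mini-phantom calibration
chain, the signal corrections, the detector characterization statistics
and the uncertainty bookkeeping as tested, reusable functions, with a
synthetic-data generator standing in for the physical detector so every
stage can be validated end to end.

## What it computes

**Reference dosimetry (TG-43 away-along).** Absorbed dose rate around a
cylindrically symmetric source is tabulated per unit air-kerma strength
Sk on an (away y, along z) grid. `dose_rate_at()` evaluates
D-dot(y, z) = Sk · T(y, z) with bilinear interpolation performed on
r²-flattened values (each node multiplied by r² before interpolation,
the query divided by r² after), which removes the steep inverse-square
gradient near the source; on a pure 1/r² field the interpolant is exact.
The line-source geometry function G_L(r, θ) = β / (L r sinθ), source
decay 2^(−Δt/T½) (T½ = 73.83 d for Ir-192) and positional-sensitivity
bounds complete the engine. Coordinates: z along the source axis
(positive toward the cable), y perpendicular; table axes in cm.

**Calibration (mini-phantom to full scatter).** Following the TRS-398
quality-factor chain under the Bragg–Gray assumption,
k_Q,Q0 = (D_w/D̄_air)_Q / (D_w/D̄_air)_Q0. The full-scatter factor

    F = (D_w^full scatter / D̄_air^PMMA phantom)_Ir-192 / [s_w,air · p]_Co-60

converts a temperature/pressure-corrected Farmer-chamber reading M in a
compact PMMA phantom directly to absorbed dose to water in the TG-43
full-scatter geometry: D_w = N_D,w,Co-60 · M · F. The denominator 1.112
is the TRS-398 constant for the PMMA Farmer chamber (stored in
`trs398_constants()`, swappable for a simulated value). The Monte Carlo
dose ratios feeding F ship as a versioned fixture
(`inst/extdata/mc_ratios.json`); recomputing them by radiation
transport is out of scope.

**Signal processing and characterization.** Stem-effect subtraction
(PSD minus dummy probe, Poisson uncertainties in quadrature), source
decay normalization with a 0.2% skip threshold, normalization of a
measured grid to the reference table at (y = 4 cm, z = 0), percent
comparison statistics (mean ± SD of |Δ%|, z = 0 radial profile,
per-radius z-profile maxima), angular sweep summaries about the sweep
mean, and the linear temperature model S(T)/S(T0) = 1 + a (T − T0) with
its correction factor 1/(1 + a ΔT).

**Uncertainty (GUM-style).** Type A repeatability (SD/mean), the
uniform-interval rule u = |T_initial − T_final|/√12 for before/after
temperature readings, quadrature combination, coverage-factor
expansion, and budget containers that recombine on every access.

## Worked example

```r
library(psdcal)

# calibration from the shipped Monte Carlo ratio fixture
res <- calibrate(load_mc_ratios(),
                 trs398_constants(nd_w_co60 = 0.054),
                 reading = chamber_reading(1.25, temperature = 22.4,
                                           pressure = 100.8,
                                           ks = 1.002, kpol = 0.999))
print(res)
#> <calibration_result> F = 1.103 +/- 2.5% (k=1)
#>   k_Ir-192^PMMA = 1.103; polystyrene gap 1.95%
#>   D_w (full scatter) = 0.07553 Gy (M = 1.268 nC)

# temperature correction from room (25 C) to body (37 C) temperature
m <- temperature_model(a = -0.0019, t0 = 25)
100 * (relative_response(m, 37) - 1)   # -2.28  (% response change)
temperature_correction(m, 37)          # 1.023331 (multiplicative factor)

# positioning sensitivity at the 60 mm angular-study radius
displacement_sensitivity(d_perp = 60, delta_long = 1.0)  # 0.02777 (%)
```

F = 1.103 means dose to water in full scatter is obtained from the
PMMA mini-phantom reading with a 10.3% conversion on top of the Co-60
calibration factor; the 1.95% polystyrene gap is the residual error of
treating polystyrene as water-equivalent in the Ir-192 spectrum; the
0.028% displacement figure shows source-positioning accuracy of 1 mm is
negligible at 60 mm.

## Analysis workflow

The `analysis/` scripts run the whole study over synthetic sessions and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # toy reference table + PSD/dummy sessions
Rscript analysis/02_away_along.R    # energy-dependence comparison stats
Rscript analysis/03_angular.R       # azimuthal/axial sweep summaries
Rscript analysis/04_temperature.R   # slope fit, 37 C correction, propagation
Rscript analysis/05_calibration.R   # F, dose to water, uncertainty budgets
```

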