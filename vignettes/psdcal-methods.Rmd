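---
title: "Methods: PSD calibration and characterization computations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSD calibration and characterization computations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdcal)
```

## The measurement problem

A plastic scintillation detector (PSD) — a millimetre-scale organic
scintillating fiber (BCF-12, polystyrene core) coupled to a PMMA
optical fiber — is attractive for in vivo dosimetry in Ir-192 HDR
brachytherapy because it is small, near water-equivalent and reads out
in real time. Before clinical use it needs (i) a calibration that turns
detector signal into absorbed dose to water in the TG-43 full-scatter
reference geometry, and (ii) a characterization of the residual
dependences — on photon energy spectrum (distance to the source),
source angle, and detector temperature — plus an uncertainty budget for
the whole chain. This package implements those computations; the
physical detector is emulated by a seeded generator so that every stage
is testable by round trip.

## Reference dose engine

Dose rate around the source is taken from an away-along table
$T(y, z)$ in cGy·h⁻¹ per unit air-kerma strength (U = µGy·m²·h⁻¹),
with $z$ along the source axis (positive toward the cable) and $y$
perpendicular. Because the field is dominated by the inverse-square
term, plain bilinear interpolation is systematically low between nodes
near the source. We therefore interpolate *flattened* values: each
corner value is multiplied by $r^2$ at its own node, the four flattened
values are combined bilinearly, and the result is divided by $r^2$ at
the query point. Two consequences drive the test design: grid nodes are
reproduced exactly, and any field proportional to $1/r^2$ is
interpolated without error (the flattened surface is constant), which
gives a machine-precision oracle. Queries outside the grid raise an
error — extrapolating a steep dose gradient silently is exactly the
failure mode a QA tool must not have.

The line-source geometry function is
$G_L(r,\theta)=\beta/(L\,r\sin\theta)$ with $\beta$ the angle the
active length $L$ subtends at the point, the on-axis limit
$1/(r^2-L^2/4)$, and the point-source limit $1/r^2$ for $L=0$; the test
oracle is direct numeric quadrature of the segment-averaged
inverse-square integral. Source decay uses
$\mathrm{RAKR}(t)=\mathrm{RAKR}_0\,2^{-\Delta t/T_{1/2}}$ with
$T_{1/2}=73.83$ d, the standard Ir-192 reference value.

## Calibration chain

Under the Bragg–Gray assumption the TRS-398 quality factor reduces to a
ratio of water-to-cavity-air dose ratios,
$k_{Q,Q_0}=(D_w/\bar D_{air})_Q/(D_w/\bar D_{air})_{Q_0}$. The
full-scatter factor

$$F=\frac{(D_w^{\text{full scatter}}/\bar D_{air}^{\text{PMMA
phantom}})_{\text{Ir-192}}}{[s_{w,air}\,p]_{\text{Co-60}}}$$

converts the temperature/pressure-corrected PMMA mini-phantom reading
$M$ straight to full-scatter dose to water,
$D_w = N_{D,w,\text{Co-60}}\,M\,F$. Design choices:

* the denominator is the TRS-398 constant 1.112 for the PMMA Farmer
  chamber, held in `trs398_constants()` so a simulated value can be
  swapped in;
* the Monte Carlo ratios are a versioned fixture
  (`inst/extdata/mc_ratios.json`). The absolute numerator ratio is not
  a primary published quantity, so the fixture stores the back-derived
  value $1.103 \times 1.112$ with a `derived` flag; asserting
  $F = 1.103$ therefore checks the algebra of the chain, not an
  independent transport recomputation;
* reference conditions for the air-density correction are 20 °C and
  101.325 kPa unless overridden;
* the combined uncertainty on $F$ is the quadrature of the ratio's MC
  component with the TRS-398 constant component (2.4% ⊕ 0.8% → 2.5%
  at one decimal), flowing through the same engine as every other
  budget.

## Signal corrections and comparison statistics

The stem effect — Cherenkov and fluorescence light generated in the
bare optical fiber — is removed by subtracting a paired dummy-probe
(scintillator-free) acquisition taken at the same geometry. Pairing
tolerances default to 0.1 mm / 0.5°. Each rate carries a Poisson
Type A uncertainty $\sqrt N/N$ (replaceable by a repeats SD when three
or more repeats exist); PSD and dummy uncertainties combine in
quadrature. Net rates are allowed to go negative — clamping would bias
the mean of repeated low-signal acquisitions — but anything below
$-3\sigma$ is flagged.

Decay normalization divides each net rate by
$\mathrm{RAKR}(t)/\mathrm{RAKR}(t_{ref})$ but is skipped (identity)
when the peak-to-peak variation across the session is under 0.2%, the
operational threshold below which routine practice leaves signals
uncorrected. A measured grid is then anchored to the reference table at
(y = 4 cm, z = 0): the source transverse plane is the natural reference
plane and 4 cm the conventional normalization distance; the rescaling
is idempotent by construction.

Percent-difference summaries (grid comparisons and angular sweeps)
report mean ± SD of the *absolute* percent deviations, with signed
per-point values preserved for plotting; published dependence figures
of this kind read most naturally as magnitude summaries, and both forms
are available (`mean_signed_pct`). Angular deviations are taken about
the sweep mean because no angle is a privileged reference. Budget
display uses half-up rounding at one decimal; internal values are never
rounded.

## Temperature model

The PSD signal is modelled as linear in water temperature,
$S(T)/S(T_0) = 1 + a\,(T-T_0)$ with $T_0 = 25$ °C. The fit is
unweighted OLS of $S$ on $T$ (no weighting information exists for the
emulated protocol; a `weights` argument exposes the weighted variant),
reparameterized to $(S_0, a = \text{slope}/S_0)$. The slope uncertainty
combines the OLS standard error with a Type B term for the abscissa
uncertainty — each set's temperature is known only as the mean of the
before/after readings, so its standard uncertainty is
$|\Delta T|/\sqrt{12}$ (uniform-interval rule) in quadrature with the
thermometer calibration uncertainty; the abscissa term is propagated as
$|b_1|\,\bar u_T\sqrt{n/S_{xx}}$. We adopt $\sqrt{12}$, the GUM rule
for a uniform distribution; dividing by 12 itself has no distributional
reading.

The correction factor $1/(1+a\,\Delta T)$ exactly inverts the fitted
response (their product is 1 by construction), errors when the modelled
response is non-positive, and warns more than 5 °C outside the fitted
range.

## Synthetic generator: what it emulates and what it does not

The generator produces the three study set-ups with injected, *known*
dependences:

* **away-along sessions** — PSD rate = sensitivity × dose rate ×
  energy_profile(r) + stem; dummy rate = stem. The stem term is the
  closed-form inverse-square-weighted integral over an irradiated fiber
  length (default 20 cm) — any monotone-in-proximity model peaking
  toward the fiber axis suffices for round-trip testing, since no
  numeric stem magnitudes are published;
* **angular sweeps** — 30°–330° in 20° steps at 60 mm; in the
  azimuthal plane the stem integral peaks toward the fiber-axis angles,
  in the axial plane it is constant;
* **temperature series** — 6 set temperatures (15–40 °C in 5 °C steps)
  × 5 repeats, water drifting up to 0.3 °C between the before/after
  readings so the uniform-interval rule is exercised.

Defaults: sensitivity 1 count per 100 ms per cGy·h⁻¹ (count rates
O(10³)/100 ms at clinical distances), 10 s acquisitions, stem
coefficient 200 counts·cm per 100 ms (a few percent of signal at 4 cm),
noise either Poisson counting statistics or 0.3% Gaussian. Seeds are
explicit arguments; the generator saves and restores the caller's RNG
state, and identical configurations are bit-reproducible.

The generator emulates count statistics, stem contamination, source
decay and the injected dependences. It does **not** model Cherenkov
spectroscopy, optical transport, afterloader mechanics or radiation
transport — so passing round-trip tests demonstrates that the
*pipeline* recovers what is put in, not that a physical detector meets
any particular dependence figure. Physical headline values (energy,
angular and overall dependence percentages) are properties of real
hardware and are out of reach by construction; the suite instead checks
zero-noise round trips to numerical precision, stochastic slope
recovery (200 seeded sessions of 6 × 5 acquisitions at 0.3% noise —
the fitted slopes are unbiased and concentrate well within ±0.0002 of
the injected −0.0019 /°C), the interpolation oracle, and the budget
engine's invariances. Those problem sizes keep the whole suite in a few
seconds while leaving the stochastic checks with comfortable margins.

## Numerical choices and degenerate inputs

* No extrapolation outside the away-along grid; explicit errors name
  the offending range. Malformed CSV cells are reported by row/column.
* Table axes must be strictly increasing; values finite and positive.
* `dose_rate_at` at a stored node returns the stored value identically
  (no floating-point drift through the flattening).
* Geometry pairing and anchor lookup use absolute tolerances
  (0.1 mm, 0.5°) rather than exact float equality.
* OLS on noiseless synthetic data would trigger a perfect-fit warning
  from the summary method; it is muffled because a ~0 standard error is
  the correct answer there.
* Fewer than 3 distinct temperatures, zero temperature spread, zero
  mean in `type_a()`, and non-positive modelled responses are all hard
  errors, not NA propagation.

## Known limitations

* The full-scatter factor path is validated as algebra over a
  transcribed fixture; an independent transport calculation would be
  needed to revalidate the ratios themselves.
* The away-along toy table is a geometry-function × exponential
  attenuation model — adequate for interpolation and round-trip tests,
  not a consensus dataset.
* Uncertainty propagation is plain quadrature without correlations or
  sensitivity coefficients beyond the linear temperature term.
* The stem model is a solid-angle proxy with a free amplitude; only its
  monotone shape, not its magnitude, is meaningful.
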