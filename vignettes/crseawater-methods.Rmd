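---
title: "Methods: chromium redox, isotope fractionation and export budgets"
author: "crseawater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromium redox, isotope fractionation and export budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crseawater)
```

## The scientific problem

Dissolved chromium in seawater is split between largely inert Cr(VI) and
particle-reactive Cr(III). Biological activity in the surface ocean reduces
Cr(VI) to Cr(III); the Cr(III) adsorbs to sinking biogenic particles and is
exported, preferentially removing light isotopes and leaving surface waters
with less Cr and heavier δ⁵³Cr (the per-mil deviation of ⁵³Cr/⁵²Cr from the
NIST SRM 979 standard). This package implements the full chain of
computations needed to test and quantify that mechanism from upper-ocean
station data: replicate quality control, redox speciation, the isotope mass
balance for Cr(III) removal, the global Rayleigh-style δ⁵³Cr–ln[Cr]
relationship, mixed-layer Cr deficit and Cr:C export budgets, net community
production (NCP) from O₂/Ar, and double-spike mass-spectrometric data
reduction. A seeded synthetic-ocean generator stands in for field data so
every stage is testable end to end.

## The core model: two-pool isotope mass balance

Write the total dissolved pool as the sum of a quasi-conservative background
(Cr(VI) plus any non-reactive Cr(III), concentration $C$) and the reactive
Cr(III) (concentration $x$):

$$[\mathrm{Cr}] = C + x, \qquad
\delta_{tot}\,[\mathrm{Cr}] = \delta_{VI+NR}\,C + \delta_{III}\,x .$$

With $C$ constant (defaulting to 2.9 nmol/kg, the observed background) and a
linear trend of $\delta_{tot}$ in $x$ with slope $b$ and intercept $a$, the
balance gives $\delta_{VI+NR} = a$ (the $x \to 0$ limit) and a *constant*
offset of the Cr(III) pool relative to the total,

$$\Delta^{53}\mathrm{Cr} \equiv \delta_{III} - \delta_{tot} = b\,C ,$$

so the fitted slope converts directly into the isotopic signature of Cr(III)
addition and removal. `cr_fractionation()` is the fitted-model interface
(OLS by default, matching the simple linear fit the field analysis uses;
York errors-in-variables as a robustness option when both axes carry known
uncertainties); `mass_balance_delta_iii()` applies the conversion and builds
the confidence interval.

The second mode of the same model fits δ⁵³Cr against $\ln[\mathrm{Cr}]$,
whose slope is the Rayleigh enrichment factor $\varepsilon$ of net Cr
addition/removal; `rayleigh_predict()` is its exact forward model
($\mathrm{cr} = f\,\mathrm{cr}_0$, $\delta = \delta_0 + \varepsilon \ln f$),
and the two are mutual inverses on noise-free data.

### Quasi-linearity: what the linear fit assumes

The linear-trend assumption is exact when the Cr(III) composition floats at
a constant offset from the evolving total pool — solving the mass balance
self-consistently under that assumption returns a straight line, which the
test suite verifies by solving the implicit mixing relation numerically. If
instead the Cr(III) pool had a *fixed* composition, δ⁵³Cr would be
hyperbolic in $x$ and the linear fit would attenuate the recovered offset
toward zero; over the sampled Cr(III) range (0.05–0.35 nmol/kg against a
2.9 nmol/kg background) the tests bound that attenuation at 20%. Both
behaviours are quantified in `test-fractionation.R`; the headline estimator
deliberately reproduces the field convention (slope × 2.9).

The ±CI on Δ⁵³Cr defaults to scaling the slope CI by $C$; a Monte-Carlo
propagation of the joint (intercept, slope) sampling distribution is
available (`ci = "monte_carlo"`) and agrees, since Δ depends on the slope
alone.

## Diel quality control

Shipboard Cr(III) coprecipitation occasionally retains seawater supernatant,
roughly doubling the apparent Cr(III); about one replicate in ten is affected,
always on the high side. Replicate sets per station × depth are screened with
a modified Thompson τ test: a point is an outlier when its deviation from the
group mean exceeds

$$\tau \, s, \qquad
\tau = \frac{t\,(n-1)}{\sqrt{n}\,\sqrt{n-2+t^2}},$$

with $t$ the Student critical value on $n-2$ degrees of freedom. Two design
choices depart from the engineering-handbook recipe, both because the
handbook form fails basic statistical contracts on this data:

* **Significance budget.** The critical value uses $\alpha/(2n)$ per point
  (a Bonferroni share) rather than $\alpha/2$. The handbook form flags
  roughly 8% of points in *clean* Gaussian groups of 10; the corrected form
  keeps the clean-data rejection rate at or below $\alpha$.
* **Iteration order.** The classic outward iteration (test and remove the
  single largest deviation, repeat) masks itself when two or more
  contaminated replicates cluster: the cluster inflates the SD and the first
  test never fires (we measured ~80% missed at three outliers in fifteen).
  The default inward order provisionally removes the most deviant half
  (judged from the median), then reinstates points — closest first — whenever
  they pass the same τ criterion against the retained set. It is identical on
  single outliers, robust to clusters, and caps rejections at half the group.
  The classic behaviour remains available (`iteration = "outward"`,
  `per_point = TRUE`).

Group means over survivors carry 1 SD; single-replicate depths get a
conservative 10% relative uncertainty. Diel periodicity is screened by
fitting a fixed 24-h sinusoid; significance uses the F test of the two
harmonic terms, because an "amplitude > 2 SE" rule tests a non-negative norm
and triples the nominal false-positive rate (measured 17% vs 5%).

## Speciation and blanks

$[\mathrm{Cr(VI)+Cr(III)_{NR}}]$ is the difference of total and reactive
Cr(III) concentrations with quadrature (independent-error) propagation;
differences more than 2σ below zero are validation errors, smaller
excursions are tolerated. Raw coprecipitate masses are blank-corrected
(defaults: 15 pg chromatography mid-range, 18 pg reagent) and sub-blank
results clip to zero with a flag rather than going negative.

## Double-spike reduction

A ⁵⁰Cr–⁵⁴Cr double spike lets one measurement solve simultaneously for the
molar spike fraction λ, the natural fractionation α and the instrumental
fractionation β (both exponential-law exponents). The three measured ratios
to ⁵²Cr define a 3×3 system solved by Newton–Raphson with an analytic
Jacobian (verified against central finite differences), tolerance 1e-12 on
the residual norm, at most 100 iterations, starting from (λ, α, β) =
(0.5, 0, 0); steps that would leave λ ∈ (0, 1) are damped. δ⁵³Cr follows
from α as $1000\,((m_{53}/m_{52})^{\alpha} - 1)$. Isobaric interferences of
Ti, V and Fe at masses 50 and 54 are stripped using the monitor masses 49,
51 and 56 scaled by natural abundance ratios. Isotope dilution converts λ to
concentration, and samples are normalized to the daily mean of bracketing
SRM 979 standards. Reference ratios are the SRM 979 certificate values; the
spike composition is a synthetic stand-in with the right 50/54-dominated
character and is a configuration input, since any real spike is calibrated
per laboratory. Only round-trip correctness is asserted (forward model →
inversion recovers δ⁵³Cr to better than 1e-6 ‰ over 1,000 random draws).

## Budgets and gas exchange

Layer means use trapezoidal integration with the shallowest sample extended
uniformly to the layer top and linear interpolation across the layer bottom
(exact on piecewise-linear profiles; verified against a dense-grid oracle).
The upper-ocean Cr deficit is the 150–200 m mean minus the 0–100 m mean
(100 m ≈ winter mixed layer); it is significant when it exceeds
$\sqrt{2} \times 0.82\% \times$ the reference mean — the combined 1 RSD of
two layer means at the stated analytical precision (a single-RSD rule is a
config option). Areal deficits over the on-station mixed layer are computed
two ways (bulk deficit × thickness × density, and profile-integrated),
because the two answer different questions and disagree on structured
profiles; both are reported and agreement is not forced.

NCP comes from the steady-state O₂/Ar mixed-layer budget:
$\mathrm{NCP} = k\,[\mathrm{O_2}]_{sat}\,\Delta(\mathrm{O_2/Ar})\,/\,1.4$,
with O₂ and Ar solubilities from the standard Garcia & Gordon (1992) and
Hamme & Emerson (2004) coefficient sets, the quadratic wind-speed gas
transfer relation ($0.251\,u_{10}^2$ cm/hr at Sc 660) with
$(\mathrm{Sc}/660)^{-1/2}$ scaling, and winds over a prior 60-day window
weighted by the fraction of the mixed layer each interval ventilated that
has not been re-ventilated since ($f_i = \min(k_i\,\Delta t/\mathrm{mld},1)$,
weight $f_i \prod_{\text{later } j}(1-f_j)$, normalized). The O₂:C quotient
1.4 divides the oxygen flux, following the standard convention. Negative
supersaturation yields negative NCP (net heterotrophy), returned as-is with
a flag.

## The synthetic ocean

The generator emulates the statistical structure the analysis assumes — it
is the package's test bed, not a circulation model. Six stations span
subarctic to subtropical conditions (ANCP 3.02 down to 0.29 mol C m⁻² yr⁻¹,
the observed span), sampled on a fixed grid (10–200 m):

* a background pool of 2.9 nmol/kg, drawn down above the 100-m winter mixed
  layer by NCP-scaled export at Cr:C = 2 µmol/mol;
* reactive Cr(III) = 0.15 nmol/kg plus an NCP-proportional surface term
  attenuated over the euphotic depth, keeping the Cr(III) share of total Cr
  in the observed 5–10% window and spanning roughly 0.15–0.35 nmol/kg;
* δ⁵³Cr generated *exactly on* the constant-background mass-balance line
  (intercept 1.178 ‰, Δ⁵³Cr = −1.08 ‰); the per-sample Cr(III) composition
  then follows from the exact Eq-balance with the actual drawn-down
  background, so concentrations and compositions close the mass balance to
  machine precision before noise;
* diel replicate sets (5–21 per chosen depth) with 10% one-sided high
  contamination drawn at 1.8–2.6× (the supernatant-retention mechanism);
* measurement noise at the stated analytical levels (0.82% RSD on [Cr],
  0.033 ‰ 2 SD on δ⁵³Cr taken as means of two replicate analyses, 10%
  relative on Cr(III)).

Two generator choices deserve comment. First, a literal combination of
"Rayleigh removal of total Cr" with "constant background plus NCP-driven
Cr(III)" is over-determined — Rayleigh removal against a constant background
would force surface Cr(III) *down*, contradicting the observed surface
maxima — so station profiles follow the export-drawdown construction above,
and a separate Rayleigh mode (`simulate_rayleigh()`, ε = −0.82 on a 6
nmol/kg reservoir, remaining fractions ⅓–1) emulates the global
δ⁵³Cr–ln[Cr] compilation for enrichment-factor recovery. Second, the
standing deficit accumulates removal over several seasons (upper waters
above the permanent halocline exchange slowly); the default
`drawdown_years = 5` places station deficits in the observed 0–0.3 nmol/kg
range, with the higher-productivity stations significant at the analytical
threshold and the oligotrophic ones not. For deficit-recovery tests the
knob is set to one seasonal cycle so the measured deficit equals the imposed
export exactly.

Synthetic mass-spectrometer beams are forward-modelled per cycle with
shot-noise-like intensities calibrated so a 40-cycle analysis has an
internal 2 SEM of 0.02–0.03 ‰ and 77 repeated standards scatter with a 2 SD
near 0.021 ‰, matching the stated session statistics; Fe can be injected at
a level computed (`fe_level_for_bias()`) to bias an uncorrected reduction by
a chosen budget, default 0.005 ‰.

## Problem sizes and determinism

Everything is seeded and re-runs byte-identically. The test suite uses
moderate sizes chosen for statistical resolution: 60 full pipeline
replicates for mass-balance recovery, 100 seeded datasets of n = 100 for
enrichment-factor CI coverage, 1,000 random draws for the double-spike
round trip, 200–500 Monte-Carlo groups for outlier-rate calibration. The
acceptance script re-derives its quantities from 40 fresh pipeline runs per
invocation under the seed it is given.

## Limitations

* The generator has no lateral circulation, no seasonal cycle, no water-mass
  structure below 200 m, and independent noise across depths; passing tests
  demonstrate the estimators recover known truth under the assumed
  statistical structure, not that the mechanism holds in any particular
  ocean.
* The Δ⁵³Cr estimator inherits the constant-background assumption; when the
  background pool varies across the fitted samples (as it does by
  construction when export draws it down), the recovered offset shifts by a
  few percent — small against its CI in all tested configurations, but not
  zero.
* Contaminated replicates that survive QC bias Cr(III) means slightly high;
  with the default contamination this attenuates recovered Δ⁵³Cr by ~3%.
* The areal mixed-layer deficit is not a uniquely defined quantity (two
  defensible constructions differ on structured profiles); both are
  reported, neither is privileged.
* The double-spike defaults describe a plausible, synthetic spike; real
  reductions must supply their calibrated spike composition.
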