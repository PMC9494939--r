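---
title: "Quantifying porous cellulose shells by unified SAXS fitting and invariant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying porous cellulose shells by unified SAXS fitting and invariant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxshell)
```

## The measurement problem

Cellulose-coated oil-in-water emulsion droplets have a layered
morphology: an oil core of micron dimensions, a thick porous
regenerated-cellulose hydrogel inner shell, and a thin, denser outer
cellulose skin, all dispersed in water. A pinhole SAXS camera measuring
7.5×10⁻³ < q < 0.264 Å⁻¹ probes length scales of roughly 2–80 nm —
orders of magnitude below the droplet size. The package's analysis
rests on the Stuhrmann decomposition of the scattering of particles
with inhomogeneous interiors,

$$I(q) = I_h(q) + I_i(q) + I_{ih}(q),$$

where $I_h$ is the homogeneous (shape) term, $I_i$ the heterogeneity
term from internal structure, and $I_{ih}$ a cross term that is
negligible when the inhomogeneities are much smaller than the particle.
For micron droplets the shape term decays steeply inside the measured
window (see *The shape-term check* below for how completely), so the
analysed signal is attributed to the nanoscale structure of the porous
inner shell.

## The unified model and its fit

The heterogeneity scattering of a fractal-like hydrogel network is
described by one structural level of the unified
Guinier/exponential/power-law model,

$$I(q) = G\,e^{-q^2 R_g^2/3}
       + B\,\mathrm{erf}\!\left(\tfrac{q R_g}{\sqrt 6}\right)^{3P} q^{-P}
       + \mathrm{bkg},$$

with $G$ (cm⁻¹) the Guinier prefactor, $R_g$ (Å) the radius of gyration
of the compact structural unit, $B$ (cm⁻¹ Å⁻ᴾ) the power-law prefactor
and $P$ the exponent: $P<3$ indicates a mass fractal, $3<P<4$ a surface
fractal, $P=4$ the Porod limit of smooth sharp interfaces.
`unified_intensity()` also evaluates multi-level sums (each level's
power-law term damped by the next-smaller level's Guinier factor), but
the default analysis uses exactly one level, which is sufficient for
these hydrogels.

`fit_unified()` performs bounded Levenberg–Marquardt least squares
(via `minpack.lm`) with these defaults, each chosen for a reason:

* **Residual scheme: log-intensity** (`weighting = "log"`). The curves
  span several decades; raw residuals would let the low-q plateau
  dominate and leave the tail parameters ($B$, $P$) essentially
  unconstrained. Log residuals weight all decades evenly and correspond
  to constant relative error, the natural error model for
  absolute-calibrated data without counting statistics.
  Uncertainty-weighted and unweighted schemes are available.
* **Bounds**: $R_g \in [10, 2000]$ Å (the instrument cannot resolve
  outside roughly this window), $P \in (1, 4)$ (physical fractal
  range), $G, B, \mathrm{bkg} \ge 0$.
* **Background floats by default.** Measured curves are
  background-subtracted upstream, but residual flat background must
  remain representable; a perfectly subtracted curve simply fits
  bkg ≈ 0.
* **Starting values** (`initial_guess()`): $P$ from the median local
  log–log slope over the upper half of the q range; $R_g$ and $G$ from
  a Guinier fit (ln I vs q²) over the lowest-q window, refined twice to
  satisfy $qR_g \le 1.3$; $B$ from the high-q tail given $P$;
  background from the minimum tail intensity. If no Guinier knee is
  found (e.g. a pure power law), $R_g$ is pegged to its upper bound and
  the guess is flagged.
* **Multi-start**: the automatic guess, `multi_start - 1` seeded
  jittered copies, plus a deterministic ladder of starts at
  $R_g = 50, 150, 600$ Å. The ladder matters: when noise corrupts the
  automatic Guinier window, a single-start fit can converge to a
  power-law-only local minimum ($R_g$ at its bound, $P \to 4$) whose
  chi-square is two orders of magnitude worse than the true optimum;
  a start inside the knee basin always exposes it. The lowest
  chi-square converged start wins; exact ties go to the smallest
  $R_g$ so reporting is deterministic.

On noise-free self-generated curves the fit recovers all parameters to
better than 0.1 % (reduced chi-square below 1e-10 unweighted); under
2 % multiplicative noise, $R_g$ is recovered well within 2 % and $P$
within 0.05 across all thirteen reference parameter sets.

## Invariant and composition

The scattering invariant $Q = \int_0^\infty I(q)\,q^2\,dq$ is computed
by `saxs_invariant()` in three parts: trapezoidal integration of
$I q^2$ on the native grid, a Guinier extrapolation
$\int_0^{q_{min}} G' e^{-q^2 R_g'^2/3} q^2\,dq$ evaluated in closed
form via the error function (with a series guard for the flat-intensity
limit $R_g' \to 0$), and a Porod extrapolation
$\int_{q_{max}}^\infty K_p q^{-2}\,dq = K_p/q_{max}$ with $K_p$ the
least-squares constant of $I q^4$ over the top 20 % of the q range.
Intensities in cm⁻¹ are converted to Å⁻¹ with 1 cm⁻¹ = 1e-8 Å⁻¹, so
the invariant is carried internally in Å⁻⁴; reports quote both Å⁻⁴ and
cm⁻¹ Å⁻³.

Numerical and policy choices:

* Guinier window: lowest half-decade, refined once to $qR_g' \le 1.3$,
  minimum five points. Convex curvature of ln I vs q² in the window (an
  aggregation signature) attaches a warning.
* Porod window: top 20 % of the q range (at least five points),
  overridable. A residual log–log slope above 0.3 in the window attaches
  a warning — for these mass-fractal curves ($P \approx 2.5$) the tail
  is *not* Porod-like, and the warning documents that the high-q
  correction is then an approximation (it contributes < 0.1 % for the
  bundled fixtures, so the approximation is inconsequential here).
* Negative post-subtraction intensities are clipped to zero with a
  warning and a reported clipped fraction; excursions beyond −3σ of a
  stated uncertainty are an error, because they indicate a subtraction
  problem rather than noise.

For a two-phase structure occupying a fraction $f$ of the irradiated
volume, $Q = 2\pi^2 \Delta\rho^2 f \phi_1 \phi_2$ with $\phi_1 =
\phi_{cell}$ the cellulose fraction *within* the shell. Using the
volume balance $f\,\phi_{cell} = \phi_{total}$ (φ_total = 0.0067 for
1 wt % cellulose at densities 1.5 and 1.0 g cm⁻³,
`wt_to_volume_fraction(0.01, 1.5)`), `phi_from_invariant()` inverts
this to

$$\phi_{cell} = 1 - \frac{Q}{2\pi^2 \Delta\rho^2 \phi_{total}}.$$

The inversion is exact (round-trip property), strictly decreasing in
$Q$, and clamped-with-flag outside $[0,1]$ — an `out_of_range` flag is
never silent. The analysis assumes water-filled pores (two-phase
contrast), an assumption imported from prior contrast-variation work on
closely related systems, not tested here.

### Two documented discrepancies

The package ships `emulsion_sample_table()`, the thirteen reference
samples with their published $R_g$, $P$, invariant and "% cellulose"
values. Two internal inconsistencies in those reference values are
surfaced rather than hidden:

1. **SLD convention.** The conventional stated SLD pair is 1.45×10⁻⁵
   (cellulose) and 9.47×10⁻⁶ Å⁻² (water). Electron counting at the
   stated densities (`xray_sld()`) gives 1.35×10⁻⁵ and 9.42×10⁻⁶ Å⁻².
   The default analysis uses the stated pair for comparability; the
   computed values are available and the choice is explicit
   (`delta_rho` argument).
2. **The percentage column.** Applying the composition formula verbatim
   to the tabulated invariants (e.g. Q = 1.84×10⁻⁴ cm⁻¹ Å⁻³,
   Δρ = 5.03×10⁻⁶ Å⁻², φ_total = 0.0067) yields φ_cell ≈ 0.45, while
   the tabulated column prints 18 % for that row — the tabulated
   $1-\phi_{cell}$ is consistently ≈1.5× larger than the formula
   produces, i.e. the column was evidently produced with an effective
   constant the table does not state. The package implements the
   formula as written and does not guess that constant; consequently
   the percentage column is validated only through properties (round
   trip, monotonicity, the closed-form two-phase oracle, end-to-end
   recovery of known synthetic compositions) and not value-by-value.

## The synthetic-data generator

`sample_fixtures()` regenerates the thirteen reference samples on the
instrument grid (200 log-spaced points over [7.5×10⁻³, 0.264] Å⁻¹ by
default) from their published $R_g$ and $P$. The published prefactors
are not available, so fixtures adopt a convention: $G = 1$ cm⁻¹ and $B$
placed by `crossover_prefactor()` so the Guinier and power-law *terms*
cross at the geometric mid-grid. Two consequences are worth stating
plainly:

* Because the Guinier factor has collapsed by many decades at mid-grid,
  this convention produces curves whose power-law section lies far
  below $G$ — a wider dynamic range than measured curves show. This is
  harmless for the $R_g$/$P$ recovery surface (the log-residual fitter
  is scale-free across decades) but makes fixture invariants ~6.8×10⁻⁷
  cm⁻¹ Å⁻³ per unit $G$, far smaller than measured ones. Where an
  absolute scale matters the package offers `fractal_prefactor()`
  ($B = G P \Gamma(P/2) / R_g^P$, the physically tied mass-fractal
  relation giving a realistic knee near $q \sim 1/R_g$) and
  `prefactor_for_invariant()` (rescale $G$ so the synthetic invariant
  matches a target).
* Default noise is 2 % multiplicative Gaussian — typical of
  absolute-calibrated pinhole SAXS — with per-point uncertainties
  attached and full seed reproducibility; a Poisson counting mode is
  available. No instrument smearing is simulated (pinhole collimation),
  no 2-D detector effects, no background-subtraction residual
  structure. Passing the recovery tests therefore demonstrates the
  estimator's correctness and noise robustness under these idealised
  conditions, not immunity to smearing or correlated subtraction
  errors in real data.

## The shape-term check

`shape_term_negligibility()` evaluates the droplet-shape (homogeneous)
term from a core–two-shell sphere profile, smears it over a lognormal
distribution of a common size factor (default σ/μ = 20 %, 61
quadrature nodes) so that the verdict reflects the form-factor
*envelope* rather than accidental nulls, and compares the maximum over
the grid with a noise floor. The verdict is monotone under enlarging
the droplets at fixed dispersed-phase volume fraction.

Quantitatively, for a representative droplet
(`droplet_profile()`: 3 μm droplet, decane core, hydrogel shells at the
stated SLD conventions, number density from 1 wt % oil) the smeared
shape term is a sharp-interface Porod tail,
$I_h(q) \approx 2\pi\,n S\,\Delta\rho^2/q^4$, reaching ≈16 cm⁻¹ at
$q_{min} = 7.5\times10^{-3}$ Å⁻¹ and falling below a few-cm⁻¹ floor
only for $q \gtrsim 0.011$ Å⁻¹. Against a floor of 2 % of the
reconstructed measured-scale low-q intensity (≈4.8 cm⁻¹), the shape
term is therefore *not* negligible over the lowest ~13 % of the
logarithmic q range — it would be negligible everywhere only if the
low-q relative uncertainty were ≳7 %, which is plausible for a
wire-detector camera near the beamstop but cannot be assumed. The
package consequently reports `q_clear`, the q beyond which the shape
term stays below the floor, and the honest summary is: the
inner-shell attribution is safe for $q \gtrsim 0.011$ Å⁻¹ and should
be treated with care in the lowest half-decade, where both the Guinier
window and the low-q invariant extrapolation live.

## Problem sizes and runtime choices

The validation suite uses 200-point instrument grids; the closed-form
invariant oracle (dilute spheres, R = 100 Å, φ = 0.0067) uses an
8000-point grid over [10⁻⁴, 2] Å⁻¹ to resolve form-factor oscillations
for trapezoidal integration to within 1 %; noisy-recovery checks use
ten replicates per parameter set and the parameter-recovery property
uses one hundred random level-1 models. These sizes give stable,
seed-reproducible statistics while keeping the whole suite fast.

## Known limitations

* One structural level is fitted; strongly hierarchical gels would need
  the multi-level model plus a fitting strategy for it.
* The Porod tail correction assumes $q^{-4}$ beyond $q_{max}$ even when
  the measured window still shows a mass-fractal slope; the attached
  warning marks this, and for mass-fractal curves the correction is
  tiny but formally inconsistent.
* The composition estimate inherits every assumption of the two-phase
  modified invariant: sharp contrast between cellulose and water-filled
  pores, the volume balance, and the SLD convention; changing the SLD
  pair rescales φ_cell substantially (see the discrepancy notes above).
* No instrument smearing, 2-D reduction, masking or azimuthal
  averaging; curves must arrive reduced, subtracted and absolutely
  calibrated (helpers: `subtract_background()`,
  `absolute_calibration()`).
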