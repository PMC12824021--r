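---
title: "Methods: non-invasive estimation of in vivo aortic material properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-invasive estimation of in vivo aortic material properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortafit)
```

## The problem

Wall stiffness of the ascending aorta matters clinically — dissected aortas
are stiffer than healthy ones, and patient-specific stiffness feeds directly
into biomechanical risk assessment — but the gold-standard measurement,
planar biaxial tensile testing, requires excised tissue. This package
implements a non-invasive alternative: estimate the anisotropic constitutive
parameters of a subject's ascending aorta from quantities obtainable before
any surgery, namely the cuff pressures and the minimum and maximum lumen
perimeter of the vessel over one cardiac cycle (from transesophageal
echocardiography), plus a wall-thickness measurement.

## Constitutive model

The wall is modelled as a homogeneous, incompressible, anisotropic
hyperelastic solid with two symmetric collagen-fiber families at `±θ` from
the circumferential direction. The strain energy per unit reference volume
is an anisotropic Mooney–Rivlin form,

$$
W = c_1 (I_1 - 3) + D_1\!\left(e^{D_2 (I_1 - 3)} - 1\right)
  + \frac{K_1}{2 K_2}\!\left[e^{K_2 (J_4 - 1)^2} + e^{K_2 (J_6 - 1)^2} - 2\right],
$$

with $I_1$ the first invariant of the right Cauchy–Green tensor and
$J_4, J_6$ the volume-normalized squared fiber stretches. The six
parameters are `c1`, `D1` (kPa), `D2`, `K1` (kPa), `K2` (dimensionless) and
the fiber half-angle `θ` (degrees); all stress-like and exponent parameters
are constrained non-negative, and fitting constrains `θ` to (0°, 45°),
consistent with imaging studies of aortic fiber orientation. Incompressibility
is enforced kinematically (`λr = 1/(λc λa)`, so `I3 = 1` and `J4 = I4`); the
`J`-forms are retained so the energy stays well defined for any state. `I2`
is computed and exposed but does not enter the printed energy. When
`K2 < 10⁻⁶` the anisotropic term uses its analytic `K2 → 0` limit
`(K1/2)[(J4−1)² + (J6−1)²]`; the stress expressions are regular at `K2 = 0`
and need no limit. Exponential overflow at extreme stretch raises an
explicit range error rather than returning infinity.

A property used throughout: every stress is homogeneous of degree one in
the stress-like triple `(c1, D1, K1)`. Scaling those three coefficients by
`k` scales every stress, every equilibrium pressure, and every effective
modulus by exactly `k`.

## Biaxial testing layer

`simulate_protocol()` reproduces a force-controlled biaxial rig: five
loading protocols at circumferential:axial force ratios 1:1, 1:0.75,
0.75:1, 1:0.5 and 0.5:1 up to a maximal force of 2 N on a nominally
20 mm × 20 mm square specimen. Forces are converted to engineering (first
Piola–Kirchhoff) stress via the undeformed cross-section — the rig
convention, since forces and undeformed dimensions are what is recorded —
and the two in-plane stretches at each load step solve the plane-stress
equilibrium equations (damped Newton with continuation along the load
path).

`fit_biaxial()` identifies parameters by bounded nonlinear least squares on
the pooled engineering-stress residuals of both directions over all
protocols, all records weighted equally. The optimizer is
Levenberg–Marquardt with box bounds (`minpack.lm::nls.lm`), with eight
seeded multi-starts whose stress-like coefficients are drawn log-uniformly
relative to the data's stress scale (making the fit equivariant to stress
units); the best residual wins, near-ties broken toward lower `K1`.
Individual coefficients of this model trade off against each other —
parameter non-uniqueness is expected — so the fitting contract is response
recovery: on noiseless five-protocol synthetic data the fitted model
reproduces stresses pointwise well below 1 % of the maximum stress, and
`R²` (about the pooled mean of both stress components) exceeds 0.999.

## Forward model: inflation–extension of a thick-walled tube

The imaged vessel segment is idealized as an incompressible axisymmetric
thick-walled tube under quasi-static luminal pressure and fixed axial
stretch `λz = 1.25` (the literature-average in vivo axial pre-stretch,
i.e. 20 % axial shrinkage to the unloaded state). Wall incompressibility
links deformed and reference radii, `r(R)² = ri² + (R² − Ri₀²)/λz`, and
radial equilibrium gives the classical pressure integral

$$
P = \int_{r_i}^{r_o} \frac{\sigma_\theta - \sigma_r}{r}\, dr ,
$$

evaluated by fixed-order Gauss–Legendre quadrature (order 16 by default)
over the reference wall. `inflate()` solves `P(ri) = P_target` by
safeguarded bracketing to an inner-radius tolerance of 10⁻¹⁰ mm and
returns the deformed lumen perimeter plus the transmural stress profile
(`σr = −P` at the lumen and `0` at the outer surface). Dynamic inertial
effects, non-circular cross-sections, residual-stress opening angles and
fluid–structure interaction are out of scope: the inverse algorithm
consumes only two static perimeters, which this model supplies. Verified
oracles: dense-trapezoid integration agrees to 10⁻⁶ relative; in the
thin-wall regime (thickness/radius = 0.01) the mean hoop stress matches
the Laplace estimate `P·r/t` within 5 %.

### Zero-pressure geometry

The unloaded reference state is built from the imaged geometry by a
circumferential shrinkage ratio `S ∈ (0, 1]`: the unloaded inner radius is
`S · reference_perimeter/(2π)`. The reference perimeter defaults to the
maximum (systolic) perimeter; only the product `S × reference` enters the
mechanics, so this convention rescales the reported `S`, not the recovered
material. The unloaded wall thickness follows from wall-area conservation
under the axial shrink (`area₀ = λz · area_in-vivo`), the convention
consistent with incompressibility; the in vivo wall area is built from the
reference radius and the measured thickness.

## Inverse estimation: the triple-loop algorithm

With only two observed states (diastole → minimum perimeter, systole →
maximum perimeter), exactly two quantities are identifiable in the inner
loop: the shrinkage `S` and a stiffness scale `k` that multiplies
`(c1, D1, K1)` of the initial guess while `D2`, `K2` and `θ` stay fixed.
The admissible set is `0 < S ≤ 1`, `k > 0`.

**Inner loop.** Homogeneity makes the solve essentially closed-form: the
pressure needed to hold a fixed deformed radius scales exactly with `k`,
and both observed radii are fixed by the measured perimeters, so `k`
cancels from the pressure ratio. `S` therefore solves the scalar equation

$$
\frac{p_{sys}(S)}{p_{dia}(S)} = \frac{P_{sys}}{P_{dia}},
$$

where `p_x(S)` is the unscaled equilibrium pressure holding the observed
radius for the zero-pressure geometry built from `S`; then
`k = P_dia / p_dia(S)` directly. An earlier design nested two 1-D root
finds (solve `S` on the diastolic match for trial `k`, bisect `log k` on
the systolic residual, assuming that residual decreases monotonically in
`k`); implementation showed the premise false — the systolic residual is
unimodal in `k`, the true solution can sit at a tangency or on the rising
branch, and the `S ≤ 1` constraint can truncate the falling branch — so the
ratio elimination, which is exact, replaced it.

**Identifiability.** The ratio residual is U-shaped in `S`: it blows up
deep in the exponential-stiffening regime (small `S`) and at the
zero-holding-pressure boundary (large `S`). Up to two exact `(S, k)`
solutions can therefore exist. All admissible roots are located on an
80-point scan plus bracketed root-finding (tolerance 10⁻¹³), and the
solution requiring the smallest proportional adjustment of the initial
guess (minimal `|log k|`) is selected — the natural reading of an
algorithm that "proportionally adjusts" an initial guess assumed close to
the truth. Two consequences are documented rather than hidden: (i)
initialized at the generating parameters, the true solution is always
selected (it has `k = 1`); (ii) invariance of the recovered products
`(c1·k, D1·k, K1·k)` to a rescaling of the initial guess is exact whenever
the solution is unique, but an extreme rescaling can switch the selected
root when two exist. Every feasible solution is verified by full inflation
solves at both pressures (relative perimeter tolerance 10⁻⁵).

**Middle and outer loops.** If no admissible solution exists, the middle
loop steps `K2` on an expanding alternating schedule `+0.01, −0.01, +0.02,
…` (floored at the positive floor), and when its budget (40 steps) is
exhausted the outer loop steps `θ` by `±1°, ±2°, …` within (0°, 45°]
(44 steps) and restarts the middle loop. The first feasible solution
terminates the search; middle-before-outer nesting and first-found
termination resolve orderings the published description leaves open. The
budgets are package defaults sized so a full sweep of one subject stays in
seconds; both are configurable via `iteration_config()`.

## Stiffness metrics and statistics

The effective Young's modulus is the slope of the proportional (zero
intercept in `λ − 1`) least-squares fit to the Cauchy stress–stretch curve
over `λ ∈ [1.0, 1.3]` (31 uniform points): `E = Σσᵢ(λᵢ−1)/Σ(λᵢ−1)²`. The
anchored, intercept-free form follows from stress vanishing at `λ = 1`.
The default loading protocol is strip-biaxial (transverse in-plane stretch
held at 1): of the candidate protocols, it is the one that reproduces the
packaged reference moduli from their own parameter sets — to 0.03–0.4 %
for five of the ten reference specimens, within ~13 % for the rest —
whereas equibiaxial loading is ~50 % off; `uniaxial` and `equibiaxial`
remain available. The anisotropy index is
`AI = (YMc − YMa) / ((YMc + YMa)/2)`, bounded in (−2, 2) and zero for an
isotropic response.

Because both moduli are homogeneous of degree one in the stress-like
triple, an inverse estimate initialized at a subject's own ex vivo
parameters has `YM_in-vivo = k · YM_ex-vivo` in both directions exactly,
so both relative errors equal `100(k − 1)` — the in vivo/ex vivo modulus
ratio *is* the recovered `k`.

Group summaries use the median with interquartile range; quantiles
interpolate order statistics at positions `1 + (n−1)q` (type 7), the
convention pinned by reproducing the packaged Q1/Q3 of the reference
relative-error column. Paired comparisons use the exact one-sided Wilcoxon
signed-rank test: zero differences are dropped, tied magnitudes get average
ranks, and the null distribution of the rank sum is enumerated exactly over
all `2ⁿ` sign assignments (computed through the rank generating function
over doubled ranks, which equals the explicit enumeration; the test suite
checks it against a literal `2ⁿ` loop). The effect size is
`r = Φ⁻¹(1 − p)/√n` from the exact p — the formula consistent with all
four reference effect sizes; it is reported as `NA` when `p` reaches a
boundary.

## Synthetic data

`cohort_spec()`/`generate_subject()` create virtual subjects with known
ground truth: true parameters sampled log-uniformly for the stress-like
coefficients (they span three orders of magnitude across real specimens)
and uniformly for `D2`, `K2`, `θ`; reference perimeter 8–15 cm, thickness
1.2–2.8 mm, systolic pressure 79–140 and diastolic 45–91 mmHg, true
shrinkage `S* ∈ [0.55, 0.90]` — the spans of the packaged clinical cohort.
The zero-pressure tube built from the truth is inflated at both pressures
to produce the observed perimeters; optional multiplicative noise
(echo-tracing error scales with size) defaults to CV 0 for exact
round-trip testing and 1 % for robustness studies. Generation is
deterministic per `(seed, index)` and never disturbs the caller's RNG
stream. What the generator does *not* emulate: non-circular lumen
contours, segmentation bias, intra-observer variability, axial-stretch
uncertainty, regional wall heterogeneity — so passing round-trip tests
demonstrate correctness of the estimation machinery under the model's own
assumptions, not robustness to real imaging artifacts.

On a 40-subject noiseless cohort initialized at the truth, the triple loop
recovers `k` within 1 % and `S` within 0.5 % for at least 95 % of
subjects (the rare misses are near-tangency geometries where the two
solution branches almost touch and the root loses conditioning).

## Numerical choices

* Quadrature order 16 for the pressure integral; root tolerances 10⁻¹⁰ mm
  (inflation), 10⁻¹³ (shrinkage ratio equation); perimeter feasibility
  tolerance 10⁻⁵ relative. All configurable.
* Gauss–Legendre reference nodes are memoized per order; the inner loop
  needs only two quadrature evaluations per trial `S`, so a full cohort
  estimate runs in seconds.
* The biaxial stretch solves use damped Newton with finite-difference
  Jacobians and load-path continuation; divergence raises an error naming
  the protocol and step.
* Table-style output rounds half away from zero (`round_half_away()`),
  matching how the packaged reference tables print.

## Known limitations

* The tube idealization cannot reproduce every clinical subject: one
  packaged reference subject (AD5, the largest cyclic distension, 22.5 %)
  is infeasible for every initial setting because its achievable
  pressure ratio never reaches the measured one and its near-zero `K1`
  makes the anisotropy-correcting loops inert. The cohort function flags
  such rows and continues.
* With two observations the inverse problem can be two-rooted; see the
  identifiability discussion above.
* A few printed values in the packaged reference tables are not
  self-consistent (one relative-error entry disagrees with its own printed
  moduli); the deterministic checks use the self-consistent entries and
  treat the printed columns as verbatim inputs for the summary statistics.
* Axial stretch is fixed, the wall is single-layered and homogeneous, and
  residual stress is ignored — all standard simplifications for this class
  of estimator.
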