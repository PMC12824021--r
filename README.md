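# aortafit

Non-invasive estimation of anisotropic material properties of the human
ascending aorta.

Pre-operative knowledge of a patient's aortic wall stiffness matters for
assessing dissection risk, but the reference measurement — planar biaxial
tensile testing — needs excised tissue. `aortafit` estimates the
anisotropic constitutive parameters of an ascending aorta *in vivo*, from
measurements available without surgery: systolic/diastolic cuff pressure,
the minimum and maximum lumen perimeter over a cardiac cycle (from
echocardiography), and wall thickness. It is aimed at cardiovascular
biomechanics researchers who want a desk-scale, fully scriptable version
of this class of inverse estimator, with synthetic-data generators that
make every step testable against known ground truth.

## The model and the algorithm

The wall is an incompressible anisotropic Mooney–Rivlin solid with two
collagen-fiber families at ±θ from the circumferential direction:

    W = c1 (I1 − 3) + D1 (exp(D2 (I1 − 3)) − 1)
        + K1/(2 K2) [exp(K2 (J4 − 1)²) + exp(K2 (J6 − 1)²) − 2]

with parameters c1, D1, K1 (kPa), D2, K2 (dimensionless) and the fiber
half-angle θ (degrees). Three layers sit on top of the constitutive core:

* **Biaxial laboratory** — simulation of the standard five force-ratio
  protocols (1:1, 1:0.75, 0.75:1, 1:0.5, 0.5:1, maximal force 2 N) and
  bounded least-squares identification (`fit_biaxial()`).
* **Forward model** — quasi-static inflation–extension of an
  incompressible thick-walled tube at axial stretch 1.25, mapping a
  zero-pressure geometry and a luminal pressure to the deformed lumen
  perimeter (`inflate()`).
* **Inverse estimator** — a triple-loop algorithm (`estimate_invivo()`)
  recovering the circumferential shrinkage ratio S ∈ (0, 1] (imaged →
  zero-pressure geometry) and a stiffness scale k > 0 applied to
  (c1, D1, K1), by matching both measured perimeters at both pressures;
  corrective middle/outer loops step K2 (by 0.01) and θ (by 1°) when the
  inner problem is infeasible.

Stiffness is compared via effective Young's moduli (proportional fit of
the stress–stretch curve over λ ∈ [1.0, 1.3]), the anisotropy index
AI = (YMc − YMa)/((YMc + YMa)/2), and exact one-sided Wilcoxon
signed-rank statistics. See the methods vignette
(`vignettes/aortafit-methods.Rmd`) for assumptions, numerical choices and
known limitations.

## Worked example

Estimate the in vivo properties of reference subject AD1 (cuff pressure
133/76 mmHg, lumen perimeter 12.62–13.88 cm, thickness 2.42 mm), using
its own ex vivo biaxial fit as the initial guess:

```r
library(aortafit)
subs <- reference_subjects()       # packaged clinical cohort
exv  <- exvivo_params_list()       # packaged ex vivo parameter sets
fit  <- estimate_invivo(subs$AD1, exv$AD1)
summary(fit)
#> In vivo estimate for subject AD1
#>   S = 0.6243 (shrinkage 62.43%), k = 0.7191
#>   loops: inner 1, middle 0, outer 0
#> Anisotropic Mooney-Rivlin parameters
#>   c1 = 1.9394 kPa, D1 = 10.8815 kPa, D2 = 0.9272
#>   K1 = 1.5620 kPa, K2 = 0.9338, theta = 5.56 deg
#>   YMc = 130.51 kPa, YMa = 103.07 kPa, AI = 0.23
```

Read: the imaged geometry must be shrunk to 62 % of its reference
perimeter to obtain the unloaded state, and the in vivo wall is about 28 %
softer than the excised specimen (k = 0.72) — the in vivo/ex vivo modulus
ratio equals k exactly, a consequence of the model's homogeneity in the
stress-like coefficients. The inner loop converged directly (no K2/θ
corrections), and the anisotropy index 0.23 matches the ex vivo value.

Cohort-level statistics from the packaged reference results:

```r
m01 <- aorta_fixture("stiffness_m01")
wilcoxon_exact(m01$YMc_invivo_kPa, m01$YMc_exvivo_kPa, "less")
#> Exact Wilcoxon signed-rank test (one-sided, less)
#>   n = 10 non-zero pairs, W = 0, p = 0.0009766, effect size r = 0.979
```

Synthetic round trip (known truth, noiseless observations):

```r
spec <- cohort_spec(n_subjects = 1, seed = 42)
gs   <- generate_subject(spec, 1)
fit  <- estimate_invivo(gs$subject, gs$params)
c(S_true = gs$S, S_hat = fit$S, k_hat = fit$k)
```

A thin command-line wrapper ships in `inst/cli/aortafit` with subcommands
`fit-biaxial`, `simulate`, `estimate`, `moduli` and `check-published`.

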