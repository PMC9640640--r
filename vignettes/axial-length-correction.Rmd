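---
title: "Axial-length measurement bias and IOL power calculation: methods"
author: "alcorrect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axial-length measurement bias and IOL power calculation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcorrect)
```

## The problem

Optical biometers based on partial coherence interferometry display the
axial length (AL) of an eye under a mode-specific conversion: phakic
(natural lens), aphakic (no lens), or pseudophakic (IOL in place, here
the acrylate variant, which adds a fixed 0.1 mm to the raw optical
reading). When the same eye is measured before and after cataract
surgery, the postoperative pseudophakic reading sits systematically about
0.11 mm *below* the preoperative phakic reading, while the aphakic
reading agrees with the phakic one. Because every modern IOL power
formula is calibrated on AL, a 0.11 mm systematic shift propagates into
roughly a quarter diopter of refractive prediction error — the same order
as the error the surgeon's lens-constant optimization is meant to remove.

`alcorrect` implements the full retrospective pipeline used to quantify
this effect and to correct it: the published vergence formulas, the
prediction-error back-calculation, lens-constant optimization by
mean-error zeroing, a linear AL correction (ALc), the accompanying
statistical battery, and a synthetic cohort generator so that every stage
is testable without patient data.

## The formulas

Three published thin-lens vergence formulas are implemented in closed
form, plus a dispatcher:

* **SRK/T** — corneal radius $r = 337.5/K$, a quadratic AL correction
  above 24.2 mm, corneal width and dome height leading to an ELP estimate
  driven by the A-constant, retinal thickness added to form the optical
  AL, and a Gaussian vergence solution with aqueous index 1.336 and
  corneal index 1.333.
* **Hoffer Q** — a personalized-ACD (pACD) chain with the published AL
  clamp to [18.5, 31] mm, the short/long-eye branch switching at 23 mm,
  and tangent terms whose arguments are **degrees** (the most common
  implementation bug; stated explicitly here). The power equation is
  solved for the corneal-plane refraction in closed form and converted to
  the spectacle plane.
* **Holladay 1** — anatomical ACD from corneal geometry (radius floored
  at 7 mm, chord capped at 13.5 mm) plus the surgeon factor (SF),
  corneal index 4/3, optical AL = AL + 0.2 mm.
* **Combo** — Hoffer Q below 23.00 mm of the AL reading used for the
  prediction, SRK/T at or exactly above it.

All predicted refractions are referenced to the spectacle plane at a
12 mm vertex distance (configurable in the vertex converter); Hoffer Q's
closed form works at the corneal plane and is converted afterwards, a
choice we document because the original publication is ambiguous about
the reference plane. The standard affine conversions
$\mathrm{SF} = 0.5663A - 65.60$ and $\mathrm{pACD} = 0.58357A - 63.896$
tie the three constants to a single A-constant. Only the published
Hoffer Q AL clamp is applied; some third-party implementations also clamp
the ACD to [2.5, 6.5] mm, which we do not adopt. Long-eye AL adjustments
of the Wang–Koch type are deliberately out of scope, as are formulas that
require anterior chamber depth (unreliable in pseudophakic eyes) and
unpublished formulas that exist only as web calculators.

Every closed form is verified, in the test suite, against an independent
Gaussian vergence propagation: a trial spectacle refraction is vertex-
converted, refracted by the cornea as a thin lens, translated as a
reduced vergence to the formula's ELP, refracted by the IOL, and required
to focus at the formula's optical AL; the refraction is found by
bisection. Agreement is required to $10^{-6}$ D over 1,000 random inputs
per formula, and each formula's emmetropia power must return a predicted
refraction of zero to $10^{-9}$ D. The SRK/T long-eye polynomial has a
small known discontinuity at 24.2 mm (about 0.0015 mm in LCOR); the test
records the actual jump rather than pretending it is zero.

## The calibration chain

The refractive prediction error of an eye is
$\mathrm{PE} = \mathrm{SE}_{\text{achieved}} - \mathrm{SE}_{\text{predicted}}$,
where the prediction uses the implanted power, the AL reading of the
chosen measurement option, and the *preoperative* keratometry (the
keratometry change after surgery is not significant). Mean error (ME),
its SD, and the median absolute error (MedAE) summarize a cohort.

Lens-constant optimization ("goal seek") finds the constant that zeroes
the cohort ME, by bracketed root finding: ME is strictly monotone in each
constant, so the root is unique. The variable is the A-constant for
SRK/T, the pACD for Hoffer Q, the SF for Holladay 1; for Combo a single
A-constant is optimized with the pACD tied through the affine conversion,
consistent with reporting a single optimized pair for that method. The ME
tolerance is $10^{-4}$ D (reported MEs are 0.00 at two decimals by
construction), the bracket defaults to ±3 A-units or ±1.5 mm, and a
bracket without a sign change is an error that reports the ME at both
ends rather than silently extending.

The AL correction itself is an ordinary least-squares regression of the
postoperative pseudophakic reading on the preoperative phakic reading,

$$\mathrm{ALc} = a + b \cdot \mathrm{AL},$$

applied to preoperative ALs before formula evaluation. Its headline
property, tested on synthetic cohorts: the ME computed with ALc-corrected
preoperative ALs agrees with the ME computed from actual postoperative
pseudophakic readings to within twice the standard error of the ME, for
every formula — the correction removes the instrument's systematic error
without touching the lens constant.

## Statistical protocol

Normality is screened with the exact one-sample Kolmogorov–Smirnov test
against a normal with the sample mean and SD. Estimating the parameters
from the same sample makes this nominal test conservative (the
Lilliefors effect); `ks_normality(x, lilliefors = TRUE)` provides the
corrected variant, and the default mirrors the nominal method for
comparability with common clinical practice. Paired and one-sample
t-tests are two-sided with $n-1$ degrees of freedom; constant non-zero
differences raise an error rather than returning an infinite statistic.
Absolute errors across the three AL options are compared with the
Friedman test (average-rank ties) followed by pairwise rank-sum
comparisons $z = |R_i - R_j| / \sqrt{nk(k+1)/6}$ with Bonferroni
multiplication capped at 1 — the post-hoc is not standardized in the
clinical literature, so this SPSS-style choice is isolated in one
function and swappable. Bland–Altman agreement uses bias ± 1.96 SD of the
paired differences (the normal quantile, per standard practice, not a t
quantile). The paired-design sample size is the smallest $n$ whose
two-sided paired t-test power, computed from the noncentral t
distribution with noncentrality $\delta\sqrt{n}/\sigma$, reaches the
request; the search starts at the normal-approximation lower bound
$\lceil ((z_{1-\alpha/2}+z_{\text{power}})\sigma/\delta)^2 \rceil$ and
increments, guaranteeing the minimal integer. For $\delta = 0.02$ D,
$\sigma = 0.08$ D, $\alpha = 0.05$, power 0.80 this yields 128 eyes
(bound: 126).

```{r power}
paired_t_sample_size(delta = 0.02, sigma = 0.08, alpha = 0.05, power = 0.80)
```

## The synthetic cohort generator

`generate_cohort()` emulates a 201-patient cohort (one operated and one
fellow eye each): true AL from a truncated normal, mean 23.59, SD
1.35 mm, truncated to the observed range [20.3, 32.2] mm; keratometry
mean 43.98, SD 1.56 D, truncated to the observed [40.1, 48.1] D. The
displayed pseudophakic reading anchors the operated eye at its true AL;
phakic and aphakic readings sit +0.11 mm above it with 0.07 mm paired
reading noise; fellow eyes repeat their phakic reading with 0.05 mm
noise. Keratometry changes by N(0, 0.39) D in operated and N(0, 0.36) D
in fellow eyes. The implanted power targets −0.25 D by the generating
formula (SRK/T with A = 119.30 by default) from the phakic reading,
rounded to 0.5 D steps; the achieved refraction is the generating
formula's prediction from the pseudophakic reading plus a +0.25 D
constant bias (emulating un-optimized catalog constants) and N(0, 0.35) D
refraction noise; 133/201 of eyes reach a stable refraction. The
refractive target, refraction noise and bias magnitude are not dictated
by any printed summary; they are typical clinical values, chosen once and
fully configurable, with the bias sized to reproduce the order of
magnitude (0.2–0.4 D) of catalog-constant MEs.

Cohorts are byte-reproducible from the seed, and
`expected_cohort_summaries()` returns the closed-form expectations the
configuration implies, for use in tests.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: anchoring the pseudophakic reading noise-free
makes the Ps option systematically the most accurate, so the near-parity
of MedAEs across options seen in real cohorts (where all three readings
carry measurement noise) is **not** reproduced; absolute-error
comparisons between options on synthetic data overstate the advantage of
the pseudophakic reading. There is also no cataract-density model, no
exclusion pathway (glaucoma, prior refractive surgery), no measurement
failures, and no correlation between AL and keratometry.

## Numerical choices and degenerate inputs

* AL plausibility range [15, 40] mm; out-of-range values are validation
  errors, never clamps.
* SRK/T's corneal-height square root is guarded: a steep cornea with
  $r^2 < C_w^2/4$ clamps the discriminant to zero with a warning;
  Holladay 1's analogous geometry failure is an error, since its chord
  cap normally prevents it.
* Rounding happens only at serialization (2 decimals for diopters and
  mm), never inside computations.
* Root finding uses bracketed methods exclusively; constant optimization
  tolerance is $10^{-6}$ on the constant and $10^{-4}$ D on the ME.

## Worked example

```{r example}
params <- generator_params(n_patients = 60)
cohort <- suppressWarnings(generate_cohort(params, seed = 42))
op <- subset(cohort, eye_role == "operated")

# mode-offset recovery
round(mean(op$al_post_pseudophakic - op$al_pre_phakic), 3)

# the ALc regression
fit <- fit_al_correction(op$al_pre_phakic, op$al_post_pseudophakic)
fit

# formula evaluation with and without mean-error zeroing
tab <- suppressWarnings(
  evaluate_options(cohort, formulas = c("srkt", "hofferq"),
                   constants = lens_constants(119.30)))
print(tab[, c("formula", "al_option", "me", "medae", "optimized_constant",
              "me_opt")], digits = 2)
```

The test suite exercises the full default-size cohort (201 patients);
the smaller cohort above keeps the vignette quick to run. Simulation-
based checks in the suite use 1,000 random formula inputs, 1,000 null
replications for t-test calibration, and 100 seeds for the normality
screen — sizes at which the Monte Carlo error is far below every
tolerance asserted.

## Known limitations

The instrument's per-mode AL computation is not public; the additive
offset model is an explicit simplification, with offsets as
configuration. The generator calibrates to printed summary statistics
only — no per-eye data exist publicly — so distributional fine structure
(skewness of AL, AL–K correlation) is not reproduced. The Hoffer Q
reference-plane choice and the Friedman post-hoc are documented,
swappable decisions rather than settled conventions.
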