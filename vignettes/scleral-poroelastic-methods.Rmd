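---
title: "Methods: poroelastic characterization of scleral compression tests and the cohort statistics around them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poroelastic characterization of scleral compression tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclerafit)
```

## The measurement problem

Unconfined compression stress relaxation is a standard way to characterize
soft hydrated tissues: a small cylindrical button (here a 1-mm punch of
posterior mouse sclera) sits between two impermeable, lubricated platens in
a saline bath at 37 °C. After a small tare load (500 µN) flattens the
sample, cumulative compressive strain steps of 5% each (to 15% maximum) are
applied as fast ramps and held until the load equilibrates. The transient
load decay during each hold is carried by interstitial fluid pressure and
its dissipation by radial fluid outflow; the equilibrium load is carried by
the solid matrix alone.

The sclera is strongly tension–compression nonlinear: compressing it
through-plane stretches the collagen lamellae in-plane. A conewise-linear
biphasic description therefore uses different aggregate moduli for in-plane
tension and axial compression. `sclerafit` adopts the following normative
model (the literature source of the protocol names the model but prints no
equations, so the governing system is fixed here explicitly):

* axisymmetric linear biphasic cylinder, radius $a$, radial fluid flow only;
* transversely isotropic effective solid stress about the loading axis with
  $C_{11} = H_{+A}$ (radial/hoop, in tension during axial compression),
  $C_{33} = H_{-A}$ (axial, in compression), and off-diagonal coupling
  $C_{12} = C_{13} = \lambda$, default $\lambda = 0$;
* total stress $\sigma = \sigma^{\mathrm{eff}} - p\,I$; Darcy flux
  $w = -k\,\partial p/\partial r$; incompressible mixture continuity;
* boundary conditions $p(a,t) = 0$ (free-draining lateral edge), zero total
  radial stress at $r=a$, regularity at $r=0$, impermeable frictionless
  platens (the protocol applies graphite powder for this reason);
* axial load $F(t) = 2\pi \int_0^a \sigma_{zz}\, r\,\mathrm{d}r$.

With $\lambda = 0$ the radial momentum balance decouples from the axial
one and the areal strain $e = \frac{1}{r}\partial_r(ru)$ obeys a pure
radial diffusion equation with diffusivity $D = H_{+A} k$. The transient is
a two-parameter family in $(H_{+A}, k)$ and the equilibrium load is
$H_{-A}\,\varepsilon\,\pi a^2$, governed by $H_{-A}$ alone — exactly
matching the per-step reporting convention (one $H_{+A}$ and one $k$
estimate per strain step plus an equilibrated stress).

### Semi-analytic solution

For a step of strain the load admits the Bessel series

$$F(t) = \pi a^2 \varepsilon \left[ H_{-A} + H_{+A} \sum_{n\ge1}
\frac{e^{-\alpha_n^2 t/\tau_g}}{\alpha_n^2 - 1} \right],
\qquad \tau_g = \frac{a^2}{H_{+A} k},$$

where $\alpha_n$ are the roots of $J_1(x) = x\,J_0(x)$ (equivalently the
zeros of $J_1'$), bracketed between consecutive zeros of $J_0$ and refined
by bisection. The instantaneous (isochoric) stiffness is
$H_{-A} + H_{+A}/2$, so the peak/equilibrium ratio grows with
$H_{+A}/H_{-A}$ — the feature the inverse problem keys on. Finite ramps
are handled by Duhamel superposition of this step response against the
constant ramp rate, which also accelerates series convergence from
$O(\alpha^{-2})$ to $O(\alpha^{-4})$; 200 terms are used for simulation and
80 during fitting (the truncated tail is far below solver tolerance).
Multi-step protocols superpose per-step strain increments.

### Independent finite-difference oracle

`fd_oracle_response()` is deliberately series-free: backward-Euler time
stepping of the $e$-diffusion equation on a uniform radial grid, with the
axisymmetric Laplacian, a symmetry row at $r=0$, and the *nonlocal*
boundary row $e(a) = a^{-2}\int_0^a e\,r\,\mathrm{d}r$ implied by zero
radial stress plus zero edge pressure (trapezoid quadrature). The two
solvers agree to about 0.03% relative RMS at default resolutions; the
acceptance suite sweeps $H_{+A}/H_{-A} \in \{1,2,5,10\}$ and
$\tau_g/t_{\mathrm{ramp}} \in \{0.1, 1, 10\}$ and requires 1%.

### Fitting conventions

* **Strain convention.** Engineering compressive strain relative to the
  post-tare thickness, cumulative across steps (5/10/15%).
* **Per-step linearization.** Each step is fit independently on its
  *incremental* strain and *incremental* load (relative to the previous
  step's equilibrium), so strain-dependent properties appear as per-step
  parameter trends rather than a finite-deformation model. The cumulative
  strain is carried as the covariate for statistics.
* **Equilibrium window.** The last 10% of each hold; $H_{-A}$ comes from
  the closed-form equilibrium ratio, exactly, before the transient fit.
* **Transient fit.** Least squares on load (N), uniform weights, first 2
  ramp samples dropped (actuator transients). $(H_{+A}, k)$ are fit in
  log-space (positivity); initialization is deterministic: $H_{+A}$ from
  the peak/equilibrium ratio via the instantaneous-stiffness relation, $k$
  from matching $\tau_g$ to the 63%-relaxation time through $\alpha_1^2$.
  Fixed multi-start perturbations (±half a decade in $k$, 2× in $H_{+A}$)
  guard against local minima; the best two starts are polished
  (Nelder–Mead then BFGS). No randomness anywhere in the fit.
* **Degenerate transients.** If the peak/equilibrium ratio is below 1.02
  the transient carries no information about $(H_{+A}, k)$ and the step is
  returned with `converged = FALSE`, reason `"insufficient transient"`.

Noise-free round trips recover parameters to ~10⁻⁷ relative; the stated
acceptance tolerance is 0.5%.

### Units

Hydraulic conductivity is stored in m⁴ N⁻¹ s⁻¹ (≡ m² Pa⁻¹ s⁻¹). Source
tables for this assay sometimes print "m⁴/Pa·s", which is dimensionally
inconsistent with Darcy's law as written; the magnitudes (~10⁻¹⁴) match
the conventional biphasic unit, which is the reading adopted here.

### The coupled material ($\lambda \neq 0$)

`cle_parameters()` carries `lambda_offdiag` so data structures can describe
the more general conewise material, but both solvers implement only the
uncoupled case and refuse nonzero values. With coupling, the equilibrium
response is no longer $H_{-A}$-only and the radial problem no longer
reduces to a single diffusion equation; since the reported quantities are
exactly $(H_{+A}, k)$ per step plus an equilibrium stress, the uncoupled
model is the minimal one consistent with the measurement, and implementing
the coupled solver would add parameters the data cannot identify.

## Biometry statistics

Ocular biometry is derived from six delineated A-scan interface positions
(anterior/posterior cornea, anterior/posterior lens, vitreoretinal
interface, RPE). Optical path lengths are converted to geometric lengths
with a single average refractive index of 1.39 applied to all segments.
Axial length is defined corneal surface to RPE, so
AL = CCT + ACD + LT + VCD + RT holds exactly for any record derived from
one interface set.

Two longitudinal statistics are used, both computed on per-animal values
that average the two eyes (a remaining eye stands in for the animal when
the fellow eye is excluded for opacity):

* **shift**$_i(t) = x_i(t) - \bar{x}_{\mathrm{Ctrl}}(t)$ — the
  between-group statistic; the control-group mean shift is 0 by
  construction;
* **Δ**$_i(t) = x_i(t) - x_i(t_0)$ — the within-animal change from
  baseline; exactly 0 at baseline and invariant to per-animal constants.

## Group-comparison models

Outcomes are compared with generalized linear models: gamma error with log
link for strictly positive outcomes (moduli, conductivity, lengths) and
gaussian for refractive error (which crosses zero). Fixed effects are
treatment, a covariate (strain % or timepoint), their interaction, and
optionally a centered age-deviation covariate. Significance uses
likelihood-ratio tests against null models lacking one term.

**Random intercepts.** Full REML mixed-model machinery is not
re-implemented. On one-value-per-animal designs (eye-averaged biometry) a
fixed-effects GLM has the same point estimates in balanced cases. For
repeated measures within a sample (three strain steps per button) a
cluster-robust (CR0, G/(G−1)-corrected) covariance is the documented
stand-in, preserving point estimates and the contrast structure while
keeping the package self-contained. This is a deliberate scope decision;
an external mixed-model backend can be substituted on the same interfaces.

**Estimated marginal means.** Group means are evaluated at exact target
covariate values (0/5/10/15% strain) on the response scale via the inverse
link, with delta-method standard errors; treated-minus-control contrasts
are formed at each value. 0% strain lies outside the observed range and is
flagged as an extrapolation.

**Multiplicity.** Families of correlated contrasts are adjusted by the
multivariate-t (max-|t|) method: Monte Carlo under the joint t implied by
the contrast correlation (fixed internal seed, ≥10⁵ draws; the caller's
RNG stream is preserved). Adjusted p is forced ≥ raw p and monotone in it;
a singular correlation falls back to Bonferroni with a warning. For
independent contrasts the method reproduces Šidák within Monte-Carlo error
(exactly so as df → ∞; at finite df the shared scale induces a small
dependence, which is the textbook behaviour of this adjustment).

## Assays

Standard curves are straight lines (ordinary least squares) on the stated
working ranges (8 standards; 0–4 for the DNA assay, 0–25 for sulfated
GAGs); the functional form is not stated by the protocol, and a pronounced
lack of fit raises an error rather than silently switching to a 4PL. The
blank is the zero-concentration standard, subtracted before inverse
prediction. Triplicates are averaged; digest concentration is intensive,
so the measured mass fraction (µg analyte per mg dry sclera, via the
200 µL digest volume) is invariant to how the digestate is split between
the two assays. GAG/DNA ratios are computed per eye, not as a ratio of
group means. IHC normalized fluorescence is the masked mean intensity of
an enzyme-treated section over the buffer-only section of the same eye,
with an optional superior/inferior split at the optic-nerve landmark;
ratios are invariant to multiplicative gain but not to additive offsets
(both properties are tested). Intensities are 12-bit integers and the
saturated-pixel fraction is reported.

## What the synthetic data emulate — and what they do not

The generators produce every input the pipeline consumes, always seeded,
always shipping their ground truth:

* **Compression traces.** The forward model plus a tare phase, per-group
  per-step true parameters, optional per-sample lognormal variability
  (mean-1 multipliers with CVs matching the printed between-eye spreads),
  multiplicative load noise and an additive sensor floor. Default group
  means are the printed ones: treated $H_{+A}$ 104 kPa, $k$ 0.96×10⁻¹⁴;
  control 160 kPa, 0.73×10⁻¹⁴. The default per-step trends are linear and
  centred on those means, with the treated arm stiffening less and losing
  less conductivity under strain, qualitatively matching the reported
  interactions; $H_{-A}$ defaults to a flat 30 kPa (not printed by the
  study; typical for compressive equilibrium moduli of fibrous soft
  tissue). Step increments are superposed assuming the previous hold fully
  equilibrated — the same linearization the fit makes.
* **Cohort.** Control n = 14, treated n = 16, three timepoints. Outcome
  values are baseline mean + animal intercept + control drift + treated
  offset (scaled by a mean-1 per-animal response heterogeneity) +
  animal×time noise + eye noise. Drifts and offsets default to the printed
  group effects (e.g. VCD shifts +20.7/+32.3 µm; RE shifts −3.7/−5.7 D;
  AL growth 82.6/132.1 µm control vs 90.9/145.0 µm treated). Baseline
  means are not printed and are set to representative 4-week mouse values
  (AL 3320 µm, VCD 830 µm, RE +2.5 D, ...). The three noise SDs per
  outcome were chosen once so the generated 2-week shift and Δ SDs
  approximate the printed ones (e.g. VCD shift SD ≈ 24.5 vs 24.8 printed;
  AL Δ SD ≈ 15–16); earlier-timepoint SDs are then only approximate.
* **Plates and images.** Linear response with configurable slope/intercept
  and gaussian absorbance noise; 12-bit images with a scleral band, an
  optic-nerve landmark column and Poisson counts.

A green recovery test therefore establishes that the pipeline inverts its
own stated model at the study's design sizes — not that the model is the
right description of real sclera, nor that instrument artifacts
(drift, friction, imperfect ramps, delineation error) are handled beyond
the specific degeneracies tested.

## Numerical choices

* Characteristic roots cached per session; bisection to 10⁻¹⁴.
* FD solver: implicit Euler (unconditionally stable), default
  `dt = min(ramp/20, τ_g/400)`, 150 radial intervals; divergence raises an
  error naming the offending step.
* Equilibrium detection: mean over the final 10% of each hold; tare drift
  beyond ~10⁻⁸ N/s is flagged but not fatal.
* Applied strains outside 0.5–1.5× target are flagged, not dropped.
* All SI internally; CSV interfaces use µm and µN for instrument
  compatibility.

## Known limitations

Finite deformation, intrinsic solid viscoelasticity, strain-dependent
permeability and platen friction are out of scope. The cluster-robust GLM
stand-in gives conservative-to-approximate inference relative to a true
random-intercept likelihood when designs are unbalanced. The incremental
(per-step) fitting convention is one of two defensible readings of
"independently fit to each step"; the total-stress alternative can be
assembled from the same primitives but is not the default.
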