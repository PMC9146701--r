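---
title: "Methods: local flow curves, breakdown kinetics and NMR droplet sizing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local flow curves, breakdown kinetics and NMR droplet sizing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emulsionrheo)
```

`emulsionrheo` analyses the time-dependent yield-stress behaviour of
concentrated oil-in-water emulsions from three measurement families:
rheo-MRI velocimetry with concurrent torque, pulsed-field-gradient (PFG)
NMR droplet sizing, and two-dimensional D-T~2~ relaxometry. This
vignette records the models, the assumptions behind them, the tunable
parameters with their defaults, and the numerical decisions the package
makes — including the places where the design was genuinely open and a
choice had to be made.

## Couette-cell mechanics and the forward model

All rheology happens in a narrow-gap concentric-cylinder (Couette) cell,
by default 20 mm / 22 mm inner and outer diameters (1 mm gap). The
momentum balance ties the local shear stress to the measured torque
independently of the constitutive law:

$$\sigma(r) = \frac{T}{2\pi r^2 H},$$

so stress decreases as $1/r^2$ across the gap ($\approx 21\%$ over
1 mm). Two conventions are fixed here because a cell drawing alone does
not fix them:

* **Rotating wall.** The inner cylinder rotates and the outer is fixed,
  the standard rheometer configuration; velocities are positive in the
  rotation direction.
* **Cell height.** $H$ enters only through the torque conversion. The
  default $H = 40$ mm is an assumed, configurable value (flagged
  `height_assumed` in the pipeline config); every fitted quantity in
  the package uses one consistent $H$, so its choice rescales torque
  but no dimensionless result.
* **Applied shear rate.** A nominal applied rate maps to the rotor
  angular velocity by the narrow-gap convention
  $\Omega = \dot\gamma_\mathrm{app}(R_o - R_i)/R_i$
  (`rotor_rate_from_applied()`).

`couette_forward_solve()` builds synthetic measurements by inverting
this balance against the Herschel–Bulkley (HB) law
$\sigma = \tau_0 + K\dot\gamma^n$: given $\Omega$, the torque is the
root of

$$\Omega = \int_{R_i}^{\min(r_y, R_o)} \frac{\dot\gamma(r)}{r}\,dr,
\qquad
\dot\gamma(r) = \left(\frac{\sigma(r) - \tau_0}{K}\right)^{1/n}
\text{ where } \sigma(r) > \tau_0,$$

with $r_y = \sqrt{T / (2\pi H \tau_0)}$ the yield radius. When
$r_y < R_o$ the flow localizes: an inner band shears while the outer
band is rigid — the shear-banding signature of yield-stress fluids in a
Couette gap. The quadrature uses `stats::integrate` at relative
tolerance $10^{-10}$ and the torque root is bracketed from the
yield-limit torque upward, so the returned torque reproduces
$\sigma(R_i) \cdot 2\pi R_i^2 H$ to better than $10^{-8}$ relative.
Profiles are sampled at 48.8 µm, a typical rheo-MRI voxel size
(21 points across the 1 mm gap).

## Velocimetry: from v(r) to local flow curves

For azimuthal flow the deformation rate is
$\dot\gamma(r) = |r\,\mathrm{d}(v/r)/\mathrm{d}r|$. The package forms
the angular velocity $v/r$ first and differentiates it in a single
Savitzky–Golay (SG) pass — one smoothing operation instead of the
algebraically equivalent $|\mathrm{d}v/\mathrm{d}r - v/r|$ computed in
two noisy steps — so rigid-body rotation maps to exactly zero shear.
The SG filter defaults to a 7-point window with a first-order
polynomial, standard practice for megahertz-field velocimetry at this
resolution; the filter matrix comes from `signal::sgolay`, whose
transient rows are exactly one-sided least-squares fits of the same
order (verified in the tests against an explicit per-point `lm()`
polyfit to $10^{-10}$).

**Near-wall masking.** A first-order one-sided fit evaluates the window
*slope*, i.e. the derivative at the window centre, not at the endpoint.
For a curved profile this leaves a bias of order
$3h\,\omega''/\omega' \approx 9h/r \approx 3\text{–}4\%$ at 48.8 µm
resolution on the three points nearest each wall, while interior
(centred) windows are accurate to $< 0.4\%$ over the whole
$\tau_0 \in [0, 300]$ Pa, $n \in [0.3, 1]$ working range.
`assemble_lfc()` therefore excludes the $(w-1)/2$ transient points on
each side by default (`mask_edges = FALSE` restores full-gap coverage
when wall-adjacent points are wanted despite the bias). Points with
$\dot\gamma$ below a resolvability threshold (default 0.05 s⁻¹,
configurable, never hard-coded into results) are masked as well: below
the velocimetry noise floor, and beyond the yield radius, the pair
$(\dot\gamma, \sigma)$ carries no constitutive information.

## Herschel–Bulkley fitting and the global flow index

`fit_hb()` performs bounded nonlinear least squares
($\tau_0 \ge 0$, $K > 0$, $0 < n \le 2$) via Levenberg–Marquardt
(`minpack.lm::nls.lm`). Start values are deterministic — $\tau_0$ from
the smallest stress, $K$ from the log–log slope of the excess stress,
$n = 0.5$ — and the fit is repeated from three jittered starts, keeping
the smallest residual with ties broken by the smaller $\tau_0$. The
loss is plain least squares on $\sigma$; a soft-L1 option exists but is
off by default. Parameter uncertainties are 1σ values from the
Jacobian-based covariance at the optimum.

`fit_hb_global_n()` fits a time series of flow curves jointly: per-curve
$(\tau_0^t, K^t)$ with a single shared $n$, started from the median of
the per-curve indices plus three alternative $n$ starts (the shared-$n$
profile likelihood can be flat; see below). The per-curve $\tau_0^t$
sequence is the yield-stress series handed to the kinetics stage. The
joint fit can never end above the sum of per-curve fits clamped at the
shared $n$ — asserted as a test property.

**Identifiability is the honest caveat of this stage.** In a 1 mm gap
the stress varies by only 21%, so a fully yielded flow curve at one
rotor rate spans roughly a factor $1.2^{1/n} \approx 2$ in shear rate.
With noise on the *shear-rate* axis (differentiated velocity noise),
$n$ is then barely identified, and errors-in-variables attenuation
biases it low. Two design consequences:

* the default pipeline measures at **two applied rates** (5 and
  25 s⁻¹) and pools all curves in one global-$n$ fit, spanning over a
  decade of $\dot\gamma$;
* the generator's default velocity noise (0.2% of the rotor surface
  speed) describes a signal-averaged, high-SNR acquisition. At 1%
  velocity noise the recovered $n$ wanders by $\pm 0.1$ even pooled —
  a limitation of the measurement geometry, not of the optimizer
  (fits match an independent optimizer's minima in the tests), and the
  reported `n_se` reflects it. Yield-stress extraction at the high rate
  is an extrapolation from $\dot\gamma \in [17, 35]$ down to zero shear
  and inherits any error in $n$; the low-rate series is much more
  stable.

The dimensionless representation divides the viscous stress
$\tau_v = K\dot\gamma^n$ by the Laplace pressure scale:
$\tilde\tau_v = \tau_v R/\sigma_i$ against
$\mathrm{Ca} = \mu\dot\gamma R/\sigma_i$ with droplet radius $R$,
interfacial tension $\sigma_i$ and continuous-phase viscosity $\mu$.
These three material properties are user inputs
(`emulsion_properties()`): they are needed for the scaling but are not
measured by any pipeline stage. Curves sharing $(K, n)$ collapse in
this plane regardless of their yield stress.

## Structural-kinetic breakdown model

Yield-stress decay under steady shear is modelled with second-order
structural kinetics,

$$\tau_0(t) = \frac{\tau_{0,0} - \tau_{0,e}}{k_s t + 1} + \tau_{0,e},$$

fitted by bounded least squares in the parameterization
$(\tau_{0,e},\ \Delta\tau = \tau_{0,0} - \tau_{0,e},\ k_s)$, all
non-negative, so $\tau_{0,0} \ge \tau_{0,e} \ge 0$ holds by
construction. Start values: first observation, last observation,
$1/\mathrm{median}(t)$. Optional inverse-variance weights accept the
$\tau_0$ uncertainties from the flow-curve stage.

Unit policy: the fit is unit-agnostic and reports $k_s$ in the inverse
of the supplied time unit, carried in a `time_unit` field — there is no
silent conversion. For experiments spanning hundreds of minutes with
$k_s \approx 0.01$, the natural reading is per minute
($k_s t_{\max} \approx 6$, comfortably identifiable); the package's
default series uses minutes throughout. Two guard rails: a flat series
returns $k_s = 0$ with a `flat` flag instead of an arbitrary rate, and
$k_s t_{\max} < 0.1$ raises an `equilibrium_unreached` flag because the
plateau $\tau_{0,e}$ is then unconstrained. The breakdown extent
$\tau_{0,0}/\tau_{0,e}$ errors out (rather than returning infinity)
when $\tau_{0,e} = 0$.

## Murday–Cotts droplet sizing

Oil confined in an emulsion droplet diffuses restrictedly; its PGSE
echo attenuation in the Gaussian phase approximation for a sphere of
radius $R$ is

$$\ln E(g) = -2\gamma^2 g^2 \sum_m
\frac{1}{\alpha_m^4(\alpha_m^2R^2 - 2)}
\cdot \frac{2\delta - f(\alpha_m^2 D)/(\alpha_m^2 D)}{D},$$

with $\alpha_m R$ the positive roots of
$x J'_{3/2}(x) - \tfrac12 J_{3/2}(x) = 0$ (equivalently the stationary
points of the spherical Bessel function $j_1$; the first is 2.08158)
and $f$ the usual five-exponential combination in $\delta$ and
$\Delta$. Three numerical decisions matter:

* **Stable evaluation.** For spheres much larger than the diffusion
  length, $f$ cancels to $O(a\Delta)$ of itself and the naive
  expression loses all significant digits. The package evaluates the
  per-mode numerator in an exact `expm1`/difference-of-exponentials
  form that is stable in both regimes; with it, the series converges
  monotonically to the free-diffusion Stejskal–Tanner limit
  $\exp(-\gamma^2g^2\delta^2 D(\Delta - \delta/3))$ (deviation
  $6\times10^{-5}$ at $R = 200\sqrt{D\Delta}$), and tiny spheres show
  full motional narrowing ($E \to 1$).
* **Truncation control.** The default truncation is 50 roots. Terms
  fall off like $x^{-6}$, so the dropped tail is bounded by its
  integral; if that bound exceeds $10^{-5}$ of the sum, the evaluation
  either grows the truncation geometrically (inside the lognormal
  forward model, up to 4096 roots) or raises an error naming the
  truncation (in the strict single-sphere API). Spheres beyond
  $300\sqrt{D\Delta}$ short-circuit to the free-diffusion exponent,
  where the converged series agrees to $2\times10^{-5}$.
* **Lognormal convention.** Sizing is reported as a volume-weighted
  lognormal distribution over *diameter* with median $D_{3,3}$ (µm)
  and log-domain width $\alpha$. $\alpha$ is dimensionless here: a
  lognormal width printed with length units is a unit-bearing
  convention the package deliberately does not follow. The average
  uses 64-node Gauss–Legendre quadrature on $\pm4\alpha$ in
  log-diameter; doubling the nodes moves the decay by $<10^{-4}$
  (tested), and $\alpha \to 0$ degenerates exactly to the single
  sphere.

`fit_droplet_size()` inverts a measured decay over
$(D_{3,3}, \alpha)$ with bounds $D_{3,3}\in(0.1, 100)$ µm,
$\alpha\in(0,2)$, from three deterministic starts. The oil
self-diffusivity is **fixed** by default at $4\times10^{-12}$ m²/s
(vegetable oil at room temperature): at micrometre droplet sizes and
$\Delta = 211$ ms the decay constrains a *combination* of size and
diffusivity ($x_1^2 D\Delta/R^2 \sim 1$), so a joint fit is weakly
identified — and for the same reason a ±25% error in the assumed
$D_\mathrm{oil}$ biases the fitted $D_{3,3}$ by several percent to
tens of percent. The tests assert exact recovery at the correct
$D_\mathrm{oil}$ and bounded propagation under misspecification;
anyone replacing the default should use a measured oil diffusivity.
Decays whose attenuation never falls below 0.7 are rejected as
under-encoded rather than fitted. The generator's acquisition defaults
(gradient pulse width $\delta = 2$ ms, marked assumed; 32 gradient
steps from 0.1 to 3 T/m; $\Delta = 211$ ms) attenuate a 3.4 µm
emulsion to $E \approx 0.36$, a competently encoded measurement.

## 2D D-T~2~ inversion

A diffusion-encoded CPMG experiment yields a surface
$S(g, t) = \sum_k A_k e^{-b(g)D_k}e^{-t/T_{2,k}}$ with
$b(g) = \gamma^2g^2\delta^2(\Delta - \delta/3)$ — exponential in both
encoding dimensions, which is exactly the assumption the inverse
Laplace transform requires. `ilt2d()` solves

$$\min_{F \ge 0}\ \|K_1 F K_2^{\mathsf T} - S\|_F^2 + \lambda\|F\|_F^2$$

on log-spaced grids (defaults: 64 points each,
$D \in [10^{-13}, 10^{-8}]$ m²/s, $T_2 \in [1\,\mathrm{ms}, 3\,\mathrm{s}]$),
after SVD compression of both kernels (singular values below $10^{-8}$
of the largest are dropped — the data's numerically informative
subspace). The bound-constrained quadratic program is solved by
L-BFGS-B with an analytic gradient on the compressed normal equations;
compressed and uncompressed solves agree to $10^{-6}$ on strongly
convex instances (tested), and the solution is invariant under
row/column permutations of the data with their axes.

$\lambda$ is either explicit (for exact reproducibility) or chosen by
the discrepancy principle: the noise level is estimated from the tail
of the echo train at the strongest gradient, and the largest $\lambda$
whose full-space residual stays within 1.1× the expected noise norm is
selected from a geometric sweep with warm starts. Two honest caveats:

* A quadratic penalty *prefers spreading* mass across the strongly
  correlated neighbouring kernel columns: a noiseless on-grid
  component reconstructs with its maximum exactly on the true cell but
  only ~65% of its mass within ±1 cell (≥97% within ±3). Peak
  *positions* are sharp; per-cell masses are not, and the package
  reports region masses and mass-weighted centroids accordingly.
* Restricted (non-exponential) diffusion of the oil phase violates the
  kernel assumption and reconstructs as spread, partly spurious
  features at low D. Quantitative use is therefore restricted to the
  aqueous peak: `extract_water_peak()` selects, among connected regions
  above 1% of total mass, the one with the highest diffusion
  coordinate (free water diffuses orders of magnitude faster than
  confined oil), breaking ties deterministically by mass, and reports
  the region's mass-weighted T~2~.

The water T~2~ decreases linearly with dissolved-protein concentration,
so `t2_concentration_fit()` (ordinary least squares) turns T~2,w~ into a
protein-release proxy. `diffusion_length()` implements the 1D
root-mean-square convention $\sqrt{2D\Delta}$; for free water at
$\Delta = 200$ ms this evaluates to ≈19 µm — the same order as the
droplet size, which is why varying $\Delta$ moves the maps little.

## The synthetic generator: what it emulates, and what it does not

`simulate_measurements()` (and `write_fixture_bundle()`) forward-model
the complete study: Couette profiles with torque at six shearing times
and two applied rates, with the yield stress decaying along the SKM at
each rate's working point (80.1 → 44 Pa at $k_s = 0.012$ min⁻¹ for
5 s⁻¹; 99 → 27 Pa at 0.06 min⁻¹ for 25 s⁻¹; $K = 30$ Pa·sⁿ,
$n = 0.47$); before/after PFG decays (3.39 µm/0.20 → 4.30 µm/0.40);
and a two-component D-T₂ surface (water: amplitude 0.22,
$9\times10^{-10}$ m²/s, 0.4 s; oil: 0.78, $4\times10^{-12}$ m²/s,
0.12 s — amplitudes reflecting a ~78% oil emulsion) at SNR 500 with
the 0.1–6.6 T/m, 32-step, 256-echo ($t_E = 2.2$ ms) acquisition.
Noise is additive Gaussian on velocities and NMR signals
(multiplicative optional), and **every random draw requires an
explicit seed** — the config constructor refuses to run without one,
and `apply_noise()` restores the global RNG state.

What passing tests on these data do *not* show about real data: the
generator has no MRI slice profile, relaxation weighting, phase or
registration artifacts (profiles arrive as tabulated v(r)); no
instrument drift or temperature effects; droplet growth is an input,
not a coalescence model; the D-T₂ oil component is synthesized as a
single exponential pair, so the real oil phase's non-exponential
restricted-diffusion signature — the reason quantitative outputs stay
with the water peak — is not reproduced, only documented. Test problem
sizes (21-point profiles, 6 shearing times × 2 rates, 32-step decays,
64×64 inversion grids, 20–100 seeded replicates for recovery
statistics) are the package's chosen working scale: large enough for
the statistics asserted, small enough to run the whole suite in well
under a minute.

## Numerical choices and degenerate inputs, collected

* Torque root bracketing doubles the upper bound until the kinematic
  constraint is crossed; non-convergence reports the bracket.
* $\Omega = 0$ with $\tau_0 > 0$ returns the zero profile with the
  yield-limit torque $2\pi R_i^2 H\tau_0$ and a boundary flag (the
  torque is only bounded, not determined, by a non-flowing state).
* SG differentiation requires uniform spacing (relative tolerance
  $10^{-6}$) and odd windows; violations are errors suggesting
  resampling, not silent interpolation.
* Zero torque with zero velocity yields an empty (fully masked) flow
  curve, and empty curves refuse to be fitted.
* Degenerate HB input (all shear rates equal) and flat SKM series are
  explicit errors/flags, not numerical accidents.
* All-zero D-T₂ signal returns an empty map; kernel-compression rank
  collapse is an error naming the threshold.
* CSV schemas carry units in their headers (`r_m`, `v_m_per_s`,
  `t_min`, `tau0_Pa`, `g_T_per_m`, `t_s`), are written at 17
  significant digits and round-trip losslessly; readers name the
  missing column on schema violations and preserve unknown extra
  columns as metadata.

## Known limitations

* The flow index from a single narrow-gap rotor rate is weakly
  identified under realistic velocimetry noise (discussed above); pool
  rates or fix $n$ when the viscous branch is not the target.
* The high-rate breakdown extent $\tau_{0,0}/\tau_{0,e}$ is an
  extrapolated, noise-sensitive ratio when $\tau_{0,e}$ is small
  relative to the fitted stresses; its uncertainty field should be
  taken seriously.
* The lognormal-parametric droplet inversion does not attempt a
  distribution-free (regularized) size inversion.
* The ILT reports no uncertainty beyond the regularization sweep;
  treat per-cell amplitudes as a density estimate, not a measurement.
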