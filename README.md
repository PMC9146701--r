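# emulsionrheo

Concentrated oil-in-water food emulsions — mayonnaise-like systems
stabilized by egg-yolk proteins and phospholipids — lose apparent
viscosity irreversibly under prolonged mild shear. The mechanism is a
slow decay of the emulsion's *yield stress*, driven by droplet
coalescence and the release of surface-active proteins from droplet
interfaces into the aqueous phase. `emulsionrheo` implements, as a
tested R pipeline, the quantitative analysis chain that characterizes
this process from rheo-MRI and low-field NMR measurements:

1. **Velocimetry → local flow curves.** Azimuthal velocity profiles
   v(r) measured across a narrow-gap Couette cell are differentiated
   with a Savitzky–Golay filter to local shear rates
   γ̇(r) = |r d(v/r)/dr|, and paired with the torque-derived local
   stress σ(r) = T / (2π r² H) into local flow curves (LFCs).
2. **Herschel–Bulkley fits with a global flow index.** Each LFC is
   fitted with σ = τ₀ + K γ̇ⁿ; across a shear-time series the flow index
   n is shared (one global n, per-curve τ₀ᵗ and Kᵗ), so the yield-stress
   decay τ₀(t) is extracted with the viscous branch pinned. The viscous
   stress can be reported dimensionlessly as τ̃ᵥ = τᵥR/σᵢ versus the
   capillary number Ca = μγ̇R/σᵢ.
3. **Structural-kinetic model (SKM) of breakdown.** The decay is
   quantified by second-order structural kinetics,
   τ₀(t) = (τ₀,₀ − τ₀,ₑ)/(kₛt + 1) + τ₀,ₑ, yielding the breakdown rate
   kₛ and the breakdown extent τ₀,₀/τ₀,ₑ.
4. **PFG-NMR droplet sizing.** Pulsed-field-gradient attenuation decays
   of the oil phase are inverted through the Murday–Cotts
   (Gaussian-phase-approximation) model of diffusion restricted in
   spheres, averaged over a volume-weighted lognormal diameter
   distribution, giving the median diameter D₃,₃ and width α, and
   growth ratios D₃,₃/D₃,₃(0) before/after shear.
5. **2D D-T₂ relaxometry.** Diffusion-encoded CPMG surfaces S(g, t) are
   inverted by a regularized non-negative 2D inverse Laplace transform
   (SVD-compressed exponential kernels, Tikhonov penalty, discrepancy-
   principle regularization) into D-T₂ correlation maps; the
   aqueous-phase peak (D ≈ 9×10⁻¹⁰ m²/s) is extracted and its T₂,w
   calibrated linearly against dissolved-protein concentration.

A seeded synthetic-data generator forward-simulates every measurement —
Couette flow of a Herschel–Bulkley fluid (including shear localization
when the stress falls below τ₀ inside the gap), SKM yield-stress series,
restricted-diffusion PFG decays and two-component D-T₂ surfaces — so the
entire pipeline is testable end-to-end without instrument data.

## Worked example

Simulate one rheo-MRI measurement of a yield-stress emulsion, rebuild
the local flow curve, and fit it:

```r
library(emulsionrheo)

geom <- couette_geometry()        # 20/22 mm Couette cell, 1 mm gap
hb   <- hb_params(tau0 = 80.1, K = 30, n = 0.47)
sol  <- couette_forward_solve(geom, hb, rotor_rate_from_applied(5, geom))
sol
#> Couette solution: torque 0.004001 N.m, fully yielded gap

lfc <- assemble_lfc(sol$profile, sol$torque, geom)
lfc
#> Local flow curve: 15 points, gamma_dot in [3.73, 6.95] 1/s, sigma in [135.7, 154.6] Pa

fit_hb(lfc)
#> HB fit: tau0 = 80.04 +/- 2.2e-05 Pa, K = 30.01 +/- 1.8e-05 Pa.s^n, n = 0.4697 +/- 1.6e-07
```

The round trip recovers the generating law to a fraction of a percent:
the 80 Pa yield stress, consistency 30 Pa·sⁿ and flow index 0.47 are the
working point of a shear-thinning egg-yolk emulsion at an applied rate
of 5 s⁻¹.

Fit the breakdown kinetics of a noisy yield-stress series and size the
droplets from a noisy PFG decay:

```r
tt     <- seq(0, 500, length.out = 20)                       # minutes
series <- skm_series(skm_params(80.1, 44, 0.012), tt,
                     noise = noise_spec(0.05, seed = 42,
                                        kind = "multiplicative"))
fit_skm(series$time, series$tau0, time_unit = "min")
#> SKM fit: tau0,0 = 82.82 +/- 3.2 Pa, tau0,e = 41.92 +/- 3.3 Pa, ks = 0.01031 +/- 0.0037 1/min
#>   breakdown extent tau0,0/tau0,e = 1.98

p   <- pgse_params(seq(0.1, 3, length.out = 32), delta = 2e-3,
                   Delta = 211e-3)
dec <- pfg_decay_lognormal(4.30, 0.40, 4e-12, p,
                           noise = noise_spec(0.005, seed = 7,
                                              kind = "additive"))
fit_droplet_size(dec, p)
#> Droplet size: D3,3 = 4.052 +/- 0.1 um, alpha = 0.248 +/- 0.086 (D_oil = 4e-12 m^2/s)
```

At 5% noise the breakdown rate kₛ = 0.0103 min⁻¹ and extent 1.98 sit
close to the generating values (0.012 min⁻¹, 1.82); the droplet fit
recovers the 4.30 µm median diameter within 6% at 0.5% attenuation
noise. `run_pipeline(pipeline_config(seed = 1), out_dir)` chains all
stages — velocimetry at two rotor rates, global-n fitting, kinetics,
droplet sizing and the D-T₂ map — and writes CSV/JSON outputs plus a
reproducibility manifest; `write_fixture_bundle()` emits the complete
seeded synthetic dataset in the package's CSV schemas.

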