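# aquaflux

Quantitative tools for measuring **unitary water permeability** (p_f, in
cm³/s) of single-file membrane channels — aquaporins, gramicidin
derivatives, potassium channels — from osmotic transport experiments.

Getting from a raw stopped-flow trace or a microelectrode scan to a
per-channel permeability involves several error-prone steps: the osmotic
driving force is partially dissipated in unstirred layers; popular
time-constant formulas overestimate the membrane permeability P_f by more
than an order of magnitude on small gradients; and channel counts based on
electrical activity miss channels that are electrically silent yet conduct
water. aquaflux implements the forward models, the inverse fitting
procedures, and the census corrections for this whole chain, together with
seeded synthetic-data generators so every estimator can be validated
without laboratory data.

## What is inside

| Area | Core relations | Functions |
|---|---|---|
| Single-file theory | p_f = v_w·D_1/(z·L) (hard-sphere limit), p_f = D_w·v_w/z², p_f/p_d = N (unconfirmed prediction) | `pf_finkelstein`, `pf_from_mobility`, `finkelstein_chain`, `pf_pd_ratio_prediction` |
| Vesicle deflation | dV/dt = A·P_f·V_w·(c_in − c_out); Lambert-W closed form V(t); τ-to-P_f conversions | `deflate_ode`, `deflate_analytic`, `fit_monoexponential`, `pf_from_tau`, `fit_deflation` |
| Light scattering | I = a + b·V + d·V²; two-population mixtures | `scatter_calibration`, `volume_from_intensity`, `mixture_trace` |
| Unstirred layers | C(x) = C_s·exp(−v_t·x/D + a·x³/3D); P_f = v_t/(χ·C_osm·V_w) | `ul_profile`, `fit_ul_profile`, `pf_from_velocity` |
| Channel census | n = G/g; P_f-vs-G and P_f-vs-density slopes; FCS two-step counting; silent-channel correction 1/(1−s) | `channels_from_conductance`, `pf_from_conductance_slope`, `channels_per_vesicle`, `pf_from_density_slope` |
| Structure–function | exponential decay of p_f with N or N_H | `fit_log_linear`, `predict_pf`, `outlier_report` |
| Energetics | p_f = ν₀·v_w·exp(−ΔG‡/RT); Arrhenius analysis | `pf_from_barrier`, `barrier_from_pf`, `barrier_consistency`, `fit_activation_energy` |
| Synthetic data | seeded generators with ground-truth sidecars | `gen_deflation`, `gen_profile`, `gen_arrhenius`, `gen_catalog`, `gen_slope_census` |

A subcommand CLI (`inst/exec/aquaflux`, a thin wrapper over
`aquaflux_cli()`) exposes the pipelines from the shell:
`simulate`, `fit-deflation`, `fit-profile`, `predict-pf`, `barrier`,
`census`, `catalog-fit`. Every analysis writes a provenance record with
the physical defaults and seed in effect.

## Worked example

Simulate a stopped-flow deflation of 100 nm proteoliposomes (290 mM
inside, challenged with 590 mM outside, true P_f = 0.01 cm/s, 1%
multiplicative noise) and fit it back:

```r
library(aquaflux)

sp <- vesicle_spec(r0 = nm_to_cm(100), c_in0 = mM_to_molcm3(290),
                   c_out = mM_to_molcm3(590), P_f = 0.01)
trace <- gen_deflation(sp, seq(0, 0.1, length.out = 500),
                       noise = noise_spec(sigma = 0.01, seed = 42))
fit_deflation(trace, r0 = sp$r0, c_in0 = sp$c_in0, c_out = sp$c_out,
              n_boot = 200, seed = 42)
#> Deflation fit (analytic strategy): P_f = 0.01002 cm/s  [95% CI 0.009976, 0.01006]
#>   monoexponential tau of data: 0.02523 s
```

The full-curve fit recovers the generating permeability to 0.2%, with a
bootstrap interval of about ±0.4%. For comparison, converting the same
time constant with the nominal-gradient formula (variant `"b"` of
`pf_from_tau`) on a *small* gradient (290 → 300 mM) overestimates P_f by
a factor of ~31 — which is why full-curve fitting, or at least the
averaged conversion (variant `"improved"`), is the supported route.

The transition-state side, in one line:

```r
barrier_model(24.1, T_K = 298)
#> Barrier model: dG = 24.1 kcal/mol at T = 298 K
#>   hopping rate r = 2.117e-05 1/s, p_f = 6.35e-28 cm^3/s
```

A 24.1 kcal/mol barrier caps p_f in the 10⁻²⁸ cm³/s decade —
immeasurably slow — and `barrier_limits()` gives the physical bracket for
facilitated transport: 4.6 (water self-diffusion) to 15.1 kcal/mol
(self-diffusion + enthalpy of vaporization). `barrier_consistency()`
checks any claimed (p_f, ΔG‡) pair against this relation.

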