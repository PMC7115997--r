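---
title: "Models and methods: extracting unitary water permeabilities from osmotic transport data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: extracting unitary water permeabilities from osmotic transport data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

## The problem

Water crosses narrow membrane channels — aquaporins, gramicidin
derivatives, the potassium channel KcsA — in single file: the pore is so
tight that water molecules cannot overtake one another.  The quantity that
characterizes one such channel is its unitary osmotic permeability
$p_f$ (cm$^3$/s), the volume of water one channel conducts per unit osmotic
driving concentration.  Measuring $p_f$ requires (i) a measurement of the
ensemble membrane permeability $P_f$ (cm/s), and (ii) an accurate count of
the channels contributing to it.  Both steps harbour classical pitfalls —
unstirred layers that dissipate the osmotic gradient, approximate
time-constant formulas that overshoot $P_f$ by an order of magnitude, and
channel censuses that miss electrically silent but water-conducting
channels.  aquaflux packages the forward models, the inverse fitting
procedures, and seeded synthetic-data generators that exercise all of them.

All internal computation is in CGS units (cm, s, erg, dyn; concentrations
in mol/cm$^3$); file formats carry human-scale units in their column names
(`time_s`, `c_mM`, `x_um`) and are converted exactly once, at the I/O
boundary.

## The classical single-file model and why it is kept at arm's length

The classical (hard-sphere) derivation treats the water column as $N$
spheres dragged through a pipe of length $L = Nz$ ($z$ = one water
diameter, default $2.8\times10^{-8}$ cm).  Balancing the osmotic force
against friction yields

$$p_f = \frac{v_w D_1}{zL} = \frac{D_w v_w}{z^2},$$

with $D_1$ the (hypothetical) mobility of an isolated pore water,
$D_w = D_1/N$ the column mobility, and $v_w$ the volume of a water
molecule (default $3.0\times10^{-23}$ cm$^3$, i.e. 18 cm$^3$/mol divided
by Avogadro's number; the literature rarely prints this value, so it is
recorded in provenance whenever the default is used).  The first form
predicts $p_f \propto 1/L$ and a $p_f/p_d$ ratio equal to $N$; neither
survives experimental scrutiny — measured permeabilities of single-file
channels span four orders of magnitude at nearly constant $L$, and the
measured ratios (about 5 for gramicidin A with $N = 7$; about 13 for AQP1
with $N \approx 8$) do not count pore waters.  `finkelstein_chain()`
therefore returns every intermediate of the derivation but the
documentation consistently labels it the hard-sphere limit.  The second
(mobility) form makes no such assumption and is exact for fully occupied
files; `pf_from_mobility()` and `mobility_from_pf()` convert between
$p_f$ and $D_w$.

What does explain the spread is hydrogen bonding: `fit_log_linear()` fits
the empirical exponential decay of $p_f$ with either the single-file water
count $N$ or the count $N_H$ of hydrogen-bond donating/accepting
pore-lining residues, in natural-log space by unweighted OLS.  Weighting
by data-quality class is available but off by default, because the
underlying relation is presented in the literature graphically, without a
stated fit procedure.  The package ships an *illustrative, synthetic*
catalog (`example_catalog_synthetic.tsv`) — the experimental values behind
the published relation are not tabulated anywhere and are deliberately not
reproduced here.  `outlier_report()` flags channels whose log-residual
exceeds $k$ robust scale units (normal-consistent MAD, default $k = 3$);
the MAD is used instead of the residual SD because catalogs are small and
a channel sitting two orders of magnitude off the line would otherwise
inflate the SD enough to mask itself.  A large negative residual is the
signature of gating — a channel dwelling in a closed state.

## Vesicle deflation kinetics

A vesicle (initial radius $r_0$, internal osmolyte concentration
$c_{in,0}$) challenged at $t=0$ with an external concentration $c_{out}$
deflates according to

$$\frac{dV}{dt} = A P_f V_w \left(c_{in}(t) - c_{out}\right),
\qquad c_{in}(t) = \frac{V_0}{V(t)} c_{in,0},$$

with surface area $A$ held constant (the membrane wrinkles rather than
disappears) and $V_w = 18$ cm$^3$/mol the partial molar volume of water.
`deflate_ode()` integrates this with `deSolve::lsoda` at relative
tolerance $10^{-10}$; `deflate_analytic()` evaluates the closed form

$$V(t) = V_0\frac{c_{in,0}}{c_{out}}\left[1 + W\!\left(
\frac{c_\Delta}{c_{in,0}}\exp\!\left(\frac{c_\Delta}{c_{in,0}}
- \frac{A P_f V_w c_{out}^2}{V_0 c_{in,0}}t\right)\right)\right],$$

with $W$ the Lambert principal branch (`pracma::lambertWp`) and
$c_\Delta = c_{out} - c_{in,0}$.  The principal branch is the one
continuous with $V(0)=V_0$; for any constructible vesicle the argument
stays inside $(-1/e, \infty)$ (shrinking keeps it positive, swelling keeps
it in $(-1/e, 0)$ because $c_{out}>0$ forces $c_\Delta/c_{in,0} > -1$), so
the branch-domain error can only fire on corrupted inputs — it is guarded
and tested anyway.  The two forward models agree to better than $10^{-6}$
relative over a broad random parameter sweep, and osmolyte mass
$c_{in}(t)V(t)$ is conserved to $10^{-8}$; both properties are asserted in
the test suite.

```{r deflation-example}
sp <- vesicle_spec(r0 = nm_to_cm(100), c_in0 = mM_to_molcm3(290),
                   c_out = mM_to_molcm3(300), P_f = 0.01)
t_grid <- seq(0, 0.5, length.out = 500)
trace <- volume_trace(t_grid, deflate_analytic(sp, t_grid))
fit_monoexponential(trace)
```

### From time constant to permeability — and how not to

Deflation traces are conventionally summarized by a monoexponential time
constant $\tau$.  `pf_from_tau()` implements the conversions in
circulation, $P_f = r_0/(3 V_w \tau\, \Delta\Pi_{\mathrm{eff}})$ with
$\Delta\Pi_{\mathrm{eff}}$ equal to $c_{out}$ (variant `a`),
$c_{out}-c_{in,0}$ (variant `b`), $c_{out}^2/c_{in,0}$ (variant `c`), plus
the averaged form (variant `improved`)
$P_f = \frac{r_0}{3V_w\tau}\frac{c_{in,0}+c_{out}}{2c_{out}^2}$.  A note
on units: the literature prints the three divisors as bare concentration
expressions that are not mutually dimensionally consistent; the forms
implemented here are the only reading under which every variant returns
$P_f$ in cm/s, with $\Delta\Pi_{\mathrm{eff}}$ a concentration in
mol/cm$^3$.  On a small gradient (290 → 300 mM) variant `b` overestimates
$P_f$ by the closed-form factor
$c_{out}^2/\!\left(c_{in,0}(c_{out}-c_{in,0})\right) = 31$ — more than an
order of magnitude — and makes $P_f$ appear gradient-dependent; variant
`c` is the small-gradient linearization of the exact solution; the
averaged form stays within a few percent at moderate gradients.  These
statements are computed, not quoted: the test suite and
`scripts/acceptance.R` regenerate the factor from a noiseless trace.

For full-curve fitting, `fit_deflation()` offers the closed-form strategy
(Levenberg-Marquardt on $\log P_f$, the only free parameter; $r_0$,
$c_{in,0}$, $c_{out}$ must be known — the error in $P_f$ scales linearly
with the error in the assumed radius, and no radius estimator is provided)
and the classical grid strategy (integrate the ODE for each candidate
$P_f$, extract $\tau_c$, match the experimental $\tau$ to the nearest
$\tau_c$).  Uncertainty comes from a residual bootstrap (200 resamples by
default, seed mandatory — there is no hidden RNG state anywhere in the
package).

### The scattering observable

Stopped-flow instruments record scattered-light intensity, related to
volume by the quadratic reduction $I = a + bV + dV^2$
(`scatter_calibration`, `intensity_from_volume`,
`volume_from_intensity`); inversion requires exactly one quadratic root
inside the physical volume interval $[V_{eq}, V_0]$ and errors otherwise,
naming both roots.  Reconstitution yields a bare-vesicle population
alongside the proteoliposomes; `mixture_trace()` forms the weighted
two-population signal, which is visibly biexponential — a monoexponential
fit to it carries a strictly worse residual sum of squares than a
two-component fit, which is how the package's tests detect mixture
structure.

## Unstirred layers

Adjacent to a membrane sustaining a water flux, transport is
diffusion-limited and the osmolyte is diluted on the draw side.  The
steady-state profile recorded by a scanning ion-selective microelectrode
is

$$C(x) = C_s\exp\!\left(-\frac{v_t x}{D} + \frac{a x^3}{3D}\right),$$

with $x$ measured into the hyperosmotic compartment, $v_t$ the
transmembrane volume-flow velocity, and $a$ an empirical stirring
parameter (the cubic term's sign and units follow the transcribed form;
$a$ is treated as purely empirical).  In log space this is linear in its
parameters, so `fit_ul_profile()` is an exact OLS of $\ln C$ on
$\{1, x, x^3\}$ with intervals from the residual covariance.  $P_f$
follows from $P_f = v_t/(\chi\, C_{osm} V_w)$ (`pf_from_velocity`), where
$C_{osm}$ is by convention the *near-membrane* concentration $C_s$ — the
driving force acts at the interface, not in the bulk — and $\chi$ is the
osmotic coefficient (default 1).

A practical caveat the package makes explicit: $x$ and $x^3$ are highly
collinear over a short scan, so fitting all three parameters to a
0–200 μm scan at 1% noise recovers $v_t$ with ~12% mean error.  The
supported workflow freezes the stirring parameter from a control
(no-gradient) scan, which brings the mean error to ~5% on that geometry
and to ~2% when the scan spans the full unstirred layer (several hundred
μm).  The recovery tests use the control-calibrated workflow.

## Channel census

Three census routes are implemented:

* **Electrical** (`channels_from_conductance`,
  `pf_from_conductance_slope`): $n = G/g$ and
  $P_f = \frac{p_f}{Ag}G$, so the slope of $P_f$ against $G$ times $Ag$
  is $p_f$, and the intercept is the lipid background.  Counts are
  returned as real numbers — they are ensemble averages.  If a fraction
  $s$ of channels is electrically silent yet water-conducting, the naive
  estimate is inflated by exactly $1/(1-s)$ (a closed-form property
  asserted in the tests; for KcsA, $s \approx 0.9$).  The correction is an
  explicit opt-in parameter, default 0, because silencing is
  channel-specific.
* **FCS two-step counting** (`fcs_census`, `channels_per_vesicle`):
  vesicles are counted, dissolved in detergent, and the labeled micelles
  counted; the count ratio over the labeling efficiency gives protomers
  per vesicle, divided by the oligomeric state gives channels per vesicle.
  Labeling efficiencies below 0.8 trigger a warning (the oligomeric state
  becomes unresolvable).  Because the literature does not fix how the
  protein-free vesicle fraction enters reported values, both conventions
  are returned: per counted vesicle and per proteoliposome
  ($\div(1-\text{bare fraction})$).  Detergent chemistry itself is not
  modelled — the two-stage mild/harsh protocol is collapsed into counts
  plus `protomers_per_oligomer`.
* **Density slope** (`pf_from_density_slope`): against channel surface
  density (channels/cm$^2$) the slope *is* $p_f$ in cm$^3$/s.

## Energetics

The hopping picture links $p_f$ to a Gibbs activation barrier:
$r = p_f/v_w$ hops per second, $r = \nu_0 e^{-\Delta G^\ddagger/RT}$ with
$\nu_0 = 10^{13}$ s$^{-1}$ the universal attempt frequency, hence

$$p_f = \nu_0 v_w\, e^{-\Delta G^\ddagger/RT}.$$

`pf_from_barrier()` and `barrier_from_pf()` are exact inverses
($R = 1.98720\times10^{-3}$ kcal/(mol K); default $T = 298.15$ K — the
evaluation temperature of published barrier curves is not always stated,
so it is an explicit parameter carried in provenance).
`barrier_consistency()` turns the pair into a check: a claimed
$p_f = 6.8\times10^{-13}$ cm$^3$/s implies a 3.6 kcal/mol barrier, which
cannot coexist with a measured 24.1 kcal/mol — that barrier predicts
$p_f \sim 10^{-28}$ cm$^3$/s, fifteen orders of magnitude less.
`barrier_limits()` composes the physically motivated bracket: the
activation energy of water self-diffusion (4.6 kcal/mol, the lower limit
when pore water stays bulk-like) plus the enthalpy of vaporization
(10.5 kcal/mol, the cost of stripping a water out of solution) gives the
~15 kcal/mol upper limit for facilitated transport.

`fit_activation_energy()` performs the Arrhenius analysis (OLS of
$\ln P_f$ on $1/T$, $E_a = -R\cdot\text{slope}$).  The slope is reported
as an activation energy; the common practice of reading it as
$\Delta G^\ddagger$ is a simplification (no enthalpy/entropy
decomposition), and the documentation says so.

## Synthetic data and what passing tests do and do not show

Every fitter input can be generated (`gen_deflation`, `gen_profile`,
`gen_arrhenius`, `gen_catalog`, `gen_slope_census`) with an explicit seed,
a stated noise model (multiplicative or additive Gaussian), and a
machine-readable ground-truth record attached.  Default problem sizes are
desk-scale: 500-point traces, 30-point profiles, 6-point temperature
series, catalogs of 6–7 channels; the recovery studies in the tests and
the acceptance script run 100 seeds each.

Chosen study conditions, fixed once: deflation recovery uses a typical
stopped-flow challenge (100 nm vesicles, 290 mM inside, external
osmolarity roughly doubled to 590 mM, $P_f = 0.01$ cm/s, 1% multiplicative
noise); the 290 → 300 mM small-gradient condition is reserved for the
approximation-error demonstration, where the variant-`b` bias is largest
and the monoexponential approximation is at its best.  Profile recovery
uses $C_s = 100$ mM, $v_t = 10^{-4}$ cm/s, $D = 2\times10^{-5}$
cm$^2$/s, stirring calibrated from a control.

The generators emulate the *statistical structure* the analyses assume —
exact forward models plus stationary Gaussian noise.  They do not emulate
instrument drift, stopped-flow mixing artifacts beyond a crop-able dead
time, vesicle polydispersity beyond discrete mixtures, scattering
photophysics, or FCS photon statistics (counts are inputs, not simulated
traces).  Passing recovery tests therefore demonstrates correctness of
the estimators under their own assumptions, not robustness to every
laboratory systematic.  Likewise, the experimental permeabilities of
named channels, the measured water:ion flux ratio of potassium channels,
and the gramicidin length-series data exist only graphically in the
literature; the package ships tooling to fit such data, not the data
themselves.

## Numerical choices

* ODE integration: `lsoda`, rtol $10^{-10}$, atol $10^{-12} V_0$.
* Volumes are $\sim10^{-15}$ cm$^3$; all nonlinear fits rescale the signal
  to unit magnitude before optimization.
* Monoexponential initialization: log-linear regression on the part of the
  decay clearly above the noise floor (5% amplitude threshold), with a
  half-decay estimate and two coarse fallbacks tried in order.
* Quadratic intensity inversion: a root is accepted only if it is the
  unique root within bounds, with a $10^{-9}$-relative tolerance at the
  endpoints.
* Bootstrap: 200 residual resamples by default; the seed is mandatory, and
  all seeded code paths restore the caller's RNG state.
* Lambert W: principal branch throughout (continuity with $V(0) = V_0$).

## Known limitations

* $r_0$ is a required input to deflation fitting; no size estimator is
  provided, and the $P_f$ error is proportional to the radius error.
* The scattering calibration is empirical per dataset; no
  refractive-index model is attempted beyond the quadratic.
* The hard-sphere chain is provided for transparency, not prediction; no
  alternative microscopic model of $W(L)$ is implemented.
* Constriction-zone (inhomogeneous-channel) corrections and electrokinetic
  couplings are out of scope.
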