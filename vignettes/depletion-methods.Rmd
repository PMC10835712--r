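---
title: "Models and methods: neutral-polymer depletion at charged membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: neutral-polymer depletion at charged membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdep)
```

## The problem

A charged lipid membrane in salt solution is wrapped in an electric double
layer: a diffuse cloud of counterions whose potential decays over the Debye
length $\kappa^{-1}$ (about 1 nm at physiological ionic strength). Within a
nanometre or two of the surface the electric field and its gradient are
enormous, and the counterion cloud carries a large osmotic excess pressure.
A *neutral* particle that is less polarizable than water — a PEG coil is
the canonical example — experiences two repulsive forces there:

* **surface dielectrophoresis (sDEP)**: the induced dipole of a
  low-permittivity sphere in the strongly non-uniform double-layer field is
  pushed toward weaker fields, i.e. away from the membrane;
* **counterion pressure**: the osmotic pressure of the ion excess acts on
  the volume the particle excludes from the double layer.

Both energies decay as $e^{-2\kappa z}$, and together they carve out a
polymer depletion zone several times wider than the coil radius. This
package implements the analytical model of that repulsion, a
composition-space neutron-reflectometry (NR) forward model and joint
multi-contrast fitting pipeline that measures the depletion zone, and the
post-processing used for potential-of-mean-force (PMF) profiles from
molecular dynamics, together with a synthetic-data module that generates
every input with known ground truth.

## The interaction model

The particle is a homogeneous dielectric sphere of radius $a$ (the
hydrodynamic radius $R_h$ of the coil) and interior permittivity
$\varepsilon_p = 10\,\varepsilon_0$, in water
($\varepsilon_w = 78.5\,\varepsilon_0$). Its effective polarizability
carries the Clausius–Mossotti factor
$\mathrm{CM} = (\varepsilon_p - \varepsilon_w)/(\varepsilon_p +
2\varepsilon_w) \approx -0.41$ — negative, hence repelled from strong
fields.

**Closed-form backend.** With the linearized (Debye–Hückel) double layer,
$\psi(z) = \sigma/(\varepsilon_w \kappa)\, e^{-\kappa z}$, the classical
point-dipole DEP energy integrates to

$$E_D(z) = K_D e^{-2\kappa z}, \qquad
K_D = -2\pi a^3\, \mathrm{CM}\, \sigma^2 / \varepsilon_w,$$

and the sphere-volume integral of the linearized osmotic excess pressure
$\Pi(z) = \sigma^2 e^{-2\kappa z} / (2 \varepsilon_w)$ gives

$$E_H(z) = K_H e^{-2\kappa z}, \qquad
K_H = \tfrac{2\pi}{3} a^3 \sigma^2\, g(2\kappa a) / \varepsilon_w,$$

where $g(c) = 3(c\cosh c - \sinh c)/c^3$ is the average of
$e^{-c(z'-z)}$ over the ball. A point worth making explicit, because it is
easy to get wrong: the *same* linearized boundary condition must be used in
both terms. If the full Grahame surface potential is decayed exponentially
instead (the convention that reproduces the order-of-magnitude ion-excess
estimates, see below), $K_H$ shrinks by roughly a factor of ten and the
predicted depletion distance drops by ~3 Å. Under the consistent
Debye–Hückel convention, $K_D \approx K_H \approx 37\,k_BT$ for
PEG600 ($a = 7$ Å) near a DPPS-like membrane
($\sigma = 0.35$ C/m², 0.1 M), and the distance where
$E_D + E_H = 1\,k_BT$ comes out near 21 Å — three times the coil radius.

```{r}
medium <- ionic_medium(0.1)
iface  <- lipid_preset("DPPS")
sphere <- dielectric_sphere(peg_geometry(600)$R_h, 10, 600)
cur <- interaction_curve(sphere, iface, medium, seq(7, 60, by = 0.25))
depletion_distance(cur, threshold = 1)
```

**Maxwell-stress backend.** The point-dipole formula assumes a uniform
field and an ion-free medium; neither holds when $\kappa a \sim 1$.
`dep_energy_stress()` solves the linearized Poisson–Boltzmann scattering
problem of the ion-excluding dielectric sphere in the exponential
double-layer field by a multipole expansion — modified spherical Bessel
functions $i_n, k_n$ outside, Laplace harmonics inside, potential and
normal displacement matched on the surface — and integrates the full
stress (electric Maxwell stress plus the linearized osmotic pressure of
the *perturbed* ion cloud) over the sphere. The reflection of the
scattered field at the membrane plane is neglected; it enters at higher
order in $e^{-\kappa z}$. The force is converted to energy by integration
from infinity, and the backend's DEP component is defined as the total
stress-tensor energy minus the unperturbed-fluid hydrostatic term $E_H$.
That decomposition reduces *exactly* to the classical $E_D$ in the
weak-field, small-$\kappa a$ limit (the tests require agreement within
10 %; the observed deviation at $\kappa a = 0.1$ is a few percent), while
in the experimental regime ($\kappa a = 0.73$) it exceeds the classical
form by ~35 %: the point-dipole expression underestimates the repulsion of
double-layer-sized particles. Truncation (multipole order and quadrature
nodes) is doubled until the energies move by less than 2 %.

**Two double-layer conventions.** The order-of-magnitude estimate chain
(`discussion_estimates()`, `run_discussion_chain()`) deliberately uses a
different convention: the full Grahame surface potential
($\psi_0 \approx 0.15$ V for DPPS) decayed as $e^{-\kappa z}$
(`linear_decay`). That convention reproduces the quotable numbers — ion
excess $\approx 0.68$ M one Debye length out, van't Hoff pressure
$\approx 1.7$ MPa, thermal force $k_BT/2R_h \approx 3$ pN — whereas the
exact nonlinear Gouy–Chapman profile (`nonlinear_gc`, also provided) is
weaker at every $z$. Both conventions are exposed, the estimate chain
defaults to `linear_decay`, and the sphere-interaction module uses the
Debye–Hückel convention throughout; mixing them is the one combination
this package intentionally avoids.

## The reflectometry model

Specular reflectivity is computed by the Parratt recursion with
Névot–Croce roughness factors in compiled code, validated against an
independent transfer-matrix implementation to $10^{-10}$. The
composition-space model arranges molecular components — native oxide,
inner/outer headgroups, acyl chains — as error-function-edged boxes along
$z$ (measured from the Si/oxide interface), fills unoccupied space with
solvent, and converts to a neutron scattering-length-density (nSLD)
profile using molecular volumes and summed coherent scattering lengths
($\rho = b/V$; D₂O comes out at $6.4\times10^{-6}\,\text{Å}^{-2}$ from
$b = 19.145$ fm and its bulk density). The polymer enters through the
Boltzmann-weighted exclusion profile

$$c(z) = c_\infty \exp\!\left[-E_0\, e^{-2\kappa (z - z_0)}\right],$$

with bulk volume fraction $c_\infty$, interaction strength $E_0$ (in
$k_BT$, the energy at the plane of charge $z_0$), and the $2\kappa$ decay
of the interaction model; where other components occupy space, $c(z)$ is
scaled by what remains. PEG scatters at a constant
$0.7\times10^{-6}\,\text{Å}^{-2}$. The **exclusion distance** — the
summary statistic of the whole experiment — is the distance from the
hydrophobic interface (outer tails/headgroup boundary) at which the
polymer density reaches half its bulk value; in closed form
$z_{1/2} = z_0 + \ln(E_0/\ln 2)/(2\kappa)$, which requires $E_0 > \ln 2$
(below that the profile never drops to half density and the result is
reported as censored).

Numerical choices that matter:

* profiles are evaluated on a 0.5 Å grid and sliced into microslabs
  (default 0.5 Å; 1 Å in the sampling studies, indistinguishable at the
  fixture noise level) whose *count is fixed* and whose widths scale
  continuously with the model geometry — slab edges that snap to a grid
  make the likelihood surface jagged at the 0.1-χ² level and break both
  quasi-Newton optimization and Hessian estimates;
* the backing medium is the analytic bulk solution
  $(1-c_\infty)\rho_{\rm solv} + c_\infty \rho_{\rm PEG}$, and the profile
  extends until the residual depletion energy falls below
  $10^{-3}\,k_BT$, so the tail truncation never perturbs the critical
  edge;
* resolution smearing is a Gaussian in $Q$ with $\sigma = \Delta Q/2.355$
  on the instrument's constant $\Delta Q/Q = 2.5\%$ binning, with
  one-sided renormalization at the grid ends;
* the rough Si|oxide interface is a Névot–Croce factor on the fronting
  boundary rather than an erf box, so no solvent is spuriously placed
  inside the substrate.

## Fitting and uncertainty

`joint_fit()` fits one structural model simultaneously to curves measured
under several solvent contrasts (solvent SLD free per contrast, everything
else shared) with a Gaussian likelihood. Lipid occupancies derive from the
area per lipid and packaged molecular volumes, so the bilayer volume per
unit area is invariant under the sampled thickness parameters — volume
conservation by construction rather than by constraint. Two
parameterization lessons are baked in: the solvent SLD is freed through
the *bulk-solution backing SLD* (`rho_b_i`), because the raw solvent SLD
and the polymer fraction form a curved trade-off ridge that defeats
Gaussian proposals; and all sampling happens in unit-box coordinates so
the Hessian is well conditioned across parameters whose natural units
differ by six orders of magnitude.

Sampling is a stretch-move ensemble interleaved with Metropolis–Hastings
independence moves. The proposal for the independence kernel starts as a
Laplace approximation at the (L-BFGS-B) optimum and is refit to the
empirical ensemble covariance after a short adaptation stage; with a
proposal close to the posterior the walkers decorrelate in a few steps,
which is what makes a strict convergence gate affordable. Convergence is
assessed with the split-chain statistic; any parameter above 1.05 flags
the fit and `exclusion_ci()` refuses to report intervals. Intervals are
central posterior percentiles (68/95 %), and the exclusion distance is
computed per posterior sample — never from the point estimate — with the
censored fraction ($E_0 \le \ln 2$) reported alongside.

Priors are uniform boxes on physical ranges (thicknesses up to tens of Å,
$E_0 \in [0, 20]\,k_BT$, $\kappa$ fixed by the known ionic strength).
Box priors plus percentile intervals mean the intervals are honest but the
sampler must be given enough steps when the data are weak; the default
study sizes are 12 walkers and 150–450 steps depending on noise level.

## The synthetic-data module

The generator is first-class code with its own ground truth, not a test
fixture. `make_ssblm_truth()` builds a solid-supported bilayer membrane (ssBLM)
(15 Å oxide, ~8 Å hydration gap, two leaflets at 70 Å² per lipid and 95 %
coverage) bathed in a PEG600 solution at 9.1 wt% (a 10:1 solvent:polymer
preparation) in a 110 mM buffer, with $E_0$ tied to the interaction theory
for the chosen lipid preset: $(K_D + K_H)/k_BT$ for the charged bilayers
(about 19 $k_BT$ for the half-charged anionic mixture), a small steric
baseline of 0.8 $k_BT$ for the neutral one.
`simulate_reflectivity()` computes the smeared forward curve on the
0.008–0.379 Å⁻¹, 2.5 %-binned grid, converts to expected counts at an
incident intensity of 10⁶ per bin, and draws Poisson samples for the
specular channel and two off-specular background channels (background at
10⁻⁶ of the incident beam, so the high-$Q$ tail is background-dominated,
as in measured data). Reduction follows $R = (I - I_B)/I_0$ with the
background interpolated from the brackets and Poisson errors propagated in
quadrature; negative net intensities are retained. The recovery studies
use a variant truth at 10 mM ionic strength whose $E_0$ (3.7 $k_BT$) embeds
an exclusion distance of exactly 30 Å.

`simulate_profiles()` emulates the PMF route: a smooth steric step for the
neutral membrane, multiplied by $\exp[-A e^{-2\kappa z}]$ for the charged
one, with $A = e^{2\kappa d}$ chosen so the charged-minus-neutral free
energy crosses $1\,k_BT$ at the tabulated distance for each molecular
weight (16 Å for PEG600 up to 28 Å for PEG6000 at 0.1 M), plus Gaussian
bin noise (default 1 % of the bulk mass fraction).

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: polymer conformational flexibility and
concentration-dependent crowding (the measured exclusion shrinks at high
polymer concentration; the generator's profiles have fixed shape),
membrane undulations and defects, instrument backgrounds beyond a flat
incoherent level, and any hydration-layer structure. Recovery results
certify the *pipeline* (reduction, forward model, sampler, interval
construction), not the physics of real membranes.

## Analysis workflow and study sizes

The numbered scripts under `analysis/` run the full chain and write their
tables under `results/`: `01_discussion_chain.R` (the deterministic
estimate table), `02_theory_curves.R` (energy curves, depletion distances
for all MWs and lipids, stress-vs-closed comparison),
`03_synthetic_nr_fit.R` (two-contrast simulation and joint fits for the
three lipid presets), and `04_md_profile_analysis.R` (decay fits and the
size-scaling exponent). Study sizes — 12 walkers, 150–450 ensemble steps,
20-seed recovery repeats, 1 Å fitting slabs — were chosen so a full run
completes in minutes on a single core while keeping every convergence
gate strict; they are the package's defaults, and all of them are plain
function arguments.

## Known limitations

* The multipole stress backend omits the image of the scattered field in
  the membrane; for $z \gtrsim a + \kappa^{-1}$ this is a higher-order
  correction, but contact values should be read qualitatively.
* The sphere model itself is crude for a polymer coil — the measured and
  simulated depletion distances are expected to sit *below* the sphere
  prediction, and do.
* The composition-space model fixes headgroup thickness and leaflet
  symmetry; freeing them is a prior-specification exercise, not a code
  change.
* Exclusion distances are only defined for $E_0 > \ln 2$; fits of
  neutral-membrane data correctly return censored intervals rather than
  numbers.
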