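---
title: "Models and methods behind neotrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neotrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The nanopore electro-osmotic trap (NEOtrap) docks a porous DNA-origami
sphere onto a lipid-coated solid-state nanopore. Under positive bias the
counter-cations screening the DNA's fixed negative charge are driven through
the origami's internal nanochannels, dragging water with them: an
electro-osmotic flow (EOF) through the pore that can hold a single,
unmodified protein against diffusion. Because the origami is built from
parallel DNA helices, the sphere is anisotropic: docked "vertically"
(helices along the pore axis) its nanochannels are aligned with the flow;
docked "horizontally" they lie across it. This package provides (i) a
continuum electrokinetic model of the docked system that quantifies how
orientation modulates the EOF, and (ii) a trace-level simulation and
analysis pipeline for the single-molecule recordings such an experiment
produces: telegraph-state synthesis, event detection, dwell-time and rate
estimation, noise spectroscopy, and thermodynamic interpretation.

# The continuum model

## Equations

On an axisymmetric (r, z) domain we solve the steady coupled system

* Poisson: $-\nabla\cdot(\varepsilon\varepsilon_0\nabla\psi) = F\sum_i z_i c_i + \rho_f$,
  where $\rho_f$ is the smeared fixed charge of the DNA inside the origami;
* Nernst–Planck per ion: $\nabla\cdot\left(-D_i\nabla c_i - z_i \frac{D_i F}{RT} c_i\nabla\psi + c_i\,\mathbf v\right)=0$;
* Stokes–Brinkman: $\eta\nabla^2\mathbf v - \nabla p - \rho_e\nabla\psi - \eta\,\kappa^{-1}\mathbf v = 0$, $\nabla\cdot\mathbf v = 0$,
  with $\rho_e = F\sum_i z_i c_i$ the *mobile* space charge and the drag term
  active only inside the origami, with an anisotropic permeability tensor
  $\kappa = \mathrm{diag}(\kappa_r,\kappa_z)$.

Two modelling points deserve emphasis. First, the momentum source is the
electric force on the mobile ions only: the fixed DNA charge is anchored to
the origami lattice, and the momentum it absorbs from the field is already
represented by the Brinkman drag of that lattice. Including $\rho_f$ in the
body force would cancel the screened counter-charge and suppress exactly the
EOF the trap relies on. Second, inertia is dropped (creeping flow): at
nanopore scales the Reynolds number is $\ll 10^{-3}$, so the Stokes limit is
the appropriate reading of the hydrodynamics.

## Geometry and materials

The domain is a cylinder: trans reservoir below, SiN membrane (20 nm)
coated with a neutral 5-nm lipid bilayer on both faces and the pore wall
(10 nm pore radius, so a 10 nm *effective* diameter), cis reservoir above,
100 nm reservoirs in radius and height. The origami sphere (radius 20 nm)
is a porous Brinkman medium. Defaults are typical values for this
experimental system; all headline outputs are ratios or signs, which makes
them robust to the absolute choices.

The sphere **seats on the pore rim**: its center sits at
$z = z_\text{top} + \sqrt{R^2-a^2} - d_\text{seat}$, touching the rim circle
of the effective pore radius $a$ and settling a further
$d_\text{seat} = 0.7$ nm into the mouth. A sphere tangent to the flat
membrane instead leaves a sub-nanometre wedge between sphere and membrane
that hydraulically shunts the porous medium and almost erases the
orientation contrast. The seating depth is the one calibrated constant in
the geometry: it is set so that the simulated docked current blockade
matches the observed 17% of the open-pore current, an observable
independent of the flow-rate contrast the model is then asked to produce.

Origami material parameters: nanochannel diameter $d_c = 1.5$ nm (the
honeycomb lattice of helices leaves 1–2 nm interstitial channels), channel
void fraction $\phi = 0.3$, and a fixed charge from the B-DNA backbone (2e
per 0.34 nm rise per helix, smeared over the composite:
$\approx -1.6\times10^8$ C/m³, the charge equivalent of ~1.7 M monovalent
ions). Permeability along the channels uses the parallel-capillary bundle,
$\kappa_\parallel = \phi d_c^2/32 \approx 2.1\times10^{-20}\,$m²; across
them, Happel's transverse-flow-past-rods cell model (valid at all solid
fractions), capped at $\kappa_\parallel/2$, the dilute-array anisotropy
limit. At the defaults $\kappa_\parallel/\kappa_\perp \approx 6$. A
vertical sphere carries $\kappa_z = \kappa_\parallel$, a horizontal one
$\kappa_r = \kappa_\parallel$ — the *only* difference between the two
configurations.

## Discretization and numerics

Finite volumes on a graded structured mesh (uniform ~0.75 nm cells around
the membrane, pore, and sphere; geometric coarsening to 8 nm toward the
reservoirs; default ~46 x 138 cells). Ion fluxes use Scharfetter–Gummel
exponential fitting with the advective velocity folded into the Peclet
number, which keeps concentrations positive at any mesh Peclet number.
Velocities live on a staggered (MAC) grid and incompressibility is a
per-cell flux balance solved as a saddle point by sparse LU, so the flow
rate is conserved to machine precision and plane-independent. The outer
coupling is a Gummel fixed point with damped-Newton linearisation of the
Poisson space charge and under-relaxation 0.3 (default; robustness over
speed), tolerance $10^{-6}$ on the largest relative block update, at most
200 iterations; non-convergence is flagged on the returned object and
warned about, never silent. The Stokes operator depends only on the mesh
and is factorised once per solve.

One resolution caveat is deliberate: at 1 M KCl the Debye length is 0.30 nm
and the `resolution` target of 2 cells per Debye length cannot be met
globally at desk scale. For the quantities this model reports this is
benign — the origami's charge is a *volumetric* smeared density screened
over the sphere's interior, not a surface layer — and the wall-double-layer
physics is verified separately: the Helmholtz–Smoluchowski test runs in
dilute electrolyte (20 mM, $b/\lambda_D = 4.7$) where the layer is
resolved, in a long channel ($L/b = 20$) because in short channels EOF
back-pressure through the access resistance genuinely depresses the plug
velocity by ~20% (physics, not error). The analytic oracle there is the
cylindrical Debye–Hückel profile including the Bessel-function corrections
for both the $\sigma\!\to\!\zeta$ relation and the axis velocity.

Verification oracles (all in the test suite): Poiseuille law and profile
within 2%; cylindrical Helmholtz–Smoluchowski within 10%; access+channel
conductance formula $G=\sigma_b[4t/(\pi d^2)+1/d]^{-1}$ within 15%;
plane-independence of current and flow within 1%; zero fields at zero bias;
low-bias linearity; sign reversal under bias reversal (the small residual
asymmetry is real ionic-current rectification by the charged sphere).

With the defaults at +100 mV the model gives a docked blockade of ~17% and
a vertical/horizontal flow-rate ratio of ~1.7 — the right sign and order of
the reported ~2.5x contrast. We regard the quantitative gap as expected for
a smeared two-dimensional axisymmetric reduction: the experiment's rod-level
channel alignment is sharper than any smeared-permeability ellipsoid can be.

# The synthetic recordings

`simulate_state_path()` runs an exact Gillespie simulation of the
open / attempt / docked / trapped continuous-time Markov chain; all dwell
times are exponential, and voltage protocols switch the rate matrix by bias
sign (bare spheres eject at negative bias, cholesterol-anchored ones do
not), which is exact because exponential clocks are memoryless.
`render_trace()` then scales each state's current level by the
instantaneous bias, adds white noise in the time domain and 1/f noise by
spectral shaping with a deterministic per-seed spectrum, and finally applies
the causal acquisition filter — a 4-pole Bessel (the patch-clamp standard,
built from the tabulated analog prototype poles via the bilinear transform
with prewarping).

Preset operating points mirror the published system: open-pore current
1500 pA at 100 mV; docked levels 0.83 (vertical) and 0.855 (horizontal) of
open; trapped level 0.8 of docked; vertical avidin kinetics capture 7.7 /s
and escape 11 /s; horizontal capture 3.85 /s (half) and escape 2970 /s
(270-fold); uniformly functionalized spheres trap avidin with a 50 ms time
constant. Noise presets put the cholesterol-functionalized baseline near
sigma = 8 pA at 10 kHz bandwidth (vs 7 pA open-pore) and the bare-sphere
baseline near 13 pA, with the difference carried almost entirely by an
order-of-magnitude larger 1/f coefficient — the mechanical-fluctuation
signature that cholesterol anchoring suppresses.

Acquisition defaults to 125 kHz sampling with a 10 kHz cutoff; the presets
sample at 25 kHz (50 kHz for the fast horizontal kinetics), which keeps the
cutoff below Nyquist while making 600-s traces cheap to synthesize — these
are the problem sizes used throughout the tests and the acceptance script.
What the generator does *not* emulate: capacitive transients at voltage
steps, amplifier dynamics beyond the single low-pass, lipid-rupture noise
bursts, and any within-state conformational substructure. Passing the
recovery tests therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every artifact of real
recordings.

# Event analysis

Detection uses the field-standard two-threshold scheme: an event opens when
the current crosses `baseline - k*sigma` (k = 5) and closes on re-crossing
`baseline - k/2*sigma`; events shorter than 3 samples are discarded and
events touching the trace boundaries are dropped (censored sojourns would
bias the mean; at the trace lengths used the loss is negligible). Baseline
and sigma come from the highest mode of the kernel-smoothed all-points
histogram and a MAD around it. For exponential dwells the MLE of the time
constant is the sample mean (`mean(dwells) - t_min` under a hard detection
dead time); uncertainties are bootstrap SDs; the escape rate is
$1/\hat\tau$ and the capture rate is events per unit *unoccupied* time
(a `normalization = "total"` option exists because published "molecules/s"
figures do not always state the convention).

A dead-time correction for missed short events
($N/\exp(-t_\text{min}/\hat\tau)$) is implemented but **off by default**:
on band-limited traces the causal filter stretches each pulse by roughly
its rise time, so sub-dead-time events are mostly still detected, and
applying the hard-dead-time correction over-counts — we verified this
against the generator's ground-truth state paths, where the uncorrected
estimator recovers capture rates within a few percent even at dwell times
of eight samples. Events shorter than three filter rise times carry a
`quality_ok = FALSE` flag because their amplitudes are attenuated.

Noise metrics use a Welch PSD (Hann window, half-overlapping segments,
default length $2^{14}$), one-sided and Parseval-normalised, with the
pink/white decomposition $S(f)=A/f^\alpha+B$ fit by least squares on the
log-PSD over 1 Hz–1 kHz, where the excess noise lives.

# Interpretation layer

Fold changes of trapping times convert to barrier changes through the bare
Boltzmann factor, $\Delta\Delta G = \ln(\tau_a/\tau_b)\,k_BT$, assuming the
attempt frequency is unchanged between conditions (reasonable when the
trap geometry is unchanged and only the escape pathway is blocked); the
headline 100-fold extension is $\ln 100 \approx 4.6 \approx 5\,k_BT$. The
mass dependence of trapping times is fit as $\ln\tau = \ln\tau_0 + bM$ in
log space, where multiplicative scatter is homoscedastic. The drag force on
a trapped protein is the Stokes estimate $F = 6\pi\eta r v$ with $v$ taken
from the solved velocity field at the protein's position — a few pN at
cm/s-scale EOF velocities.

# Reproducibility and scope

Every stochastic function takes an explicit integer seed and is bit-for-bit
reproducible; traces and event tables round-trip through CSV files with a
JSON metadata header carrying the full generator configuration. Known
limitations: the axisymmetric reduction cannot represent genuinely
non-axisymmetric docking poses; the smeared porous sphere has no rod-level
structure; the trapped protein is not resolved in the flow field; and the
solver is steady-state, so docking dynamics and voltage-ramp experiments
are out of scope.
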