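---
title: "Modeling magnetically guided bioassembly of nanoparticle-coated microtissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling magnetically guided bioassembly of nanoparticle-coated microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(magassembly)
```

## The model

`magassembly` simulates the magnetically guided assembly of cartilaginous
microtissues ("spheroids") coated with superparamagnetic iron oxide
nanoparticles (MNPs) in a cylindrical culture well placed over a small
permanent magnet. Each microtissue is a single elastic sphere in an
overdamped force balance: at every instant the Stokes drag and the
velocity-dependent contact friction balance the magnetic pull, net
gravity, and the Hertzian contact repulsion,

$$ \mathbf F_{d,i} + \sum_{\delta_{ij} \ge 0}\mathbf F_{c,ij}
 + \mathbf F_{m,i} + \mathbf F_{g,i}
 + \sum_{\delta_{ij} \ge 0}\mathbf F_{k,ij} = 0 . $$

Because every velocity-dependent term is linear in the velocities, each
step reduces to a sparse symmetric positive-definite linear system
$C\mathbf v = \mathbf F$: diagonal $3\times3$ blocks carry the Stokes
coefficient $6\pi\eta_m r_i$ plus the contact-damping blocks
$S_{ij}\,[c_n\hat n\hat n^T + c_t(I-\hat n\hat n^T)]$, and off-diagonal
blocks of contacting pairs carry the negated damping block. The system is
solved by Jacobi-preconditioned conjugate gradients (relative residual
$10^{-10}$, warm-started from the previous step) and positions advance
semi-implicitly, $x \leftarrow x + \Delta t\, v$, with an optional
$\sqrt{2D}\,dW$ Wiener increment. Thermal forces are negligible for
bodies of ~100 µm radius, so `D = 0` by default and the diffusion term is
inert. The degree of implicitness `lam` defaults to 0 (fully explicit);
for `lam > 0` the Hertz stiffness blocks
$k_{ij} = \partial F_k/\partial\delta\,\hat n\hat n^T$ augment the
operator as $(C + \lambda\,\Delta t\,k)$, which only damps the contact
response.

### Forces

* **Magnetic.** A single nanoparticle of volume $V_{NP}$ feels
  $\mathbf F = \mu_0 V_{NP} f(|H|)\,(\mathbf H\cdot\nabla)\mathbf H$,
  with the piecewise magnetization factor $f(H) = 3$ below saturation
  ($|H| < M_{NP}/3$, the high-susceptibility sphere limit) and
  $M_{NP}/|H|$ above it; $M_{NP}$ is the volumetric saturation
  magnetization, 60 emu g⁻¹ × 5180 kg m⁻³ = 3.11×10⁵ A m⁻¹. In the
  current-free exterior of the magnet,
  $(\mathbf H\cdot\nabla)\mathbf H \equiv \tfrac12\nabla|H|^2$, which is
  the form evaluated (and the identity is asserted in the tests). A
  spheroid carrying $N_{NP,i}$ particles feels $N_{NP,i}$ times the
  single-particle force at its centre.
* **Gravity/buoyancy.** $\frac43\pi r_i^3(\rho_s-\rho_m)g$ downward, with
  $\rho_s = 1014$, $\rho_m = 1000$ kg m⁻³.
* **Hertz contacts.** Overlap $\delta_{ij} = r_i + r_j - |x_i - x_j|$
  (for the well: $\delta_{iw} = r_i - (x_i - x_w)\cdot\hat n_w$ against
  the analytic cylinder floor and side), repulsion
  $\frac43 E^* \sqrt{\hat r_{ij}}\,\delta^{3/2}\hat n$ with
  $\hat r_{ij} = r_ir_j/(r_i+r_j)$ (wall: $\hat r = r_i$) and contact
  area $S_{ij} = \pi\delta\hat r$. The effective modulus combines both
  bodies as $1/E^* = (1-\nu^2)/E_a + (1-\nu^2)/E_b$ with $\nu = 1/2$
  (incompressible soft tissue), the standard discrete-element
  convention; with the 120 Pa spheroid and 1000 Pa well moduli this
  gives 80 Pa (spheroid–spheroid) and 143 Pa (spheroid–wall). The
  spheroid–well adhesion energy density (10⁻²⁰ N m⁻¹) is stored in the
  configuration for fidelity but no adhesion force is applied: it enters
  no model equation and is numerically negligible at that value.
* **Rotation** is ignored throughout; `c_n`, `c_t` absorb wet and
  rolling friction.

### The magnet field

The field of the 5 mm × 5 mm NdFeB cylinder (remanence 1.48 T) is the
exact field of a uniformly axially magnetized cylinder, evaluated through
Bulirsch's generalized complete elliptic integral `cel` (the
equivalent-solenoid form). The magnet sits under the well; the
plate-bottom thickness separating its top face from the well floor is not
a measured quantity, so by default the gap is calibrated (≈1.04 mm) so
that the on-axis flux density at the well-floor centre equals the
measured 0.4 T maximum. A remanence-calibration mode (fixed gap, rescaled
Br) is also provided. The production engine interpolates |H| and
$\tfrac12\nabla|H|^2$ bilinearly from a 400×400 axisymmetric (ρ, z) table
precomputed with the exact evaluator; the table tracks the exact force to
about one part in 10³ across the well, and the exact evaluator remains
the reference for all field-level tests.

### Nanoparticle allocation

The total added MNP mass (10 µg or 20 µg for the "30" and "60" µg Fe mL⁻¹
incubation conditions) fixes the total particle count
$N_{tot} = m/(V_{NP}\rho_{NP})$ with $\rho_{NP} = 5180$ kg m⁻³
(magnetite; the value is not printed in the source material and is
configurable). A fraction $\alpha = 0.75$ binds to the spheroids,
distributed in proportion to surface area, and each spheroid's count is
drawn from a normal with standard deviation equal to half its mean. How
negative draws were handled originally is unstated; we truncate at zero
and round, which biases the population total upward by well under 1% at
these means (the mass-conservation property is verified by Monte Carlo).

## Parameters

All defaults reproduce the published model-parameter table: Δt = 5×10⁻⁵ s,
μ₀ = 1.256×10⁻⁶ N A⁻², g = 9.807 m s⁻², η_m = 1.2×10⁻³ Pa s,
ρ_m = 1000 and ρ_s = 1014 kg m⁻³, E_well = 1000 Pa, E_spheroid = 120 Pa,
c_t = c_n = 0.6 Pa s m⁻¹, t_end = 60 s, I_out = 1 s, λ = 0, α = 0.75.
Quantities the source does not specify, fixed once here:

* **Well radius 7.8 mm, fill height 5 mm** — nominal 24-well plate
  geometry and ~1 mL medium.
* **Spheroid radii**: lognormal, mean 100 µm, CV 0.1; **n = 1200** per
  well by default (300,000 cells per well at ~250 cells per microtissue).
* **Magnet gap**: calibrated to the 0.4 T floor field (above).
* **Initial placement**: uniform in the well volume with full containment
  and no initial overlaps, mimicking freshly pipetted microtissues.

## Numerical choices

* **Timestep and stability.** With the soft contacts the Hertz relaxation
  time can approach Δt; an adaptive sub-stepping guard splits any step
  whose largest displacement would exceed 10% of the smallest radius,
  re-solving forces at each substep. Halving Δt changes final positions
  of a 50-spheroid reference run by <0.4% of a radius.
* **Contact detection** uses a sorted cell list (cell size twice the
  largest radius), verified against the all-pairs brute force.
* **Coverage** is the union of equatorial disks projected on the floor,
  rasterized at r_min/10 pixels, clipped to the 2.5 mm magnet-footprint
  ROI. The rasterizer matches closed-form disk-union areas to ~0.1%.
* **Assembly time** is defined as the first time the coverage reaches 95%
  of its final plateau (linearly interpolated); the source never defines
  its "time coefficient", so an exponential-fit time constant is also
  available (`assembly_time(..., method = "exp_fit")`). A series still
  visibly rising at its end is flagged rather than silently accepted.
* **Saturation read-off** for hysteresis curves interpolates linearly at
  ±7 T and uses the odd part $(m(+7) - m(-7))/2$, making the
  control-subtracted mass exactly invariant to any shared additive
  background.
* **Fiber directionality** uses a Hann-windowed 2D power spectrum
  accumulated into angular bins on [0°, 180°) (frequency angle + 90° =
  fiber angle), excluding DC, radii below 3 cycles and beyond Nyquist;
  the dominant direction comes from a wrapped-Gaussian least-squares fit
  initialised at the axial circular mean. Bin width (2° at the default 90
  bins) and the window are configurable; angle recovery is within ±2°
  down to SNR 3 on stripe fixtures.

## Stress profiles: a genuinely open definition

The radial and vertical stress readouts admit two natural definitions,
and the package exposes both (`stress_profiles(component = ...)`):

* `"body"` — the per-spheroid body force (magnetic + net gravity) over
  the cross-section $\pi r_i^2$. Its vertical component is nearly
  constant across the construct (the magnetic pull toward the magnet face
  dominates), matching the observed near-constancy of the vertical
  profile. Its radial component, however, vanishes on the axis by
  symmetry and *grows* outward — it cannot produce a radial profile that
  peaks at the centre and decays with distance.
* `"transmitted"` — the standard per-particle Cauchy stress assembled
  from the Hertzian contact forces,
  $\sigma_i = V_i^{-1}\sum_c \mathbf b_c \otimes \mathbf F_c$. This is
  the load the tissue actually carries. Accumulating the inward magnetic
  push of the outer material, it peaks at the construct centre and decays
  monotonically outward — the shape the radial measurements show.

The package therefore reports the radial profile from the transmitted
stress and the vertical profile from the body stress in its analysis
scripts, and keeps `"body"` as the default component of
`stress_profiles()` for the simple force-per-area reading. In our
scaled-down runs (n = 300) the transmitted radial peak is about
−11 N m⁻² (10 µg) and −13 N m⁻² (20 µg): compressive, correctly ordered,
and centre-peaked, but a factor ~2.5–4 below the reported −30 / −52
N m⁻². The total inward magnetic force — fixed by the added MNP mass and
the 0.4 T-calibrated field — bounds the radial load the pile can
accumulate, and spheroids arrive sequentially rather than pressing
simultaneously from the strong-gradient annulus, so the model as
published cannot reach those magnitudes; we report the discrepancy
rather than re-tuning any parameter toward it. Vertical stresses
(≈ −12 and −23 N m⁻²) and assembly times reproduce the reported values
closely, supporting the overall force calibration.

## What the synthetic data emulate — and what they do not

The generators reproduce the stochastic structure the analysis assumes:
unimodal (lognormal) radii, uniform random placement, surface-area-
weighted nanoparticle loading with 50% relative spread, Langevin-shaped
superparamagnetic hysteresis with flat controls, and sinusoidal fiber
textures at known orientation. They do not emulate microtissue shape
irregularity, aggregation during pipetting, nanoparticle detachment over
culture time, field inhomogeneity from neighbouring magnets in the
multi-well grid, or the image-formation physics of second-harmonic
microscopy — so green tests demonstrate correctness of the algorithms
under the model's assumptions, not fidelity of those assumptions to any
particular experiment.

## Problem sizes

Simulation-based tests and the acceptance script run n = 300 spheroids
(the desk-scale end of the 300–1200 range) for 6–10 simulated seconds —
assembly completes within ~3 s and the coverage series plateaus well
before the window ends — with three to five seeds per condition. The
Table-defaults (n = 1200, t_end = 60 s) remain the package defaults for
full-scale runs.

## Known limitations

* No hydrodynamic coupling between spheroids (independent Stokes drag),
  no lubrication, no tangential spring friction, no rotation — as in the
  source model.
* The magnet-grid geometry is reduced to a single cylinder under the
  well; superposition of several cylinders is possible through
  `magnet_spec` objects but is not calibrated against field maps.
* The radial transmitted-stress magnitude falls short of the reported
  values (discussed above).
* Spheroids are non-deformable spheres; large Hertz overlaps at these
  soft moduli stand in for visible flattening of real microtissues.

## A worked micro-example

```{r example}
params <- sim_params(t_end = 4, seed = 1, m_NPtot = mnp_total_mass("30"))
res <- run_simulation(params, magnet_spec(), nanoparticle_spec(),
                      well_geometry(), n = 300, kin_interval = 0.05)
assembly_time(res$kinetics)
stress_profiles(res$final, magnet_spec(), nanoparticle_spec(), params,
                component = "transmitted")
```
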