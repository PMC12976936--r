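---
title: "Virtual TEVG implantation: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual TEVG implantation: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tevgsim)
```

## The problem

A patient-specific tissue-engineered vascular graft (TEVG) is designed on a
preoperative anatomy, manufactured, and sutured in place of a resected aortic
segment. The implanted graft never sits exactly where the design assumed: the
suture line lands millimetres away, the graft is rotated, and the manufactured
size differs from the plan. `tevgsim` asks the quantitative question behind
those observations: *how much placement imprecision can a graft tolerate
before the postoperative shape and hemodynamics leave the clinically safe
envelope?*

The package builds the whole chain in code: a parametric synthetic aorta, the
virtual clamp/resection/graft-design step, a controlled placement deviation, a
hyperelastic membrane finite-element (FE) solve of the end-to-end anastomosis,
a reduced-order hemodynamic evaluation, and one-factor tolerance sweeps that
map allowable deviations.

## Synthetic anatomy

`generate_aorta()` lofts a structured quadrilateral shell over a candy-cane
centerline (straight ascending segment, circular arch, straight descending
segment) with 0-2 supra-aortic branch tubes. Coordinates follow a right-handed
patient frame: +x = anatomical Left, +y = Anterior, +z = Superior; all
geometry is in mm. Rings are placed on rotation-minimizing frames rather than
Frenet frames so the circumferential parametrization carries no twist flips at
curvature sign changes.

Published dimensions for this porcine protocol stop at animal mass
(20-30 kg), so the defaults are configurable stand-ins chosen once at sizes a
cardiovascular modeller would call plausible for that mass: lumen radius 6 mm,
arch radius 25 mm, wall thickness 1.5 mm, branch radii 3-3.5 mm. The optional
seeded radial noise (off by default) perturbs the radius profile smoothly to
emulate anatomic irregularity; everything else in the generator is
deterministic for a fixed seed.

What the generator does **not** emulate: non-circular lumen sections, vessel
taper patterns of a real aorta, wall-thickness variation, and the image
segmentation noise of MRA-derived models. Tests passing on these synthetic
anatomies demonstrate correctness of the machinery, not fidelity to any
individual animal.

The designed anatomy is the imaged anatomy expanded uniformly by 5%
(`growth_scale = 1.05`, applied via `scale_uniform()`) to account for animal
growth between imaging and implantation.

## Resection, graft design and deviations

`place_resection_planes()` puts the two clamp/anastomosis planes perpendicular
to the centerline; `resect()` splits the trunk at the structured rings nearest
the planes and projects those rings exactly onto the planes (the cut-band
re-mesh). Because both sides of each cut inherit the same ring, the mating
loops automatically carry equal node counts — the contract the anastomosis
coupling relies on. `design_graft()` lofts the graft over the resected
segment's centerline and then assigns its end rings the (diameter-scaled)
native cut-ring geometry, so a unit-scale design mates the native cut exactly.

`apply_deviation()` realizes the placement error: rotation (right-hand rule,
intrinsic L-R then A-P then I-S order) about the proximal anastomosis-plane
center, translation, and uniform size scaling about the same center. The
anastomosis plane co-moves with L-R translations and with all rotations (those
shift the resection location), and stays put for A-P and I-S translations.
Two open choices were settled as follows and are flagged here deliberately:

* **Scaling center.** Size deviations scale about the proximal anastomosis
  centroid, not the graft centroid, so size mismatch does not also translate
  the proximal suture line; the size effect stays isolated.
* **Resection re-cut.** An L-R translation conceptually shifts the resection
  location. The sweep pipeline applies the deviation to the graft and carries
  the plane transform as bookkeeping; the native trunk is not re-resected per
  grid point. This keeps every sweep point on the same native mesh, which is
  what makes percent differences between grid points meaningful.

`sample_deviation_thresholds()` turns observed deviations into sweep ranges as
the per-axis sample mean plus/minus two sample standard deviations.

## The anastomosis FE model

The native remnant and the graft are merged into one membrane shell
(4-node quads, 2x2 Gauss, total Lagrangian). The wall is an incompressible
isotropic Yeoh solid,

$$W = C_{10}(I_1-3) + C_{20}(I_1-3)^2 + C_{30}(I_1-3)^3,$$

with plane-stress incompressibility enforced analytically through the
thickness stretch \(\lambda_3 = 1/(\lambda_1\lambda_2)\); at a Gauss point
\(I_1 = \mathrm{tr}(A^{-1}a) + \det A/\det a\) with \(A, a\) the reference and
current in-plane metrics. Bending stiffness is omitted — the suture pull is
resisted in-plane — which is a deliberate simplification of the shell walls.
The graft wall uses the same form with every coefficient multiplied by 2.5
(the "2.5x less compliant" reading as a coefficient scaling; an alternative
reading — 2.5x tangent stiffness at a reference strain — would change the
multiplier's meaning, not the machinery). The default coefficients
(C10 = 30 kPa, C20 = 150 kPa, C30 = 1000 kPa, native thickness 1.5 mm, graft
0.7 mm) are stand-ins of the order measured for porcine thoracic aorta; they
are user-configurable and are not values from any specific published fit.

Suturing is node-to-node: `pair_nodes()` matches the equal-count edge loops by
the cyclic offset and winding that minimize the total angular difference of
centroid direction vectors. Each pair becomes a multi-point constraint with a
dummy offset equal to the initial gap,
\(u_{\text{native}} = u_{\text{graft}} - (X_{\text{native}} -
X_{\text{graft}})\), so satisfied constraints make paired nodes coincide.
Constraints are imposed by exact slave-DOF elimination — closure is machine
precision by construction, not a penalty approximation. The offsets are ramped
linearly over the load steps.

Three numerical choices deserve emphasis:

* **Graft anchoring.** A free graft held only by the anastomosis constraints
  has an exact zero-energy mode: rigidly sliding back to the designed pose
  undoes any placement deviation at no cost, making every deviation
  hemodynamically invisible. Physically the graft body sits where the surgeon
  placed it while the tissues accommodate. The solver therefore clamps the
  graft's middle ring at its implanted pose by default
  (`graft_anchor = "mid_ring"`); both anastomoses still deform according to
  the native/graft stiffness balance. `"all"` (rigid graft) and `"none"`
  (for fixtures that clamp graft boundaries explicitly) are available.
* **Wrinkling stabilization.** A bare membrane has zero or negative stiffness
  against in-plane compression; wrinkling makes the energy landscape
  oscillatory and static solvers unusable. A small convex 2-D neo-Hookean
  term \(k_s(\mathrm{tr}(A^{-1}a) - 2 - \ln(\det a/\det A))\) with
  \(k_s = 0.05\,C_{10}\) restores mild positive stiffness in compression
  while perturbing tensile response by a few percent
  (`stabilization` argument; 0 recovers the bare membrane).
* **Solver.** Each ramp increment is solved by quasi-Newton energy descent
  (L-BFGS with an inversion barrier) from a linearly extrapolated warm start,
  then polished by damped Newton with an adaptively regularized sparse
  tangent (constant sparsity pattern, cached CHOLMOD symbolic analysis). A
  failing increment first triggers one direct solve of the full gap closure
  (intermediate ramp states can snap through configurations the final state
  does not visit) and then adaptive bisection of the ramp. The pipeline
  default of 2 ramp increments (rather than the solver's general default of
  10) relies on this adaptivity and was chosen for throughput after
  verifying identical converged states on representative cases.

An increment is accepted at a relative residual of 1e-8 (with an absolute
floor scaled by a characteristic nodal force), at a stalled residual below
1e-5 of that characteristic force, or when the quasi-Newton stage terminates
on its own energy-stationarity test (relative energy change ~1e-13): in
wrinkled zones the raw gradient norm sits on a noise floor that pure residual
criteria cannot cross, while the energy is stationary to machine precision.
With wrinkling the energy is non-convex and admits multiple local minima;
converged states are deterministic for a given configuration, but
quantitative stresses inside wrinkled zones should be read as regularized
approximations.

## Reduced-order hemodynamics

The package deliberately replaces 3-D CFD with a 0-D surrogate — the central
fidelity decision of the artifact. The deformed lumen is profiled at the
structured mesh rings (`extract_lumen_profile()`): ring polygon vector-areas
give section areas and area-equivalent radii; ring stations of a deformed
assembly stack remnant, graft and remnant segments into one trunk profile and
attach branch profiles at their take-off stations. `build_network()` turns
inter-station segments into Poiseuille resistances
\(R = 8\mu L/(\pi r^4)\) (trapezoidal in \(r^{-4}\)), series-connected, with a
three-element Windkessel (proximal resistance, compliance, distal resistance)
at every outlet — the same boundary-condition structure a 3-D solve would use.
Blood is Newtonian with the single printed viscosity 0.00371 Pa s and density
1060 kg/m3.

`simulate_network()` prescribes a pulsatile inflow (default: half-sinusoid
systole over one third of a 0.5 s cycle, 200 mL/s peak — a generic porcine
aortic-root shape, configurable) and integrates the compliance states with
the trapezoidal theta-scheme coupled implicitly to the resistive network
solve. Second-order integration was chosen over first-order implicit Euler
because the latter leaves a few-tenths-percent amplitude error at practical
step sizes; `theta = 1` recovers implicit Euler if wanted. Cycles repeat until
the cycle-to-cycle pressure change falls below 0.1 mmHg (at most 10 cycles).

Metrics follow the clinical definitions: PSPD is the ascending-to-descending
pressure difference at the instant of peak inflow (a `max_diff` mode computes
the maximum instantaneous difference instead — the definition is ambiguous in
the clinical wording, both are available); TAWSS uses the Poiseuille closure
\(\tau = 4\mu|Q|/(\pi r^3)\) averaged over the final cycle, with the maximum
over network segments standing in for the pointwise surface maximum. What the
surrogate preserves: metric definitions, outlet physics, and the monotone
geometry-to-hemodynamics relationships (resistance ~ r^-4, shear ~ r^-3) that
tolerance maps rely on. What it cannot represent: secondary flows, curvature
and entrance effects, turbulence, and any localized WSS pattern — absolute
magnitudes are indicative only, and comparisons across grid points are the
meaningful output.

## Tolerance maps and shape validation

`run_sweep()` evaluates a one-factor-at-a-time grid (translations in 1-mm,
rotations in 5-degree, size in 5% increments — the study's increments — with
optional opt-in 2-D factor pairs), computes percent differences of PSPD and
max TAWSS against the zero-deviation baseline, classifies each point against
the safe limits (PSPD < 20 mmHg, 0.4 Pa < TAWSS < 15 Pa, strict
inequalities), and extracts per-direction allowable ranges as the maximal
contiguous safe interval containing the baseline (a safe island disconnected
from zero does not count). Failed FE points are recorded as unevaluated,
never dropped. `scale < 1` denotes an undersized graft.

`run_shape_validation()` reproduces the shape-accuracy protocol: apply an
observed deviation, solve the anastomosis FE problem, and compare (A) the
unchanged design and (B) the FE-informed prediction against a postoperative
reference, reporting `100 (A_mean - B_mean) / A_mean`. With no imaging data
available the reference is synthetic: the FE solution under the observed
deviation plus seeded Gaussian surface noise (0.2 mm by default), labelled as
such. Surface distances are symmetric (mean of both directed means); whether
the original protocol used one-directed or symmetric means is unstated, so
the symmetric choice is flagged here.

## Problem sizes and determinism

The package's own test and reporting sizes, chosen as the smallest meshes
whose refinement changes the reported quantities by a few percent or less:
anatomy meshes of 16-32 circumferential nodes; implantation sweeps on
1,100-1,900-element assemblies with 2 ramp increments; hemodynamics at 200
steps per cycle (1,000 for analytic comparisons); 50 lumen stations; and
shape metrics from a few thousand seeded area-weighted surface samples.
Every random element (generator noise, surface sampling, validation noise)
is governed by explicit seeds; identical configuration and seed reproduce
byte-identical sweep tables.

## Known limitations

* The anastomosis model has no bending stiffness, no contact, no pressurized
  equilibrium and no layered or anisotropic wall — converged shapes near
  strongly wrinkled zones depend on the stabilization constant.
* The hemodynamic surrogate is 0-D; its absolute PSPD/TAWSS values inherit
  Poiseuille assumptions and a generic inflow, so safe-limit crossings mark
  relative, not patient-absolute, thresholds.
* Euler-angle decomposition of rotations is convention-dependent
  (intrinsic L-R, A-P, I-S here); reports near gimbal lock
  (middle angle near 90 degrees) are flagged.
* The in-vivo arm of the original study (four porcine anatomies, commercial
  FE/CFD toolchains) is not reproducible here; all inputs are synthetic and
  all comparisons are property-based.
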