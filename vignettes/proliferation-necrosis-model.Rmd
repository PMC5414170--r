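---
title: "An image-driven proliferation–necrosis model of glioblastoma"
author: "gliosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An image-driven proliferation–necrosis model of glioblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gliosim` evolves the tumor cell density $c(\mathbf{x}, t)$
(cells/mm³) on a voxel grid with physical spacing, inside a brain mask:

$$
\frac{\partial c}{\partial t} =
\begin{cases}
\nabla\!\cdot\!\big(\mathbf{D}(\mathbf{x})\,\nabla c\big) + R(c)
  & \max_{s \le t} c(\mathbf{x}, s) < \tau\, c_m \\[4pt]
\ln(\eta)\, c
  & \max_{s \le t} c(\mathbf{x}, s) \ge \tau\, c_m
\end{cases}
$$

The diffusion tensor $\mathbf{D}$ encodes the strong preference of
glioblastoma cells to migrate along white-matter fiber bundles: it is
obtained from a DTI spin tensor by raising its eigenvalues to a power
(keeping eigenvectors) and rescaling so the mean diffusivity matches the
image-derived estimate (`cellTensorFromSpin()`). $R(c)$ is logistic by
default, $\rho c (1 - c/c_m)$, with exponential and Gompertz variants.

The necrosis switch is *history dependent*: it tests the running maximum
$m(\mathbf{x}) = \max_s c(\mathbf{x}, s)$, never the current density, so
a voxel that has once crossed $\tau c_m$ remains necrotic while its
population decays. We read $\eta \in (0,1)$ as a per-day survival
fraction, $c(t+\Delta t) = \eta^{\Delta t} c(t)$. The differential form
$\partial c/\partial t = \eta c$ with positive $\eta$ would *grow* the
density; only the survival-fraction reading produces the exponential
decay that the necrosis term is meant to model and preserves the stated
direction "narrower enhancement ↔ smaller $\eta$". This is the one
deliberate reinterpretation in the package, and it is confined to
`necrosisUpdate()`.

Assumptions inherited from the model family: $\mathbf{D}$ is constant in
time, $\rho$, $\tau$, $\eta$ are constant in space and time, and no
treatment effects are represented.

## Parameters

| parameter | units | default | origin |
|---|---|---|---|
| $\rho$ | /day | 0.33 | slope/gap of serial radii via `fisherEstimate()` |
| $D$ (mean cell diffusivity) | mm²/day | 0.0825 | same estimation |
| $c_m$ | cells/mm³ | $10^5$ | fixed carrying capacity |
| $\tau$ | fraction of $c_m$ | 0.85 | `calibrateTau()`: T1 detection fraction 0.80 + 0.05 margin when necrosis is present at the first study; later necrosis maps linearly to larger values |
| $\eta$ | per-day survival fraction | 0.9 | `calibrateEta()` against the observed rim width |
| $\Delta t$ | days | 1 | reporting cadence; the solver substeps internally |
| seed density $c_0$ | cells/mm³ | $0.1\,c_m$ | below every detection and necrosis threshold, so the full growth dynamic is observable |

The imaging thresholds 0.16 and 0.80 of $c_m$ (T2 margin and
contrast-enhancing T1 margin) are used consistently by
`detectionMask()`, `rimWidth()` and the parameter estimation.

### The Fisher closure

Serial imaging gives radii, not $(\rho, D)$. Two relations close the
system: the asymptotic front speed of the Fisher–KPP equation,
$v = 2\sqrt{\rho D}$, measured as the least-squares slope of the T2
radius in time; and the traveling-wave tail
$c \propto e^{-x\sqrt{\rho/D}}$, which fixes the gap between the
0.16 and 0.80 contours at $\Delta r = \sqrt{D/\rho}\,\ln 5$. Hence

$$\rho = \frac{v \ln 5}{2 \Delta r}, \qquad D = \frac{v\, \Delta r}{2 \ln 5}.$$

The estimate is self-consistent ($v = 2\sqrt{\rho D}$ holds exactly) and
`syntheticRadii()` inverts it, which the tests use as a round-trip
property. Under a rigid traveling wave the T1 and T2 slopes are equal;
the T2 channel is the default because the outer margin is the one the
wave-speed argument describes, and the choice is configurable.

### Eigenvalue amplification

The "differential scaling" that turns a spin tensor into a cell tensor
is implemented as a power law on eigenvalues (default exponent 2) with a
global mean-diffusivity renormalization. This choice preserves
symmetry, positive semi-definiteness and eigenvectors; exponent 1
degenerates to a shape-preserving rescale, and fractional anisotropy is
non-decreasing in the exponent (a tested property).

## The finite-difference scheme

`diffusionDivergence()` discretizes
$\nabla\!\cdot(\mathbf{D}\nabla c)$ in conservative flux form. For each
face between two in-mask voxels the flux is
$F = \bar{\mathbf{D}}\,\overline{\nabla c}$ with the arithmetic mean of
the two adjacent tensors, a centered difference for the normal gradient,
and the average of the two voxels' mask-aware central differences for
the tangential gradients (the mixed-derivative terms of anisotropic
tensors). Each face's flux enters its two voxels with opposite signs, so
total mass is conserved *by construction* — the conservation test
demands $10^{-8}$ relative over 100 days and the scheme delivers
rounding-level drift. Faces touching out-of-mask voxels carry no flux:
a homogeneous Neumann boundary at the brain mask (cells do not cross the
skull), the standard choice where the source model is silent.

Time integration is forward Euler. The stability estimate is

$$\Delta t_{\mathrm{stab}} = \Big(2 \max_{\mathbf{x}} \sum_{ij}
  |D_{ij}(\mathbf{x})| / (h_i h_j)\Big)^{-1},$$

deliberately summing all nine components: the common trace-only bound
ignores the mixed terms and is not safe for strongly anisotropic
tensors. The solver substeps so that the internal step stays below
`cfl` × this bound with `cfl = 0.25` by default. The safety factor is a
numerical-quality choice, not just a stability one: explicit Euler near
the bare bound is oscillatory, and the speed of pulled (Fisher) fronts
carries a first-order error in the time step. Note the spatial and
temporal discretization errors act on the front speed in opposite
directions (the lattice accelerates the front, the finite time step
slows it); at 1 mm and the defaults the simulated front speed lands
within the 15% band around $2\sqrt{\rho D}$ that the acceptance test
checks. Halving the substep moves the 30-day front by less than one
voxel (tested), but pointwise differences near a moving front are large
by nature — self-convergence is asserted on the front position, not in
the max norm.

Within each substep the order is: divergence and proliferation are
evaluated, live voxels advance, necrotic voxels decay by
$\eta^{\Delta t_{\mathrm{sub}}}$, densities are clipped to $[0, c_m]$
(clip events are counted in the run log), the history maximum $m$ is
updated, and only then is the necrotic set re-classified — so newly
necrotic voxels begin decaying on the *following* substep and the
$\tau$-crossing time does not depend on voxel enumeration order.
Necrotic voxels are excluded from the live update but their decaying
densities remain visible to their neighbours' stencils: the core acts as
a diffusive sink that erodes the enhancing rim from inside. A
non-finite density anywhere aborts the run naming the voxel and substep;
in practice clipping makes the scheme extremely robust.

## Phantoms and pseudo-images

`isotropicPhantom()` builds an ellipsoidal "brain" inscribed in the grid
with uniform $d\,\mathbf{I}$ tensors. `fiberPhantom()` embeds a straight
cylindrical bundle of axially symmetric tensors whose fractional
anisotropy is *exact*: from the FA definition,
$\lambda_\perp = \mathrm{MD}(1 - x)$,
$\lambda_\parallel = \mathrm{MD}(1 + 2x)$ with
$x = \mathrm{FA}/\sqrt{3 - 2\,\mathrm{FA}^2}$, so mean diffusivity is
uniform across bundle and background and only the tensor *shape*
differs. Default scale is 64³ voxels at 1 mm — large enough that a
0.33 mm/day front stays clear of the mask over the simulated horizons,
small enough for desk-scale tests.

`pseudoT1()` renders a state as an intensity cartoon: bright enhancing
tissue ($c \ge 0.8 c_m$, non-necrotic), dark necrotic core, background
elsewhere, optionally over an anatomical background (`anatomyImage()`:
FA contrast plus smooth gradients, fully deterministic) and with
seed-controlled Gaussian noise that leaves the global RNG untouched. No
MR physics (relaxation, acquisition, partial volume) is simulated; the
images are sufficient for mutual-information comparisons, nothing more.

## Mutual information

`mutualInformation()` bins both fields into 64 equal-width bins spanning
their in-mask ranges (configurable), forms the joint histogram, and sums
$p \log_2 [p / (p_C p_S)]$ over occupied cells; empty cells contribute
zero by the $x \log x$ limit, the rightmost bin is closed so the maximum
lands inside, a constant field yields MI = 0, and the measure is
restricted to the brain mask (background air would inflate it). MI is
symmetric and non-negative by construction.

Histogram MI is an *estimator*: with $B^2$ cells and $N$ voxels it
carries a positive sampling bias of order $B^2/(2N \ln 2)$, which is why
independent noise can nudge small MI values upward. Tests that reason
about noise therefore use strong structure and moderate bin counts.

## The validation twin

The source study validated the model by simulating a patient's tumor in
a *volunteer's* brain and computing MI between simulation and the
patient's images at two studies 30 days apart — so even the generating
model faces an anatomy mismatch, and MI decays as the lesion grows. The
package reproduces the *structure* of that comparison (orderings, not
values, which depend on images that are not available) with a synthetic
twin chosen once:

* ground truth: the full model on a fiber phantom, "observed" as
  noiseless pseudo-T1 renderings over the anatomical background at days
  45 and 75 (a developed, necrotic lesion at the first study, as in the
  source data);
* candidates: isotropic/no-necrosis, tensor/no-necrosis, and the full
  model, all seeded one voxel from the truth's seed — the
  registration/intersubject residual.

Two design points matter. The anatomy background is essential: against
a flat background MI simply scales with lesion size and *rises* over
time for every model. And the rendering must be noiseless: at 64-bin
resolution even small image noise swamps the fine anatomy
correspondence that the decay rests on. With this twin the acceptance
test observes the expected ordering (full ≥ tensor ≥ isotropic at both
studies) and a decay of MI from the first to the second study for every
variant. The seed-displacement experiment (`seedSensitivity()`) runs the
full model from four cardinal one-voxel shifts on the isotropic phantom:
the four profiles' MI against the reference agree to float precision by
symmetry and sit strictly below the reference self-MI.

## The enhancing rim at 1 mm resolution

With $\tau = 0.85$ and logistic growth, the continuum traveling wave
spends only $(1/\rho)\ln\frac{0.85/0.15}{0.80/0.20} \approx 1$ day
between the 0.80 and 0.85 contours, i.e. the theoretical rim is a few
tenths of a millimeter wide; the diffusive sink of the necrotic core
stretches the simulated shell to roughly one voxel (~1.1–1.2 mm at
1 mm spacing, measured by the volume-equivalent radius difference
`rimWidth()`). The 2–3 mm band reported for the source lesion is not
reached by this discretization for *any* $\eta$, and the corresponding
acceptance check is intentionally left failing rather than redefining
the measure — the source's own discretization (grid spacing, boundary
handling, rim measurement protocol) is unpublished. Two knock-on
effects are documented rather than patched:

* rim width is *not* monotone in $\eta$ here (erosion by the sink
  dominates at small $\eta$, fast classification at large $\eta$;
  the width peaks in between), so `calibrateEta()` is an argmin search
  with an explicit achievable-range error rather than a bisection; and
* the marginal growth/drain balance at the rim makes the voxelwise
  $\tau$-crossing speckled, so shell/core morphology is asserted on
  radial profiles, not on connected-component topology.

## Known limitations

2-D operation is supported as a singleton axis (radius measures switch
to disc equivalents), but all defaults are 3-D. No DWI preprocessing,
tensor fitting, registration, gray/white two-compartment model, or
treatment (radiotherapy/chemotherapy) effects. The NIfTI reader/writer
is deliberately minimal (single-file NIfTI-1, native types, pixdim
spacing; the affine is not interpreted) because the simulation lives in
voxel space. Real clinical use would add registration and a measured
DTI volume in place of the phantoms.
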