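# gliosim

Image-driven reaction–diffusion simulation of glioblastoma multiforme
(GBM) growth and necrosis on voxel grids, for researchers modeling
individual tumor progression from serial MR imaging.

GBM lesions expand by intrinsic cell division and by migration of tumor
cells preferentially along white-matter fiber bundles, and their dense
centers die back once the cell population outstrips the tissue's
supporting capacity — the necrotic core with a thin enhancing rim that
contrast-enhanced T1 imaging shows. `gliosim` implements this as a
piecewise reaction–diffusion model of the tumor cell density
*c*(**x**, *t*):

```
∂c/∂t = ∇·(D(x) ∇c) + ρ c (1 − c/c_m)        while max_t c(x) < τ·c_m
∂c/∂t = ln(η) c                              once  max_t c(x) ≥ τ·c_m
```

* **D**(**x**) — per-voxel cell diffusion tensor (mm²/day), derived from a
  DTI spin tensor by differential eigenvalue scaling, so cells migrate
  fastest along fiber directions; an isotropic scalar variant is included
  for comparison.
* ρ — proliferation rate (/day); logistic growth toward the carrying
  capacity c_m = 10⁵ cells/mm³ (exponential and Gompertz laws are also
  available).
* τ — necrosis threshold as a fraction of c_m. The switch tests the
  *historical maximum* of c, so a voxel stays necrotic even after its
  density decays below the threshold.
* η ∈ (0,1) — per-day survival fraction of necrotic tissue
  (c → η^Δt · c).

Model parameters are estimated from imaging: serial T2 and
contrast-enhanced T1 tumor radii (hypothesized to track the 0.16·c_m and
0.80·c_m density contours) give the radial velocity *v* and the contour
gap Δr, which invert through the Fisher–KPP traveling-wave relations
v = 2√(ρD) and Δr = √(D/ρ)·ln 5 to tumor-specific (ρ, D). Simulated
fields are compared against (pseudo-)images with a joint-histogram mutual
information metric in bits. Synthetic phantoms — isotropic media and
fiber bundles of exact fractional anisotropy — plus a pseudo-T1 renderer
make the entire pipeline testable with no patient data.

## Worked example

Estimate tumor-specific parameters from serial radii, then simulate 30
days of growth seeded inside a coherent fiber bundle:

```r
library(gliosim)

radii <- readRadiiCsv(system.file("extdata", "example_radii.csv",
                                  package = "gliosim"))
est <- fisherEstimate(radii)
est
#> EstimatedParams: v=0.33 mm/day, rho=0.33/day, D=0.0825 mm^2/day, tau=NA, eta=NA

params <- GrowthParams(rho = est@rho, cM = 1e5, tau = calibrateTau(TRUE),
                       eta = 0.9)
phantom <- fiberPhantom(shape = c(64, 64, 64), meanDiffusivity = est@dMean,
                        faTarget = 0.8)
state <- makeState(phantom$grid, c(32, 32, 32), params = params)
run <- simulateGrowth(state, phantom$tensor, params,
                      modelVariant("tensor", necrosis = TRUE), nDays = 30)
final <- run$snapshots[[length(run$snapshots)]]
final
#> SimulationState at t=30 days: max c=8.574e+04, 17 necrotic voxel(s)

c(t2_radius_mm = equivalentRadius(detectionMask(final, 0.16, params@cM),
                                  gridSpacing(phantom$grid)),
  rim_width_mm = rimWidth(final, params@cM))
#> t2_radius_mm rim_width_mm
#>    4.7075789    0.5086439
```

The radii were generated from (ρ, D) = (0.33, 0.0825) and are recovered
exactly; after 30 days the lesion's outer (T2, 0.16·c_m) margin has an
equivalent radius of 4.7 mm, its center has crossed the necrosis
threshold (17 voxels), and the enhancing shell around the nascent core is
about half a millimeter wide. `run$log` records per-day totals (cell
mass, peak density, necrotic voxel count, substeps, clip events) — the
time series the validation experiments consume.

A thin command-line front end with `phantom`, `simulate`, `estimate`,
`calibrate-eta`, `mi` and `seed-sensitivity` subcommands is installed at
`inst/scripts/gbmsim`; every subcommand wraps the exported functions
shown above and exchanges NIfTI volumes, CSV tables and JSON configs.

## Acceptance script

`scripts/acceptance.R` recomputes the headline quantity from scratch
against the installed package: it builds the 64³ voxel, 1 mm isotropic
brain phantom, runs the full proliferation–necrosis model for 30
simulated days with the case-study parameters (ρ = 0.33/day,
D = 0.0825 mm²/day, τ = 0.85·c_m, η = 0.9/day), measures the enhancing
rim width, and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/proliferation-necrosis-model.Rmd` documents the model and its
assumptions, the finite-difference scheme and its stability safeguards,
the parameter-estimation closures, what the phantoms do and do not
emulate, and the package's numerical design choices and known
limitations.
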