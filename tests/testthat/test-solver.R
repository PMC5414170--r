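test_that("diffusion divergence vanishes on uniform fields and checks grids", {
  ph <- isotropicPhantom(shape = c(15, 15, 15), meanDiffusivity = 0.1)
  vals <- array(0, gridShape(ph$grid))
  vals[brainMask(ph$grid)] <- 5
  cf <- DensityField(ph$grid, vals)
  expect_equal(max(abs(diffusionDivergence(cf, ph$tensor))), 0)

  other <- isotropicPhantom(shape = c(9, 9, 9), meanDiffusivity = 0.1)
  expect_error(diffusionDivergence(cf, other$tensor), "different grids")
  spin <- TensorField(ph$grid, tensorArray(ph$tensor), kind = "spin")
  expect_error(diffusionDivergence(cf, spin), "cell tensor")
})

test_that("isotropic tensor divergence matches a scalar Laplacian oracle", {
  g <- cubeGrid(21)
  d <- 0.1
  vals <- gaussianBump(g)
  div <- diffusionDivergence(DensityField(g, vals),
                             uniformIsotropicTensor(g, d))
  lap <- scalarLaplacian(vals, d)
  inner <- array(FALSE, gridShape(g))
  inner[3:19, 3:19, 3:19] <- TRUE
  # identical stencils in the interior; edges differ only by the
  # one-sided boundary handling
  expect_lt(max(abs(div - lap)[inner]), 1e-12)
})

test_that("proliferation laws evaluate to their closed forms", {
  g <- cubeGrid(3)
  cM <- 1e5
  at <- function(val, law, rho = 0.33) {
    p <- GrowthParams(rho = rho, cM = cM, growthLaw = law)
    proliferation(DensityField(g, array(val, c(3, 3, 3))), p)[1]
  }
  expect_equal(at(cM, "logistic"), 0)                       # carrying capacity
  expect_equal(at(cM / 2, "logistic"), 0.0825 * cM)         # rho/4 * cM
  expect_equal(at(1, "exponential", rho = 0.1), 0.1)
  expect_equal(at(0, "gompertz"), 0)                        # limit convention
  expect_equal(at(cM / exp(1), "gompertz"), 0.33 * cM / exp(1))
})

test_that("necrosis decay is geometric in time and the set never shrinks", {
  g <- cubeGrid(5)
  p <- caseParams(eta = 0.9)
  vals <- array(0, c(5, 5, 5))
  vals[3, 3, 3] <- p@cM
  nec <- vals >= p@tau * p@cM
  st <- syntheticState(g, vals, nec)

  one <- necrosisUpdate(st, p, dt = 1)
  expect_equal(densityValues(one)[3, 3, 3], 0.9 * p@cM)

  # eta -> 1 limit leaves the density untouched
  nearOne <- GrowthParams(rho = 0.33, cM = p@cM, tau = 0.85,
                          eta = 1 - 1e-12)
  expect_equal(densityValues(necrosisUpdate(st, nearOne))[3, 3, 3], p@cM,
               tolerance = 1e-9)

  cur <- st
  for (i in 1:10) cur <- necrosisUpdate(cur, p, dt = 1)
  expect_equal(densityValues(cur)[3, 3, 3], 0.9^10 * p@cM)
  # necrotic classification is permanent although c fell below tau*cM
  expect_true(all(necroticMask(cur)[necroticMask(st)]))
  expect_lt(densityValues(cur)[3, 3, 3], p@tau * p@cM)
})

test_that("zero density is an absorbing state and runs are deterministic", {
  ph <- isotropicPhantom(shape = c(11, 11, 11), meanDiffusivity = 0.0825)
  p <- caseParams()
  empty <- syntheticState(ph$grid, array(0, gridShape(ph$grid)))
  out <- simulateGrowth(empty, ph$tensor, p, modelVariant(), nDays = 5)
  expect_equal(max(densityValues(out$snapshots[[length(out$snapshots)]])), 0)

  st <- makeState(ph$grid, c(6, 6, 6), params = p)
  a <- simulateGrowth(st, ph$tensor, p, modelVariant(), nDays = 8)
  b <- simulateGrowth(st, ph$tensor, p, modelVariant(), nDays = 8)
  expect_identical(lapply(a$snapshots, densityValues),
                   lapply(b$snapshots, densityValues))
  expect_identical(a$log, b$log)
  # n_days = 0 returns only the initial state
  expect_length(simulateGrowth(st, ph$tensor, p, modelVariant(),
                               nDays = 0)$snapshots, 1L)
})

test_that("densities stay in [0, cM], m dominates c, necrosis grows", {
  ph <- isotropicPhantom(shape = c(15, 15, 15), meanDiffusivity = 0.0825)
  p <- caseParams()
  st <- makeState(ph$grid, c(8, 8, 8), c0 = 0.95 * p@cM, params = p)
  prevNec <- necroticMask(st)
  cur <- st
  for (d in 1:12) {
    cur <- stepState(cur, ph$tensor, p, modelVariant())
    v <- densityValues(cur)
    expect_true(all(v >= 0 & v <= p@cM))
    expect_true(all(historyMax(cur) >= v))
    expect_true(all(necroticMask(cur)[prevNec]))
    prevNec <- necroticMask(cur)
  }
  expect_equal(stateTime(cur), 12)
})

test_that("total mass is conserved with proliferation and necrosis off", {
  fb <- fiberPhantom(shape = c(24, 24, 24), meanDiffusivity = 0.0825,
                     faTarget = 0.8)
  p0 <- GrowthParams(rho = 0, cM = 1e5, tau = 0.85, eta = 0.9)
  st <- makeState(fb$grid, c(12, 12, 12), c0 = 5e4, params = p0)
  run <- simulateGrowth(st, fb$tensor, p0,
                        modelVariant("tensor", necrosis = FALSE),
                        nDays = 100, snapshotEvery = 100)
  mass <- run$log$totalMass
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-10)
})

test_that("peak density grows monotonically to saturation without necrosis", {
  ph <- isotropicPhantom(shape = c(15, 15, 15), meanDiffusivity = 0.02)
  p <- caseParams(rho = 0.5)
  st <- makeState(ph$grid, c(8, 8, 8), params = p)
  run <- simulateGrowth(st, ph$tensor, p,
                        modelVariant("tensor", necrosis = FALSE),
                        nDays = 40, snapshotEvery = 1)
  peaks <- run$log$maxDensity
  expect_true(all(diff(peaks) > -1e-9 * p@cM))
  expect_gt(max(peaks), 0.99 * p@cM)
})

test_that("an isotropic run is symmetric under axis permutations", {
  ph <- isotropicPhantom(shape = c(33, 33, 33), meanDiffusivity = 0.0825)
  p <- caseParams()
  st <- makeState(ph$grid, c(17, 17, 17), params = p)
  run <- simulateGrowth(st, ph$tensor, p, modelVariant(), nDays = 20,
                        snapshotEvery = 20)
  v <- densityValues(run$snapshots[[length(run$snapshots)]])
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2)))
    expect_lt(max(abs(v - aperm(v, perm))), 1e-9 * p@cM)
  expect_lt(max(abs(v - v[33:1, , ])), 1e-9 * p@cM)
})

test_that("halving the internal substep moves the front by less than a voxel", {
  ph <- isotropicPhantom(shape = c(41, 41, 41), meanDiffusivity = 0.0825)
  p <- caseParams()
  st <- makeState(ph$grid, c(21, 21, 21), params = p)
  radius <- function(cfl) {
    run <- simulateGrowth(st, ph$tensor, p,
                          modelVariant("tensor", necrosis = FALSE),
                          nDays = 25, snapshotEvery = 25, cfl = cfl)
    fin <- run$snapshots[[length(run$snapshots)]]
    equivalentRadius(detectionMask(fin, 0.16, p@cM), gridSpacing(ph$grid))
  }
  expect_lt(abs(radius(0.25) - radius(0.125)), 1)
})

test_that("the isotropic variant demands a scalar and tensor a field", {
  ph <- isotropicPhantom(shape = c(9, 9, 9), meanDiffusivity = 0.1)
  p <- caseParams()
  st <- makeState(ph$grid, c(5, 5, 5), params = p)
  expect_error(stepState(st, ph$tensor, p, modelVariant("isotropic")),
               "scalar")
  expect_error(stepState(st, 0.1, p, modelVariant("tensor")),
               "TensorField")
  # isotropic-scalar and uniform-tensor paths agree exactly
  a <- stepState(st, 0.1, p, modelVariant("isotropic"))
  b <- stepState(st, uniformIsotropicTensor(ph$grid, 0.1), p,
                 modelVariant("tensor"))
  expect_identical(densityValues(a), densityValues(b))
})

test_that("tensor-guided growth elongates along the fiber axis", {
  fb <- fiberPhantom(shape = c(33, 33, 33), meanDiffusivity = 0.0825,
                     faTarget = 0.8, fiberAxis = 2L)
  p <- caseParams()
  st <- makeState(fb$grid, c(17, 17, 17), params = p)
  run <- simulateGrowth(st, fb$tensor, p, modelVariant(), nDays = 20,
                        snapshotEvery = 20)
  supp <- densityValues(run$snapshots[[length(run$snapshots)]]) >
    0.02 * p@cM
  ix <- which(supp, arr.ind = TRUE)
  ext <- apply(ix, 2, function(z) diff(range(z)) + 1)
  expect_gt(ext[2], max(ext[c(1, 3)]))
})
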