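test_that("radial velocity is the least-squares slope of radius vs time", {
  rr <- RadiiSeries(c(0, 30), rT1 = c(9.1953, 19.0953),
                    rT2 = c(10.0, 19.9))
  expect_equal(radialVelocity(rr, "t2"), 0.33, tolerance = 1e-12)
  expect_equal(radialVelocity(rr, "t1"), 0.33, tolerance = 1e-12)

  flat <- RadiiSeries(c(0, 10, 20), rT1 = rep(9, 3), rT2 = rep(10, 3))
  expect_equal(radialVelocity(flat), 0)

  three <- RadiiSeries(c(0, 15, 30), rT1 = c(9, 9 + 15 * 0.2, 9 + 30 * 0.2),
                       rT2 = c(10, 10 + 15 * 0.2, 10 + 30 * 0.2))
  two <- RadiiSeries(c(0, 30), rT1 = c(9, 9 + 30 * 0.2),
                     rT2 = c(10, 10 + 30 * 0.2))
  expect_equal(radialVelocity(three), radialVelocity(two))
})

test_that("fisherEstimate recovers the case-study parameters", {
  rr <- RadiiSeries(c(0, 30), rT1 = c(9.1953, 19.0953),
                    rT2 = c(10.0, 19.9))
  est <- fisherEstimate(rr)
  # constructed so that delta-r = sqrt(D/rho) * ln 5 with (0.33, 0.0825)
  expect_equal(est@rho, 0.33, tolerance = 1e-3)
  expect_equal(est@dMean, 0.0825, tolerance = 1e-3)
  expect_equal(est@v, 2 * sqrt(est@rho * est@dMean), tolerance = 1e-12)
})

test_that("fisher estimation round-trips any (rho, D) through radii", {
  set.seed(42)
  for (i in 1:25) {
    rho <- runif(1, 0.01, 0.5)
    d <- runif(1, 0.01, 0.5)
    times <- sort(c(0, runif(3, 5, 120)))
    est <- fisherEstimate(syntheticRadii(rho, d, times, r0T2 = 12))
    expect_equal(est@rho, rho, tolerance = 1e-6)
    expect_equal(est@dMean, d, tolerance = 1e-6)
  }
  # the printed case values round-trip too
  est <- fisherEstimate(syntheticRadii(0.33, 0.0825, c(0, 30)))
  expect_equal(est@rho, 0.33, tolerance = 1e-6)
  expect_equal(est@dMean, 0.0825, tolerance = 1e-6)
})

test_that("doubling the contour gap at fixed v halves rho and doubles D", {
  base <- syntheticRadii(0.2, 0.1, c(0, 40))
  wide <- RadiiSeries(base@times, rT2 = base@rT2,
                      rT1 = base@rT2 - 2 * (base@rT2 - base@rT1))
  a <- fisherEstimate(base)
  b <- fisherEstimate(wide)
  expect_equal(b@rho, a@rho / 2, tolerance = 1e-12)
  expect_equal(b@dMean, a@dMean * 2, tolerance = 1e-12)
})

test_that("degenerate radii are rejected", {
  eq <- RadiiSeries(c(0, 30), rT1 = c(10, 20), rT2 = c(10, 20))
  expect_error(fisherEstimate(eq), "gap")
  shrink <- RadiiSeries(c(0, 30), rT1 = c(19, 9), rT2 = c(20, 10))
  expect_error(fisherEstimate(shrink), "velocity")
})

test_that("cell tensors inherit shape from spin tensors and match the target MD", {
  # isotropic input stays isotropic at the target mean diffusivity
  ph <- isotropicPhantom(shape = c(7, 7, 7), meanDiffusivity = 7e-4,
                         kind = "spin")
  ct <- cellTensorFromSpin(ph$tensor, 0.0825, amplification = 3)
  expect_equal(max(fractionalAnisotropy(ct)[brainMask(ph$grid)]), 0,
               tolerance = 1e-10)
  md <- meanDiffusivity(ct, perVoxel = TRUE)
  expect_equal(range(md[brainMask(ph$grid)]), c(0.0825, 0.0825),
               tolerance = 1e-12)

  # amplification 1 is a pure rescale
  fb <- fiberPhantom(shape = c(9, 9, 9), meanDiffusivity = 7e-4,
                     faTarget = 0.6, kind = "spin")
  ct1 <- cellTensorFromSpin(fb$tensor, 0.0825, amplification = 1)
  scale <- 0.0825 / meanDiffusivity(fb$tensor)
  expect_equal(tensorArray(ct1), scale * tensorArray(fb$tensor),
               tolerance = 1e-9)
  expect_equal(meanDiffusivity(ct1), 0.0825, tolerance = 1e-12)

  # hand-checkable eigendecomposition: diag(3,1,1)e-3, exponent 2 -> 9:1:1
  g1 <- VoxelGrid(c(1, 1, 1))
  a <- array(0, c(1, 1, 1, 6))
  a[1, 1, 1, c(1, 3, 6)] <- c(3e-3, 1e-3, 1e-3)
  ct2 <- cellTensorFromSpin(TensorField(g1, a, kind = "spin"), 0.0825,
                            amplification = 2)
  ev <- tensorEigenvalues(ct2)[1, ]
  expect_equal(ev / ev[3], c(9, 1, 1), tolerance = 1e-9)
  expect_equal(sum(ev) / 3, 0.0825, tolerance = 1e-12)

  expect_error(cellTensorFromSpin(fb$tensor, -1), "dMeanTarget")
  expect_error(cellTensorFromSpin(fb$tensor, 0.0825, amplification = 0.5),
               "amplification")
})

test_that("fractional anisotropy is non-decreasing in the amplification", {
  fb <- fiberPhantom(shape = c(9, 9, 9), meanDiffusivity = 7e-4,
                     faTarget = 0.5, kind = "spin")
  vox <- which(fb$bundle)[1]
  fa <- vapply(c(1, 1.5, 2, 3, 4), function(amp)
    fractionalAnisotropy(cellTensorFromSpin(fb$tensor, 0.0825, amp))[vox],
    numeric(1))
  expect_true(all(diff(fa) > 0))
  expect_equal(fa[1], 0.5, tolerance = 1e-9)
})

test_that("tau calibration follows the necrosis-timing schedule", {
  expect_equal(calibrateTau(TRUE), 0.85)
  expect_equal(calibrateTau(TRUE, margin = 0), 0.80)
  late <- vapply(c(0, 10, 40, 90, 200), function(d)
    calibrateTau(FALSE, delayDays = d), numeric(1))
  expect_equal(late[1], 0.85)
  expect_true(all(diff(late) >= 0))
  expect_lt(max(late), 1)
})

test_that("eta calibration is deterministic and reports unreachable targets", {
  shape <- c(33, 33, 33)
  # a target measured from the model itself is certainly achievable
  ref <- calibrateEta(0.8, shape = shape, horizonDays = 35, tol = 0.05)
  expect_true(ref$eta > 0.01 && ref$eta < 0.999)
  # re-simulation at the returned eta reproduces the achieved width exactly
  ph <- isotropicPhantom(shape = shape, meanDiffusivity = 0.0825)
  p <- caseParams(eta = ref$eta)
  st <- makeState(ph$grid, c(17, 17, 17), params = p)
  run <- simulateGrowth(st, ph$tensor, p, modelVariant(), nDays = 35,
                        snapshotEvery = 35)
  expect_identical(rimWidth(run$snapshots[[length(run$snapshots)]], p@cM),
                   ref$achievedRimWidthMm)

  expect_error(calibrateEta(50, shape = shape, horizonDays = 20),
               "achievable range")
})
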