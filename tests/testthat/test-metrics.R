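test_that("mutual information matches closed forms on 2x2 joint tables", {
  # perfectly dependent binary fields: MI = 1 bit
  a <- array(rep(c(0, 1), 32), dim = c(4, 4, 4))
  expect_equal(mutualInformation(a, a, bins = 2), 1)
  expect_equal(mutualInformation(a, 1 - a, bins = 2), 1)
  # independent: a constant partner carries no information
  expect_equal(mutualInformation(a, array(0.7, c(4, 4, 4)), bins = 2), 0)
  # checkerboard-independent: all four joint cells equally occupied
  b <- array(rep(c(0, 0, 1, 1), 16), dim = c(4, 4, 4))
  ab <- table(a, b)
  expect_true(all(ab == 16))  # confirms independence of the construction
  expect_equal(mutualInformation(a, b, bins = 2), 0)
  # unequal margins: direct evaluation of the double sum
  c1 <- array(c(rep(0, 48), rep(1, 16)), dim = c(4, 4, 4))
  p <- c(0.75, 0.25)
  expect_equal(mutualInformation(c1, c1, bins = 2), -sum(p * log2(p)))
})

test_that("MI is symmetric and equals the marginal entropy for s = c", {
  set.seed(7)
  for (i in 1:5) {
    x <- array(runif(6^3), dim = c(6, 6, 6))
    y <- array(rnorm(6^3), dim = c(6, 6, 6))
    expect_equal(mutualInformation(x, y, bins = 8),
                 mutualInformation(y, x, bins = 8))
    jh <- jointHistogram(x, x, bins = 8)
    pc <- rowSums(jh@counts) / sum(jh@counts)
    expect_equal(mutualInformation(x, x, bins = 8),
                 -sum(pc[pc > 0] * log2(pc[pc > 0])))
  }
})

test_that("independent noise never increases MI", {
  set.seed(11)
  x <- array(runif(8^3), dim = c(8, 8, 8))
  s <- sqrt(x) + array(rnorm(8^3, sd = 0.05), dim = c(8, 8, 8))
  base <- mutualInformation(x, s, bins = 16)
  for (sd in c(0.1, 0.3, 1)) {
    noisy <- s + array(rnorm(8^3, sd = sd), dim = c(8, 8, 8))
    expect_lt(mutualInformation(x, noisy, bins = 16), base + 0.05)
  }
})

test_that("joint histograms count every in-mask voxel and shape errors reject", {
  set.seed(3)
  x <- array(runif(5^3), dim = c(5, 5, 5))
  y <- array(runif(5^3), dim = c(5, 5, 5))
  mask <- array(runif(5^3) > 0.3, dim = c(5, 5, 5))
  jh <- jointHistogram(x, y, mask = mask, bins = 6)
  expect_equal(sum(jh@counts), sum(mask))
  expect_equal(dim(jh@counts), c(6L, 6L))
  expect_error(jointHistogram(x, array(0, c(4, 4, 4))), "different shapes")
  expect_error(jointHistogram(x, y, mask = array(TRUE, c(4, 4, 4))),
               "mask")
})

test_that("detection masks realize the imaging thresholds", {
  g <- cubeGrid(5)
  cM <- 1e5
  st <- syntheticState(g, array(0.5 * cM, c(5, 5, 5)))
  expect_true(all(detectionMask(st, 0.16, cM)))
  expect_false(any(detectionMask(st, 0.80, cM)))
  # enhancing excludes necrotic voxels; necrotic returns the core
  nec <- array(FALSE, c(5, 5, 5)); nec[3, 3, 3] <- TRUE
  st2 <- syntheticState(g, array(0.9 * cM, c(5, 5, 5)), nec)
  expect_equal(sum(detectionMask(st2, 0.80, cM, "enhancing")), 124L)
  expect_identical(detectionMask(st2, 0.80, cM, "necrotic"), nec)
})

test_that("equivalent radius follows the closed-form volume relations", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  expect_equal(equivalentRadius(m, c(1, 1, 1)), (3 / (4 * pi))^(1 / 3))
  expect_equal(equivalentRadius(array(FALSE, c(5, 5, 5))), 0)
  m2 <- m; m2[4, 3, 3] <- TRUE
  expect_equal(equivalentRadius(m2, c(1, 1, 1)),
               2^(1 / 3) * equivalentRadius(m, c(1, 1, 1)))
  # anisotropic spacing scales the volume
  expect_equal(equivalentRadius(m, c(2, 1, 1)),
               (3 * 2 / (4 * pi))^(1 / 3))
  # singleton axis: disc-equivalent radius
  flat <- array(TRUE, c(1, 2, 2))
  expect_equal(equivalentRadius(flat, c(5, 1, 1)), sqrt(4 / pi))
})

test_that("rim width recovers the gap between concentric digital spheres", {
  g <- cubeGrid(27)
  cM <- 1e5
  outer <- digitalBall(g, 10)
  inner <- digitalBall(g, 7.5)
  vals <- array(0, c(27, 27, 27))
  vals[outer] <- 0.9 * cM     # enhancing shell + core above threshold
  st <- syntheticState(g, vals, necrotic = inner)
  expect_equal(rimWidth(st, cM), 2.5, tolerance = 0.1)
  # without a necrotic core the rim is the full enhancing radius
  st2 <- syntheticState(g, vals)
  expect_equal(rimWidth(st2, cM), 10, tolerance = 0.15)
})

test_that("a mature isotropic lesion has a decayed core inside a dense shell", {
  # Strict genus checks (one hollow shell component) do not survive the
  # speckled threshold crossings of the 1 mm discretization, so the
  # core/shell morphology is asserted on the radial profile instead.
  ph <- isotropicPhantom(shape = c(43, 43, 43), meanDiffusivity = 0.0825)
  p <- caseParams()
  st <- makeState(ph$grid, c(22, 22, 22), params = p)
  run <- simulateGrowth(st, ph$tensor, p, modelVariant(), nDays = 60,
                        snapshotEvery = 60)
  fin <- run$snapshots[[length(run$snapshots)]]
  v <- densityValues(fin)
  nec <- necroticMask(fin)
  co <- lapply(1:3, function(a) seq_len(43) - 22)
  r <- sqrt(outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`))
  expect_gt(sum(nec), 1000)
  # center has necrosed and decayed below the T2 detection threshold
  expect_lt(max(v[r < 3]), 0.16 * p@cM)
  expect_true(all(nec[r < 3]))
  # a dense (enhancing-level) shell surrounds the core
  expect_gt(max(v[r >= 8 & r <= 12]), 0.80 * p@cM)
  # density falls back below detection outside the lesion
  expect_lt(max(v[r > 17]), 0.16 * p@cM)
  # the necrotic set is confined inside the lesion's outer shell
  outer_r <- equivalentRadius(detectionMask(fin, 0.80, p@cM, "enhancing") |
                                nec, gridSpacing(ph$grid))
  expect_lt(max(r[nec]), outer_r + 1.5)
})

test_that("front speed is a slope over the trailing snapshots", {
  g <- cubeGrid(9)
  cM <- 1e5
  static <- lapply(0:4, function(t)
    syntheticState(g, gaussianBump(g, amplitude = 0.5 * cM, width = 2),
                   t = t))
  expect_equal(frontSpeed(static, 0.16, cM), 0)
  expect_error(frontSpeed(static[1:2], 0.16, cM), "three snapshots")
  same_t <- lapply(1:4, function(i) static[[1]])
  expect_error(frontSpeed(same_t, 0.16, cM), "degenerate")
})

test_that("front speed scales as sqrt(rho * D)", {
  run_speed <- function(rho, d) {
    ph <- isotropicPhantom(shape = c(41, 41, 41), meanDiffusivity = d)
    p <- caseParams(rho = rho)
    st <- makeState(ph$grid, c(21, 21, 21), params = p)
    run <- simulateGrowth(st, ph$tensor, p,
                          modelVariant("tensor", necrosis = FALSE),
                          nDays = 50, snapshotEvery = 2)
    frontSpeed(run$snapshots, 0.16, p@cM)
  }
  v1 <- run_speed(0.33, 0.0825)
  v2 <- run_speed(0.165, 0.04125)   # halve both -> speed halves
  expect_equal(v2 / v1, 0.5, tolerance = 0.15)
})
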