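# Shared fixtures: everything is built in code at test time.

# canonical case-study parameters (glioblastoma, serial-imaging derived)
caseParams <- function(rho = 0.33, cM = 1e5, tau = 0.85, eta = 0.9, ...) {
  GrowthParams(rho = rho, cM = cM, tau = tau, eta = eta, ...)
}

# small all-TRUE cubic grid
cubeGrid <- function(n = 9, h = 1) {
  VoxelGrid(rep(n, 3L), rep(h, 3L))
}

# a SimulationState with prescribed density/necrosis, bypassing makeState
syntheticState <- function(grid, values, necrotic = NULL, t = 0) {
  if (is.null(necrotic)) necrotic <- array(FALSE, dim = gridShape(grid))
  new("SimulationState", t = t, c = DensityField(grid, values),
      m = values, necrotic = necrotic)
}

# discrete Gaussian bump centered on the grid
gaussianBump <- function(grid, amplitude = 1, width = 3) {
  sh <- gridShape(grid)
  co <- lapply(1:3, function(a) seq_len(sh[a]) - (sh[a] + 1) / 2)
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  vals <- amplitude * exp(-r2 / (2 * width^2))
  vals[!brainMask(grid)] <- 0
  vals
}

# independent 7-point scalar Laplacian oracle with edge replication
scalarLaplacian <- function(vals, d, h = 1) {
  sh <- dim(vals)
  shift1 <- function(a, ax, by) {
    idx <- pmin(pmax(seq_len(sh[ax]) + by, 1L), sh[ax])
    if (ax == 1) a[idx, , ] else if (ax == 2) a[, idx, ] else a[, , idx]
  }
  lap <- array(0, dim = sh)
  for (ax in 1:3)
    lap <- lap + shift1(vals, ax, 1L) + shift1(vals, ax, -1L) - 2 * vals
  d * lap / h^2
}

# digital ball mask of given radius (mm) centered on the grid
digitalBall <- function(grid, radius) {
  sh <- gridShape(grid)
  sp <- gridSpacing(grid)
  co <- lapply(1:3, function(a) (seq_len(sh[a]) - (sh[a] + 1) / 2) * sp[a])
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  r2 <= radius^2
}

# 6-connected components of a logical 3-D mask (BFS flood fill)
connectedComponents <- function(mask) {
  sh <- dim(mask)
  lab <- array(0L, dim = sh)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ix <- arrayInd(v, sh)
      for (k in 1:6) {
        jx <- ix + nb[k, ]
        if (any(jx < 1L) || any(jx > sh)) next
        j <- jx[1] + sh[1] * (jx[2] - 1L + sh[2] * (jx[3] - 1L))
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}
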