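# Image-derived parameter estimation: radial velocity and (rho, D) from
# serial T1/T2 radii via the Fisher traveling-wave relation, cell tensors
# from spin tensors, and calibration of the necrosis parameters.

.LN5 <- log(0.80 / 0.16)  # density ratio between the T1 and T2 contours

#' Tumor radial growth velocity
#'
#' Least-squares slope of radius versus time for the chosen imaging
#' channel. Under a rigid traveling wave the T1 and T2 slopes coincide;
#' the T2 (outer, infiltrative) margin is the default.
#'
#' @param radii a \linkS4class{RadiiSeries}.
#' @param channel \code{"t2"} or \code{"t1"}.
#' @return Velocity in mm/day.
#' @examples
#' radialVelocity(RadiiSeries(c(0, 30), c(9.2, 19.1), c(10, 19.9)))
#' @export
radialVelocity <- function(radii, channel = c("t2", "t1")) {
  stopifnot(is(radii, "RadiiSeries"))
  channel <- match.arg(channel)
  t <- radii@times
  r <- if (channel == "t2") radii@rT2 else radii@rT1
  if (diff(range(t)) <= 0) stop("zero time span: cannot fit a velocity")
  stats::cov(t, r) / stats::var(t)
}

#' Estimate proliferation rate and diffusivity from serial radii
#'
#' Inverts the Fisher-KPP traveling-wave description of the tumor margin.
#' The radial velocity v comes from the slope of the T2 radius; the mean
#' gap between the T2 (0.16 c_m) and T1 (0.80 c_m) contours samples the
#' exponential wave tail c ~ exp(-x sqrt(rho/D)), giving
#' sqrt(D/rho) = dr / ln 5. Combining with Fisher's relation
#' v = 2 sqrt(rho D) yields rho = v ln5 / (2 dr) and D = v dr / (2 ln5).
#'
#' @param radii a \linkS4class{RadiiSeries}.
#' @param channel imaging channel for the velocity fit (default T2).
#' @return An \linkS4class{EstimatedParams} with v, rho and dMean set
#'   (tau, eta are NA until calibrated).
#' @examples
#' rr <- syntheticRadii(rho = 0.33, d = 0.0825, times = c(0, 30))
#' fisherEstimate(rr)
#' @export
fisherEstimate <- function(radii, channel = c("t2", "t1")) {
  stopifnot(is(radii, "RadiiSeries"))
  dr <- mean(radii@rT2 - radii@rT1)
  if (dr <= 0)
    stop("mean T2-T1 radius gap must be positive (contours inverted?)")
  v <- radialVelocity(radii, channel)
  if (v <= 0) stop("non-positive radial velocity: no growth to fit")
  rho <- v * .LN5 / (2 * dr)
  d <- v * dr / (2 * .LN5)
  new("EstimatedParams", v = v, rho = rho, dMean = d,
      tau = NA_real_, eta = NA_real_)
}

#' Forward-generate radii from model parameters
#'
#' The inverse of \code{\link{fisherEstimate}}: radii of a rigid Fisher
#' traveling wave with speed v = 2 sqrt(rho d) and T2-T1 contour gap
#' sqrt(d/rho) * ln 5.
#'
#' @param rho proliferation rate, /day.
#' @param d cell diffusivity, mm^2/day.
#' @param times acquisition times, days.
#' @param r0T2 T2 radius at the first time point, mm.
#' @return A \linkS4class{RadiiSeries}.
#' @export
syntheticRadii <- function(rho, d, times, r0T2 = 10) {
  v <- 2 * sqrt(rho * d)
  dr <- sqrt(d / rho) * .LN5
  rT2 <- r0T2 + v * (times - times[1])
  RadiiSeries(times, rT1 = rT2 - dr, rT2 = rT2)
}

#' Derive the cell diffusion tensor from a spin diffusion tensor
#'
#' Differential eigenvalue scaling: each in-mask spin tensor is
#' eigendecomposed, its eigenvalues are raised to the power
#' \code{amplification} (sharpening anisotropy; 1 preserves tensor shape),
#' the tensor is reassembled with unchanged eigenvectors, and the whole
#' field is rescaled so that the in-mask mean diffusivity (trace/3) equals
#' the target estimated from serial imaging. Output tensors are symmetric
#' and positive semi-definite by construction.
#'
#' @param spin a \linkS4class{TensorField} (any kind; typically
#'   \code{"spin"}).
#' @param dMeanTarget target in-mask mean diffusivity, mm^2/day.
#' @param amplification eigenvalue exponent, >= 1 (default 2).
#' @return A \linkS4class{TensorField} of kind \code{"cell"}.
#' @export
cellTensorFromSpin <- function(spin, dMeanTarget, amplification = 2) {
  stopifnot(is(spin, "TensorField"))
  if (!(is.finite(dMeanTarget) && dMeanTarget > 0))
    stop("dMeanTarget must be positive")
  if (!(is.finite(amplification) && amplification >= 1))
    stop("amplification must be >= 1")
  mask <- spin@grid@mask
  powered <- .power_tensor_eigenvalues(as.numeric(spin@tensors),
                                       as.logical(mask), amplification)
  dim(powered) <- c(spin@grid@shape, 6L)
  md <- (powered[, , , 1] + powered[, , , 3] + powered[, , , 6]) / 3
  mdbar <- mean(md[mask])
  if (mdbar <= 0)
    stop("spin tensor field has zero in-mask mean diffusivity")
  TensorField(spin@grid, powered * (dMeanTarget / mdbar), kind = "cell")
}

#' Calibrate the necrosis threshold tau
#'
#' The threshold is tied to when necrosis first becomes visible on
#' contrast-enhanced T1 imaging: a tumor already necrotic at the first
#' study gets tau just above the T1 detection fraction
#' (detection + margin, 0.85 by default); later necrosis maps linearly to
#' larger thresholds up to \code{tauMax}.
#'
#' @param necrosisSeenAtT0 logical; was necrosis present on the first
#'   study?
#' @param detectionFraction T1 detection fraction of c_m (default 0.80).
#' @param margin offset above the detection fraction (default 0.05).
#' @param delayDays days from first imaging to first observed necrosis
#'   (ignored when \code{necrosisSeenAtT0}).
#' @param delayScale delay at which tau reaches \code{tauMax}, days.
#' @param tauMax upper end of the schedule, < 1.
#' @return tau as a fraction of c_m.
#' @examples
#' calibrateTau(TRUE)  # 0.85
#' @export
calibrateTau <- function(necrosisSeenAtT0, detectionFraction = 0.80,
                         margin = 0.05, delayDays = 0, delayScale = 90,
                         tauMax = 0.99) {
  stopifnot(detectionFraction > 0, detectionFraction < 1, margin >= 0)
  base <- detectionFraction + margin
  if (isTRUE(necrosisSeenAtT0) || delayDays <= 0) return(base)
  stopifnot(tauMax > base, delayScale > 0)
  base + (tauMax - base) * min(delayDays / delayScale, 1)
}

#' Calibrate the necrosis survival fraction eta from the rim width
#'
#' Deterministic golden-section search over eta in (0.01, 0.999)
#' minimizing the absolute difference between the simulated enhancing rim
#' width on an isotropic phantom and the observed target width. On
#' phantoms the rim width is empirically monotone non-decreasing in eta
#' (faster necrosis erodes the rim from inside), so the search is
#' well-posed; if the target lies outside the achievable range at the
#' interval ends, the achievable range is reported in the error.
#'
#' @param targetRimWidthMm observed enhancing rim width, mm.
#' @param rho,d,tau,cM fixed model parameters.
#' @param shape,spacing isotropic phantom geometry (scale down for quick
#'   exploratory runs).
#' @param horizonDays simulated horizon, days.
#' @param tol search tolerance on eta.
#' @param cfl substep safety fraction passed to the solver.
#' @return A list with \code{eta}, \code{achievedRimWidthMm} and
#'   \code{evaluations} (data.frame of every (eta, rim width) probed).
#' @export
calibrateEta <- function(targetRimWidthMm, rho = 0.33, d = 0.0825,
                         tau = 0.85, cM = 1e5, shape = c(64, 64, 64),
                         spacing = c(1, 1, 1), horizonDays = 30L,
                         tol = 1e-3, cfl = 0.25) {
  stopifnot(targetRimWidthMm > 0)
  ph <- isotropicPhantom(shape = shape, spacing = spacing,
                         meanDiffusivity = d)
  center <- as.integer((gridShape(ph$grid) + 1) %/% 2)
  variant <- modelVariant("tensor", necrosis = TRUE)
  evals <- data.frame(eta = numeric(0), rimWidthMm = numeric(0))
  rim_of <- function(eta) {
    hit <- which(abs(evals$eta - eta) < .Machine$double.eps)
    if (length(hit)) return(evals$rimWidthMm[hit[1]])
    params <- GrowthParams(rho = rho, cM = cM, tau = tau, eta = eta)
    st <- makeState(ph$grid, center, params = params)
    run <- simulateGrowth(st, ph$tensor, params, variant,
                          nDays = horizonDays,
                          snapshotEvery = max(1L, horizonDays), cfl = cfl)
    w <- rimWidth(run$snapshots[[length(run$snapshots)]], cM)
    evals[nrow(evals) + 1L, ] <<- c(eta, w)
    w
  }
  lo <- 0.01
  hi <- 0.999
  w_lo <- rim_of(lo)
  w_hi <- rim_of(hi)
  rng <- range(w_lo, w_hi)
  if (targetRimWidthMm < rng[1] - 0.5 || targetRimWidthMm > rng[2] + 0.5)
    stop(sprintf(
      "target rim width %.3g mm is outside the achievable range [%.3g, %.3g] mm for eta in (0.01, 0.999)",
      targetRimWidthMm, rng[1], rng[2]))
  objective <- function(eta) abs(rim_of(eta) - targetRimWidthMm)
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- objective(x1)
  f2 <- objective(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a)
      f1 <- objective(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a)
      f2 <- objective(x2)
    }
  }
  eta <- (a + b) / 2
  list(eta = eta, achievedRimWidthMm = rim_of(eta), evaluations = evals)
}
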