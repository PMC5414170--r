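#' @import methods
NULL

.TOL_SYM <- 1e-8
.TOL_PSD <- 1e-8

#' Voxel grid geometry
#'
#' Spatial domain shared by all fields: grid shape (voxels per axis), voxel
#' spacing in mm, and a boolean brain mask marking the tissue inside which
#' tumor cells may live and migrate. Axis order is (x, y, z), matching the
#' first three dimensions of the stored arrays; voxel indices are 1-based.
#'
#' @slot shape integer triple, voxels per axis.
#' @slot spacing numeric triple, mm per voxel along each axis.
#' @slot mask logical array of dimension \code{shape}; \code{TRUE} inside
#'   the brain.
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", mask = "array"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive reals (mm)")
  if (!is.logical(object@mask) || !identical(dim(object@mask),
                                             as.integer(object@shape)))
    msg <- c(msg, "mask must be a logical array of dimension `shape`")
  else if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one TRUE voxel")
  if (length(msg)) msg else TRUE
})

#' Construct a voxel grid
#'
#' @param shape integer triple of voxels per axis.
#' @param spacing numeric triple, mm per voxel (default 1 mm isotropic).
#' @param mask logical array of dimension \code{shape}; default all
#'   \code{TRUE}.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(c(8, 8, 8))
#' gridShape(g)
#' @export
VoxelGrid <- function(shape, spacing = c(1, 1, 1), mask = NULL) {
  shape <- as.integer(shape)
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  new("VoxelGrid", shape = shape, spacing = as.numeric(spacing), mask = mask)
}

#' Per-voxel symmetric diffusion tensor field
#'
#' Stores one symmetric 3x3 tensor per voxel in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) as a 4-D array, the common FSL-style
#' convention. \code{kind} distinguishes the measured water (spin) tensor
#' from the modeled tumor cell tensor (mm^2/day). Symmetry is guaranteed by
#' the 6-component storage; validity additionally requires every in-mask
#' tensor to be positive semi-definite to tolerance.
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot tensors numeric array, dim \code{c(shape, 6)}.
#' @slot kind \code{"spin"} or \code{"cell"}.
#' @export
setClass("TensorField",
  representation(grid = "VoxelGrid", tensors = "array", kind = "character"))

setValidity("TensorField", function(object) {
  msg <- character()
  sh <- object@grid@shape
  if (!identical(dim(object@tensors), c(sh, 6L)))
    msg <- c(msg, "tensors must have dimension c(shape, 6)")
  if (!object@kind %in% c("spin", "cell"))
    msg <- c(msg, "kind must be 'spin' or 'cell'")
  if (!length(msg)) {
    nvox <- prod(sh)
    ev <- .tensor_eigenvalues(as.numeric(object@tensors), nvox)
    inm <- as.logical(object@grid@mask)
    lmin <- ev[inm, 3]
    scale <- max(abs(ev[inm, 1]), 1e-30)
    if (any(lmin < -.TOL_PSD * scale))
      msg <- c(msg, sprintf(
        "in-mask tensor at linear voxel %d is not positive semi-definite",
        which(inm)[which.min(ev[inm, 3])]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a tensor field
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param tensors 4-D array \code{c(shape, 6)} in lower-triangular order
#'   (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#' @param kind \code{"cell"} (mm^2/day) or \code{"spin"}.
#' @return A \linkS4class{TensorField}.
#' @export
TensorField <- function(grid, tensors, kind = c("cell", "spin")) {
  kind <- match.arg(kind)
  new("TensorField", grid = grid, tensors = tensors, kind = kind)
}

#' Tumor cell density field
#'
#' Per-voxel tumor cell concentration c(x) in cells/mm^3. Values are finite,
#' non-negative, and zero outside the brain mask; the solver's clipping
#' contract keeps them at or below the carrying capacity.
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot values numeric array of dimension \code{shape}, cells/mm^3.
#' @export
setClass("DensityField",
  representation(grid = "VoxelGrid", values = "array"))

setValidity("DensityField", function(object) {
  msg <- character()
  if (!identical(dim(object@values), object@grid@shape))
    msg <- c(msg, "values must have the grid's dimension")
  else {
    if (any(!is.finite(object@values)))
      msg <- c(msg, "density values must be finite")
    else {
      if (any(object@values < 0))
        msg <- c(msg, "density values must be non-negative")
      if (any(object@values[!object@grid@mask] != 0))
        msg <- c(msg, "density must be zero outside the mask")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a density field
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param values numeric array of dimension \code{shape} (default all zero).
#' @return A \linkS4class{DensityField}.
#' @export
DensityField <- function(grid, values = NULL) {
  if (is.null(values)) values <- array(0, dim = grid@shape)
  new("DensityField", grid = grid, values = values)
}

#' Growth, necrosis and time-step parameters
#'
#' Scalar parameters of the proliferation-necrosis model: proliferation rate
#' rho (/day), carrying capacity c_m (cells/mm^3), necrosis threshold tau
#' stored as a fraction of c_m, per-day survival fraction eta of necrotic
#' tissue, reporting time step dt (days), and the proliferation law.
#'
#' @slot rho numeric, /day.
#' @slot cM numeric, cells/mm^3.
#' @slot tau numeric in (0, 1], fraction of \code{cM}.
#' @slot eta numeric in (0, 1), per-day survival fraction of necrotic voxels.
#' @slot dt numeric, days.
#' @slot growthLaw \code{"logistic"}, \code{"exponential"} or
#'   \code{"gompertz"}.
#' @export
setClass("GrowthParams",
  representation(rho = "numeric", cM = "numeric", tau = "numeric",
                 eta = "numeric", dt = "numeric", growthLaw = "character"))

setValidity("GrowthParams", function(object) {
  msg <- character()
  if (!(is.finite(object@rho) && object@rho >= 0))
    msg <- c(msg, "rho must be non-negative (0 disables proliferation)")
  if (!(is.finite(object@cM) && object@cM > 0))
    msg <- c(msg, "cM must be positive")
  if (!(is.finite(object@tau) && object@tau > 0 && object@tau <= 1))
    msg <- c(msg, "tau must lie in (0, 1] (fraction of cM)")
  if (!(is.finite(object@eta) && object@eta > 0 && object@eta < 1))
    msg <- c(msg, "eta must lie in (0, 1)")
  if (!(is.finite(object@dt) && object@dt > 0))
    msg <- c(msg, "dt must be positive")
  if (!object@growthLaw %in% c("logistic", "exponential", "gompertz"))
    msg <- c(msg, "growthLaw must be logistic, exponential or gompertz")
  if (length(msg)) msg else TRUE
})

#' Construct growth parameters
#'
#' Defaults follow the glioblastoma case study the model was built around:
#' rho = 0.33/day, c_m = 1e5 cells/mm^3, tau = 0.85, eta = 0.9/day,
#' dt = 1 day, logistic proliferation.
#'
#' @param rho proliferation rate, /day.
#' @param cM carrying capacity, cells/mm^3.
#' @param tau necrosis threshold as a fraction of \code{cM}.
#' @param eta per-day survival fraction applied to necrotic voxels.
#' @param dt reporting time step, days.
#' @param growthLaw proliferation law.
#' @return A \linkS4class{GrowthParams}.
#' @examples
#' GrowthParams(rho = 0.33, cM = 1e5, tau = 0.85, eta = 0.9)
#' @export
GrowthParams <- function(rho = 0.33, cM = 1e5, tau = 0.85, eta = 0.9,
                         dt = 1, growthLaw = c("logistic", "exponential",
                                               "gompertz")) {
  growthLaw <- match.arg(growthLaw)
  new("GrowthParams", rho = rho, cM = cM, tau = tau, eta = eta, dt = dt,
      growthLaw = growthLaw)
}

#' Simulation state
#'
#' The full state of a simulation at time t: the current density field c,
#' the running per-voxel maximum m(x) = max over elapsed time of c(x, t)
#' (the quantity the necrosis switch tests), and the necrotic mask. Once
#' m(x) reaches tau*c_m a voxel is permanently necrotic, even after decay
#' pulls its density back below the threshold.
#'
#' @slot t numeric, days since seeding.
#' @slot c a \linkS4class{DensityField}.
#' @slot m numeric array, historical maximum of c, cells/mm^3.
#' @slot necrotic logical array.
#' @export
setClass("SimulationState",
  representation(t = "numeric", c = "DensityField", m = "array",
                 necrotic = "array"))

setValidity("SimulationState", function(object) {
  msg <- character()
  sh <- object@c@grid@shape
  if (!identical(dim(object@m), sh))
    msg <- c(msg, "m must have the grid's dimension")
  if (!is.logical(object@necrotic) || !identical(dim(object@necrotic), sh))
    msg <- c(msg, "necrotic must be a logical array of the grid's dimension")
  if (!length(msg) && any(object@m < object@c@values - 1e-9 * max(object@m, 1)))
    msg <- c(msg, "m must dominate c pointwise (historical maximum)")
  if (length(msg)) msg else TRUE
})

#' Serial tumor radii
#'
#' Timestamped tumor radii measured on serial imaging: the contrast-enhanced
#' T1 radius (hypothesized 0.80*c_m density contour) and the T2 radius
#' (0.16*c_m contour). The T2 radius is never smaller than the T1 radius at
#' the same visit because the 16% contour lies outside the 80% contour.
#'
#' @slot times numeric, days; strictly increasing, at least two points.
#' @slot rT1 numeric, mm.
#' @slot rT2 numeric, mm.
#' @export
setClass("RadiiSeries",
  representation(times = "numeric", rT1 = "numeric", rT2 = "numeric"))

setValidity("RadiiSeries", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n < 2L)
    msg <- c(msg, "at least two time points are required")
  if (length(object@rT1) != n || length(object@rT2) != n)
    msg <- c(msg, "times, rT1 and rT2 must have equal length")
  if (!length(msg)) {
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(object@rT1 <= 0) || any(object@rT2 <= 0))
      msg <- c(msg, "all radii must be positive")
    if (any(object@rT2 < object@rT1))
      msg <- c(msg, "rT2 must be >= rT1 at every time point")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a radii series
#'
#' @param times acquisition times, days.
#' @param rT1 contrast-enhanced T1 radii, mm.
#' @param rT2 T2 radii, mm.
#' @return A \linkS4class{RadiiSeries}.
#' @examples
#' RadiiSeries(c(0, 30), rT1 = c(9.2, 19.1), rT2 = c(10, 19.9))
#' @export
RadiiSeries <- function(times, rT1, rT2) {
  new("RadiiSeries", times = as.numeric(times), rT1 = as.numeric(rT1),
      rT2 = as.numeric(rT2))
}

#' Image-derived model parameter estimates
#'
#' Output of the Fisher traveling-wave estimation: radial velocity v
#' (mm/day), proliferation rate rho (/day) and mean cell diffusivity
#' (mm^2/day), self-consistent with v = 2*sqrt(rho*D). The necrosis
#' parameters tau and eta are NA until calibrated.
#'
#' @slot v numeric, mm/day.
#' @slot rho numeric, /day.
#' @slot dMean numeric, mm^2/day.
#' @slot tau numeric fraction of c_m, or NA.
#' @slot eta numeric per-day survival fraction, or NA.
#' @export
setClass("EstimatedParams",
  representation(v = "numeric", rho = "numeric", dMean = "numeric",
                 tau = "numeric", eta = "numeric"))

setValidity("EstimatedParams", function(object) {
  msg <- character()
  if (object@rho <= 0 || object@dMean <= 0)
    msg <- c(msg, "rho and dMean must be positive")
  else if (abs(object@v - 2 * sqrt(object@rho * object@dMean)) >
           1e-8 * max(object@v, 1e-12))
    msg <- c(msg, "v must equal 2*sqrt(rho*dMean) (Fisher self-consistency)")
  if (length(msg)) msg else TRUE
})
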