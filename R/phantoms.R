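# Synthetic tensor fields and pseudo-images: stand-ins for volunteer DTI
# and post-contrast T1 acquisitions so the whole pipeline is testable
# without external data.

.voxel_coords <- function(shape, spacing) {
  # voxel-center coordinates in mm relative to the grid center
  lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a])
}

.ellipsoid_mask <- function(shape, spacing) {
  co <- .voxel_coords(shape, spacing)
  semi <- shape * spacing / 2
  x2 <- (co[[1]] / semi[1])^2
  y2 <- (co[[2]] / semi[2])^2
  z2 <- (co[[3]] / semi[3])^2
  outer(outer(x2, y2, `+`), z2, `+`) <= 1
}

#' Isotropic diffusion phantom
#'
#' An ellipsoidal "brain" mask inscribed in the grid, with every in-mask
#' tensor equal to meanDiffusivity * I. Fully deterministic.
#'
#' @param shape integer triple of voxels per axis (default 64^3).
#' @param spacing voxel spacing, mm (default 1 mm isotropic).
#' @param meanDiffusivity scalar diffusivity, mm^2/day.
#' @param kind tensor kind, default \code{"cell"}.
#' @return A list with elements \code{grid} (\linkS4class{VoxelGrid}) and
#'   \code{tensor} (\linkS4class{TensorField}).
#' @examples
#' ph <- isotropicPhantom(shape = c(16, 16, 16), meanDiffusivity = 0.0825)
#' meanDiffusivity(ph$tensor)
#' @export
isotropicPhantom <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                             meanDiffusivity = 0.0825, kind = "cell") {
  shape <- as.integer(shape)
  grid <- VoxelGrid(shape, spacing, .ellipsoid_mask(shape, spacing))
  list(grid = grid,
       tensor = uniformIsotropicTensor(grid, meanDiffusivity, kind = kind))
}

# exact axially symmetric eigenvalues for a given (MD, FA):
# lambda_perp = MD*(1 - x), lambda_par = MD*(1 + 2x), x = FA/sqrt(3 - 2 FA^2)
.axial_eigenvalues <- function(md, fa) {
  x <- fa / sqrt(3 - 2 * fa^2)
  c(par = md * (1 + 2 * x), perp = md * (1 - x))
}

#' Fiber-bundle diffusion phantom
#'
#' A straight cylindrical bundle of axially symmetric tensors (principal
#' eigenvector along \code{fiberAxis}, fractional anisotropy exactly
#' \code{faTarget}) embedded in an isotropic background; mean diffusivity
#' equals \code{meanDiffusivity} everywhere, so the bundle differs from the
#' background only in shape, not in total diffusivity. Emulates the
#' coherent white-matter tracts along which glioblastoma preferentially
#' migrates.
#'
#' @param shape,spacing,meanDiffusivity,kind as in
#'   \code{\link{isotropicPhantom}}.
#' @param faTarget fractional anisotropy inside the bundle, in [0, 1).
#' @param fiberAxis axis index (1, 2 or 3) of the straight fiber path.
#' @param bundleRadius cylinder radius, mm; default a quarter of the
#'   smallest transverse grid extent.
#' @return A list with elements \code{grid}, \code{tensor} and
#'   \code{bundle} (logical array marking the bundle voxels).
#' @export
fiberPhantom <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         meanDiffusivity = 0.0825, faTarget = 0.8,
                         fiberAxis = 1L, bundleRadius = NULL,
                         kind = "cell") {
  shape <- as.integer(shape)
  if (!is.finite(faTarget) || faTarget < 0 || faTarget >= 1)
    stop("faTarget must lie in [0, 1) for an axially symmetric tensor")
  fiberAxis <- as.integer(fiberAxis)
  stopifnot(fiberAxis %in% 1:3)
  trans <- setdiff(1:3, fiberAxis)
  if (is.null(bundleRadius))
    bundleRadius <- min(shape[trans] * spacing[trans]) / 4
  grid <- VoxelGrid(shape, spacing, .ellipsoid_mask(shape, spacing))

  co <- .voxel_coords(shape, spacing)
  # squared distance from the bundle axis, accumulated over transverse axes
  axis_field <- function(a) {
    rest <- setdiff(1:3, a)
    aperm(array(co[[a]], dim = shape[c(a, rest)]), order(c(a, rest)))
  }
  r2 <- axis_field(trans[1])^2 + axis_field(trans[2])^2
  bundle <- r2 <= bundleRadius^2 & grid@mask

  tensors <- array(0, dim = c(shape, 6L))
  tensors[, , , 1] <- meanDiffusivity
  tensors[, , , 3] <- meanDiffusivity
  tensors[, , , 6] <- meanDiffusivity
  if (faTarget > 0 && any(bundle)) {
    lam <- .axial_eigenvalues(meanDiffusivity, faTarget)
    e <- c(0, 0, 0)
    e[fiberAxis] <- 1
    m <- diag(rep(lam["perp"], 3)) + (lam["par"] - lam["perp"]) * tcrossprod(e)
    lower <- .sym3_to_lower(m)
    for (k in 1:6) {
      comp <- tensors[, , , k]
      comp[bundle] <- lower[k]
      tensors[, , , k] <- comp
    }
  }
  list(grid = grid, tensor = TensorField(grid, tensors, kind = kind),
       bundle = bundle)
}

#' Render a pseudo post-contrast T1 image of a simulation state
#'
#' A deterministic intensity cartoon of what contrast-enhanced T1 imaging
#' would show: bright enhancing tumor (c >= 0.80 c_m and not necrotic),
#' dark necrotic core, intermediate background tissue inside the mask, zero
#' outside, plus optional additive Gaussian noise generated from
#' \code{seed}. No MR physics is simulated; the map is sufficient for
#' mutual-information comparisons.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param cM carrying capacity, cells/mm^3.
#' @param enhancingFraction detection fraction for the bright rim
#'   (default 0.80).
#' @param noiseSd standard deviation of additive Gaussian noise (intensity
#'   units; the noiseless image spans [0, 1]).
#' @param seed integer seed for the noise; the global RNG state is left
#'   untouched.
#' @param background either the constant background intensity (default
#'   0.5) or an array of per-voxel background anatomy intensities (see
#'   \code{\link{anatomyImage}}); lesion intensities overwrite it.
#' @return Numeric array of intensities with the grid's dimension.
#' @export
pseudoT1 <- function(state, cM, enhancingFraction = 0.80, noiseSd = 0,
                     seed = 1L, background = 0.5) {
  stopifnot(is(state, "SimulationState"), noiseSd >= 0)
  mask <- state@c@grid@mask
  vals <- state@c@values
  img <- array(0, dim = dim(vals))
  if (is.array(background)) {
    stopifnot(identical(dim(background), dim(vals)))
    img[mask] <- background[mask]
  } else img[mask] <- background
  img[mask & state@necrotic] <- 0.15
  img[mask & !state@necrotic & vals >= enhancingFraction * cM] <- 1.0
  if (noiseSd > 0) {
    noise <- .with_seed(seed, stats::rnorm(sum(mask), sd = noiseSd))
    img[mask] <- img[mask] + noise
  }
  img
}

#' Deterministic anatomical background image of a phantom
#'
#' A smooth, many-valued intensity field standing in for the anatomy a
#' real T1-weighted image shows outside (and underneath) the lesion:
#' fractional-anisotropy contrast (fiber bundles are visible) plus gentle
#' large-scale intensity gradients. Deterministic given the tensor field,
#' so repeated renderings are identical.
#'
#' @param tensor a \linkS4class{TensorField}.
#' @param base,faContrast,gradientAmplitude intensity map parameters.
#' @return Numeric array of background intensities (zero outside the
#'   mask).
#' @export
anatomyImage <- function(tensor, base = 0.5, faContrast = 0.2,
                         gradientAmplitude = 0.1) {
  stopifnot(is(tensor, "TensorField"))
  grid <- tensor@grid
  sh <- grid@shape
  co <- .voxel_coords(sh, grid@spacing)
  axis_field <- function(a) {
    rest <- setdiff(1:3, a)
    aperm(array(co[[a]], dim = sh[c(a, rest)]), order(c(a, rest)))
  }
  waves <- (sin(2 * pi * axis_field(1) / 21) +
            sin(2 * pi * axis_field(2) / 17) +
            sin(2 * pi * axis_field(3) / 13)) / 3
  img <- base + faContrast * fractionalAnisotropy(tensor) +
    gradientAmplitude * waves
  img[!grid@mask] <- 0
  img
}

# evaluate `expr` under a temporary RNG seed, restoring the global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
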