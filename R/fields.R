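#' Seed an initial simulation state
#'
#' Places \code{c0} tumor cells/mm^3 in a single in-mask voxel and zero
#' elsewhere; the history maximum m starts equal to c and the necrotic set
#' follows the threshold rule m >= tau*c_m (so a seed at or above the
#' threshold is necrotic from the start).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param seedIndex integer triple, 1-based (x, y, z) voxel index.
#' @param c0 initial cell density at the seed, cells/mm^3; defaults to
#'   \code{0.1 * params@cM}, below every detection and necrosis threshold.
#' @param params a \linkS4class{GrowthParams}.
#' @return A \linkS4class{SimulationState} at t = 0.
#' @examples
#' g <- VoxelGrid(c(9, 9, 9))
#' st <- makeState(g, c(5, 5, 5), params = GrowthParams())
#' stateTime(st)
#' @export
makeState <- function(grid, seedIndex, c0 = NULL, params) {
  stopifnot(is(grid, "VoxelGrid"), is(params, "GrowthParams"))
  if (is.null(c0)) c0 <- 0.1 * params@cM
  seedIndex <- as.integer(seedIndex)
  if (length(seedIndex) != 3L || any(seedIndex < 1L) ||
      any(seedIndex > grid@shape))
    stop("seedIndex ", paste(seedIndex, collapse = ","),
         " lies outside the grid ", paste(grid@shape, collapse = "x"))
  if (!grid@mask[seedIndex[1], seedIndex[2], seedIndex[3]])
    stop("seedIndex ", paste(seedIndex, collapse = ","),
         " lies outside the brain mask")
  if (!(c0 > 0 && c0 <= params@cM))
    stop("c0 must lie in (0, cM]")
  vals <- array(0, dim = grid@shape)
  vals[seedIndex[1], seedIndex[2], seedIndex[3]] <- c0
  cf <- DensityField(grid, vals)
  necrotic <- vals >= params@tau * params@cM
  new("SimulationState", t = 0, c = cf, m = vals, necrotic = necrotic)
}

#' Mean diffusivity of a tensor field
#'
#' trace/3 averaged over the in-mask voxels (or per voxel).
#'
#' @param tensor a \linkS4class{TensorField}.
#' @param perVoxel if \code{TRUE}, return the per-voxel trace/3 array.
#' @return Scalar in-mask mean (default) or an array.
#' @export
meanDiffusivity <- function(tensor, perVoxel = FALSE) {
  stopifnot(is(tensor, "TensorField"))
  a <- tensor@tensors
  md <- (a[, , , 1] + a[, , , 3] + a[, , , 6]) / 3
  if (perVoxel) return(md)
  mean(md[tensor@grid@mask])
}

#' Fractional anisotropy of a tensor field
#'
#' Standard DTI fractional anisotropy from per-voxel eigenvalues:
#' FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||, zero for degenerate
#' (all-zero) tensors.
#'
#' @param tensor a \linkS4class{TensorField}.
#' @return Array of per-voxel FA values in [0, 1).
#' @export
fractionalAnisotropy <- function(tensor) {
  stopifnot(is(tensor, "TensorField"))
  sh <- tensor@grid@shape
  ev <- .tensor_eigenvalues(as.numeric(tensor@tensors), prod(sh))
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  array(fa, dim = sh)
}

#' Per-voxel tensor eigenvalues
#'
#' @param tensor a \linkS4class{TensorField}.
#' @return Matrix with one row per voxel (linear order) and the three
#'   eigenvalues in descending order.
#' @export
tensorEigenvalues <- function(tensor) {
  stopifnot(is(tensor, "TensorField"))
  .tensor_eigenvalues(as.numeric(tensor@tensors), prod(tensor@grid@shape))
}

#' Build a spatially uniform isotropic tensor field
#'
#' Every in-mask voxel receives d * I; a convenience used by the isotropic
#' model variant and the phantoms.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param d scalar diffusivity, mm^2/day.
#' @param kind tensor kind.
#' @return A \linkS4class{TensorField}.
#' @export
uniformIsotropicTensor <- function(grid, d, kind = "cell") {
  stopifnot(is(grid, "VoxelGrid"), d >= 0)
  a <- array(0, dim = c(grid@shape, 6L))
  a[, , , 1] <- d
  a[, , , 3] <- d
  a[, , , 6] <- d
  TensorField(grid, a, kind = kind)
}

# lower-triangular component order shared across the package
.TENSOR_COMPONENTS <- c("Dxx", "Dxy", "Dyy", "Dxz", "Dyz", "Dzz")

# assemble a 6-component voxel tensor from a full symmetric 3x3 matrix
.sym3_to_lower <- function(m) {
  c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
}
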