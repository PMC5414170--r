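#' @rdname VoxelGrid-class
#' @aliases gridShape
#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)

#' @rdname VoxelGrid-class
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname VoxelGrid-class
#' @export
setMethod("brainMask", "VoxelGrid", function(x) x@mask)

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelVolume", "VoxelGrid", function(x) prod(x@spacing))

#' @rdname TensorField-class
#' @export
setMethod("gridShape", "TensorField", function(x) x@grid@shape)

#' @rdname TensorField-class
#' @export
setMethod("gridSpacing", "TensorField", function(x) x@grid@spacing)

#' @rdname TensorField-class
#' @export
setMethod("brainMask", "TensorField", function(x) x@grid@mask)

#' @rdname TensorField-class
#' @export
setMethod("tensorArray", "TensorField", function(x) x@tensors)

#' @rdname TensorField-class
#' @export
setMethod("tensorKind", "TensorField", function(x) x@kind)

#' @rdname DensityField-class
#' @export
setMethod("densityValues", "DensityField", function(x) x@values)

#' @rdname DensityField-class
#' @export
setMethod("gridShape", "DensityField", function(x) x@grid@shape)

#' @rdname DensityField-class
#' @export
setMethod("brainMask", "DensityField", function(x) x@grid@mask)

#' @rdname SimulationState-class
#' @export
setMethod("stateTime", "SimulationState", function(x) x@t)

#' @rdname SimulationState-class
#' @export
setMethod("densityField", "SimulationState", function(x) x@c)

#' @rdname SimulationState-class
#' @export
setMethod("densityValues", "SimulationState", function(x) x@c@values)

#' @rdname SimulationState-class
#' @export
setMethod("historyMax", "SimulationState", function(x) x@m)

#' @rdname SimulationState-class
#' @export
setMethod("necroticMask", "SimulationState", function(x) x@necrotic)

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %s voxels @ %s mm, %d in mask\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing), collapse = "x"),
              sum(object@mask)))
})

setMethod("show", "TensorField", function(object) {
  md <- meanDiffusivity(object)
  cat(sprintf("TensorField (%s): %s voxels, in-mask mean diffusivity %.4g\n",
              object@kind, paste(object@grid@shape, collapse = "x"), md))
})

setMethod("show", "DensityField", function(object) {
  cat(sprintf("DensityField: %s voxels, max %.4g cells/mm^3\n",
              paste(object@grid@shape, collapse = "x"), max(object@values)))
})

setMethod("show", "GrowthParams", function(object) {
  cat(sprintf(
    "GrowthParams: rho=%.4g/day, cM=%.4g cells/mm^3, tau=%.3g, eta=%.3g, dt=%g day(s), %s growth\n",
    object@rho, object@cM, object@tau, object@eta, object@dt,
    object@growthLaw))
})

setMethod("show", "SimulationState", function(object) {
  cat(sprintf(
    "SimulationState at t=%g days: max c=%.4g, %d necrotic voxel(s)\n",
    object@t, max(object@c@values), sum(object@necrotic)))
})

setMethod("show", "RadiiSeries", function(object) {
  cat(sprintf("RadiiSeries: %d time points over %g days (T1 %.3g-%.3g mm, T2 %.3g-%.3g mm)\n",
              length(object@times), diff(range(object@times)),
              min(object@rT1), max(object@rT1),
              min(object@rT2), max(object@rT2)))
})

setMethod("show", "EstimatedParams", function(object) {
  cat(sprintf(
    "EstimatedParams: v=%.4g mm/day, rho=%.4g/day, D=%.4g mm^2/day, tau=%s, eta=%s\n",
    object@v, object@rho, object@dMean,
    ifelse(is.na(object@tau), "NA", format(object@tau)),
    ifelse(is.na(object@eta), "NA", format(object@eta))))
})
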