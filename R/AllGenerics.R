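#' @rdname VoxelGrid-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname TensorField-class
#' @export
setGeneric("tensorArray", function(x) standardGeneric("tensorArray"))

#' @rdname TensorField-class
#' @export
setGeneric("tensorKind", function(x) standardGeneric("tensorKind"))

#' @rdname DensityField-class
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @rdname SimulationState-class
#' @export
setGeneric("stateTime", function(x) standardGeneric("stateTime"))

#' @rdname SimulationState-class
#' @export
setGeneric("densityField", function(x) standardGeneric("densityField"))

#' @rdname SimulationState-class
#' @export
setGeneric("historyMax", function(x) standardGeneric("historyMax"))

#' @rdname SimulationState-class
#' @export
setGeneric("necroticMask", function(x) standardGeneric("necroticMask"))
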