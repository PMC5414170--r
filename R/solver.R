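#' Model variant selector
#'
#' The model family compared in the original study: isotropic scalar
#' diffusion versus full tensor-guided diffusion, with or without the
#' history-triggered necrosis term, under a selectable proliferation law.
#'
#' @slot diffusion \code{"isotropic"} or \code{"tensor"}.
#' @slot necrosis logical; enable the necrosis switch.
#' @slot growthLaw proliferation law used by the step.
#' @export
setClass("ModelVariant",
  representation(diffusion = "character", necrosis = "logical",
                 growthLaw = "character"))

setValidity("ModelVariant", function(object) {
  msg <- character()
  if (!object@diffusion %in% c("isotropic", "tensor"))
    msg <- c(msg, "diffusion must be 'isotropic' or 'tensor'")
  if (!object@growthLaw %in% c("logistic", "exponential", "gompertz"))
    msg <- c(msg, "growthLaw must be logistic, exponential or gompertz")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelVariant-class
#' @param diffusion,necrosis,growthLaw see slots.
#' @return A \linkS4class{ModelVariant}.
#' @examples
#' modelVariant("tensor", necrosis = TRUE)
#' @export
modelVariant <- function(diffusion = c("tensor", "isotropic"),
                         necrosis = TRUE,
                         growthLaw = c("logistic", "exponential",
                                       "gompertz")) {
  new("ModelVariant", diffusion = match.arg(diffusion),
      necrosis = isTRUE(necrosis), growthLaw = match.arg(growthLaw))
}

.same_grid <- function(a, b) {
  identical(a@shape, b@shape) && isTRUE(all.equal(a@spacing, b@spacing)) &&
    identical(a@mask, b@mask)
}

#' Divergence of the tensor diffusion flux
#'
#' Discrete conservative-form divergence of D(x) grad c: fluxes are
#' evaluated at voxel faces using arithmetic face averages of the adjacent
#' tensors, centered differences for the normal gradient, and averaged
#' mask-aware central differences for the tangential (mixed-derivative)
#' gradients. Faces touching out-of-mask voxels carry no flux, giving a
#' homogeneous Neumann (zero-flux) boundary at the brain-mask boundary; by
#' construction the operator conserves total mass.
#'
#' @param c a \linkS4class{DensityField}.
#' @param D a \linkS4class{TensorField} of kind \code{"cell"} on the same
#'   grid.
#' @return Numeric array of dc/dt contributions, cells/mm^3/day.
#' @export
diffusionDivergence <- function(c, D) {
  stopifnot(is(c, "DensityField"), is(D, "TensorField"))
  if (!.same_grid(c@grid, D@grid))
    stop("density and tensor fields are defined on different grids")
  if (D@kind != "cell")
    stop("diffusion requires a cell tensor (kind = 'cell'), got '",
         D@kind, "'")
  .div_tensor_flux(as.numeric(c@values), as.numeric(D@tensors),
                   as.logical(c@grid@mask), c@grid@shape, c@grid@spacing)
}

#' Proliferation term
#'
#' Per-voxel intrinsic cell multiplication rate R(x, t): exponential
#' (rho*c), logistic (rho*c*(1 - c/c_m)) or Gompertz (rho*c*ln(c_m/c), with
#' the limit value 0 at c = 0).
#'
#' @param c a \linkS4class{DensityField} (or bare numeric array).
#' @param params a \linkS4class{GrowthParams}; \code{params@growthLaw}
#'   selects the law.
#' @return Numeric array, cells/mm^3/day.
#' @export
proliferation <- function(c, params) {
  stopifnot(is(params, "GrowthParams"))
  v <- if (is(c, "DensityField")) c@values else c
  switch(params@growthLaw,
    exponential = params@rho * v,
    logistic = params@rho * v * (1 - v / params@cM),
    gompertz = {
      r <- array(0, dim = dim(v))
      pos <- v > 0
      r[pos] <- params@rho * v[pos] * log(params@cM / v[pos])
      r
    })
}

#' Apply the necrosis decay and re-classify
#'
#' In necrotic voxels the density is multiplied by eta^dt (eta read as the
#' per-day survival fraction, so cells decay exponentially at rate
#' -ln(eta)); non-necrotic voxels are untouched. The necrotic set is then
#' recomputed from the history maximum, so it can only grow.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param params a \linkS4class{GrowthParams}.
#' @param dt decay interval in days; defaults to \code{params@dt}.
#' @return The updated \linkS4class{SimulationState} (time unchanged).
#' @export
necrosisUpdate <- function(state, params, dt = NULL) {
  stopifnot(is(state, "SimulationState"), is(params, "GrowthParams"))
  if (is.null(dt)) dt <- params@dt
  vals <- state@c@values
  vals[state@necrotic] <- vals[state@necrotic] * params@eta^dt
  m <- pmax(state@m, vals)
  necrotic <- state@necrotic | (m >= params@tau * params@cM)
  new("SimulationState", t = state@t, c = DensityField(state@c@grid, vals),
      m = m, necrotic = necrotic)
}

#' Explicit stability bound for the diffusion step
#'
#' Largest forward-Euler time step guaranteed stable for the tensor
#' stencil, 1 / (2 * max over voxels of sum_ij |D_ij| / (h_i h_j)). The sum
#' over all nine components (not just the trace) covers the
#' mixed-derivative terms of anisotropic tensors.
#'
#' @param D a \linkS4class{TensorField} or a scalar diffusivity (mm^2/day).
#' @param grid required when \code{D} is scalar.
#' @return Time step in days (Inf for zero diffusivity).
#' @export
stableTimeStep <- function(D, grid = NULL) {
  if (is(D, "TensorField")) {
    a <- D@tensors
    h <- D@grid@spacing
    s <- abs(a[, , , 1]) / h[1]^2 + abs(a[, , , 3]) / h[2]^2 +
      abs(a[, , , 6]) / h[3]^2 +
      2 * abs(a[, , , 2]) / (h[1] * h[2]) +
      2 * abs(a[, , , 4]) / (h[1] * h[3]) +
      2 * abs(a[, , , 5]) / (h[2] * h[3])
    smax <- max(s[D@grid@mask])
  } else {
    stopifnot(is(grid, "VoxelGrid"))
    smax <- D * sum(1 / grid@spacing^2)
  }
  if (smax <= 0) Inf else 1 / (2 * smax)
}

# One reporting step with internal substepping; returns diagnostics too.
.step_core <- function(state, D, params, variant, cfl = 0.25) {
  grid <- state@c@grid
  if (variant@diffusion == "isotropic") {
    if (is(D, "TensorField"))
      stop("isotropic variant requires a scalar diffusivity D (mm^2/day)")
    D <- uniformIsotropicTensor(grid, D, kind = "cell")
  } else if (!is(D, "TensorField")) {
    stop("tensor variant requires a TensorField of kind 'cell'")
  }
  if (!.same_grid(grid, D@grid))
    stop("state and tensor field are defined on different grids")
  if (D@kind != "cell") stop("diffusion requires a cell tensor")

  dt <- params@dt
  dt_stab <- stableTimeStep(D)
  n_sub <- max(1L, as.integer(ceiling(dt / (cfl * dt_stab))))
  dt_sub <- dt / n_sub
  decay <- params@eta^dt_sub
  tau_abs <- params@tau * params@cM
  mask <- grid@mask
  darr <- as.numeric(D@tensors)
  gp <- params
  gp@growthLaw <- variant@growthLaw

  vals <- state@c@values
  m <- state@m
  necrotic <- if (variant@necrosis) state@necrotic else
    array(FALSE, dim = grid@shape)
  clip_events <- 0L

  for (s in seq_len(n_sub)) {
    div <- .div_tensor_flux(as.numeric(vals), darr, as.logical(mask),
                            grid@shape, grid@spacing)
    R <- proliferation(vals, gp)
    live <- mask & !necrotic
    newvals <- vals
    newvals[live] <- vals[live] + dt_sub * (div[live] + R[live])
    if (variant@necrosis && any(necrotic))
      newvals[necrotic] <- vals[necrotic] * decay
    bad <- !is.finite(newvals)
    if (any(bad)) {
      ix <- arrayInd(which(bad)[1], grid@shape)
      stop(sprintf(
        "non-finite density at voxel (%d,%d,%d) in substep %d of %d (t=%g); reduce cfl or dt",
        ix[1], ix[2], ix[3], s, n_sub, state@t))
    }
    out_of_bounds <- live & (newvals < 0 | newvals > params@cM)
    clip_events <- clip_events + sum(out_of_bounds)
    newvals <- pmin(pmax(newvals, 0), params@cM)
    m <- pmax(m, newvals)
    if (variant@necrosis) necrotic <- necrotic | (m >= tau_abs)
    vals <- newvals
  }
  st <- new("SimulationState", t = state@t + dt,
            c = DensityField(grid, vals), m = m, necrotic = necrotic)
  list(state = st, substeps = n_sub, clipEvents = clip_events)
}

#' Advance the simulation by one reporting step
#'
#' Forward-Euler integration of the full piecewise model over one reporting
#' interval \code{params@dt} (1 day by default). Non-necrotic voxels evolve
#' by tensor diffusion plus proliferation; necrotic voxels only decay.
#' After each internal substep the history maximum m is updated, the
#' necrotic set is re-classified (newly necrotic voxels start decaying on
#' the following substep), and the density is clipped to [0, c_m]. The
#' solver substeps internally whenever \code{cfl * stableTimeStep(D)} is
#' finer than \code{params@dt}, so the reporting cadence is unaffected.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param D a \linkS4class{TensorField} (tensor variant) or scalar
#'   diffusivity in mm^2/day (isotropic variant).
#' @param params a \linkS4class{GrowthParams}.
#' @param variant a \linkS4class{ModelVariant}.
#' @param cfl safety fraction of the explicit stability bound used for the
#'   internal substep (default 0.25; accuracy of traveling fronts degrades
#'   near the bare bound).
#' @return The advanced \linkS4class{SimulationState}.
#' @export
stepState <- function(state, D, params, variant = modelVariant(),
                      cfl = 0.25) {
  stopifnot(is(state, "SimulationState"), is(params, "GrowthParams"),
            is(variant, "ModelVariant"))
  .step_core(state, D, params, variant, cfl)$state
}

#' Run a multi-day simulation
#'
#' Repeatedly applies \code{\link{stepState}} for \code{nDays} reporting
#' steps, collecting snapshots (always including t = 0 and the final day)
#' and a per-step log of total cell mass, peak density, necrotic voxel
#' count, substep count and clip events. Fully deterministic given its
#' inputs.
#'
#' @param initial a \linkS4class{SimulationState} (typically from
#'   \code{\link{makeState}}).
#' @param D tensor field or scalar diffusivity, as in
#'   \code{\link{stepState}}.
#' @param params a \linkS4class{GrowthParams}.
#' @param variant a \linkS4class{ModelVariant}.
#' @param nDays number of reporting steps (days when dt = 1) to simulate.
#' @param snapshotEvery snapshot cadence in reporting steps.
#' @param cfl substep safety fraction, see \code{\link{stepState}}.
#' @return A list with elements \code{snapshots} (list of
#'   \linkS4class{SimulationState}, including t = 0 and the final state)
#'   and \code{log} (data.frame with columns t, totalMass, maxDensity,
#'   necroticVoxels, substeps, clipEvents).
#' @examples
#' ph <- isotropicPhantom(shape = c(17, 17, 17), meanDiffusivity = 0.0825)
#' st <- makeState(ph$grid, c(9, 9, 9), params = GrowthParams())
#' run <- simulateGrowth(st, ph$tensor, GrowthParams(), modelVariant(),
#'                       nDays = 3)
#' length(run$snapshots)
#' @export
simulateGrowth <- function(initial, D, params, variant = modelVariant(),
                           nDays, snapshotEvery = 1L, cfl = 0.25) {
  stopifnot(is(initial, "SimulationState"), nDays >= 0,
            snapshotEvery >= 1L)
  vol <- voxelVolume(initial@c@grid)
  snapshots <- list(initial)
  log <- data.frame(t = initial@t,
                    totalMass = sum(initial@c@values) * vol,
                    maxDensity = max(initial@c@values),
                    necroticVoxels = sum(initial@necrotic),
                    substeps = 0L, clipEvents = 0L)
  state <- initial
  if (nDays >= 1) {
    for (d in seq_len(nDays)) {
      res <- .step_core(state, D, params, variant, cfl)
      state <- res$state
      log <- rbind(log, data.frame(
        t = state@t, totalMass = sum(state@c@values) * vol,
        maxDensity = max(state@c@values),
        necroticVoxels = sum(state@necrotic),
        substeps = res$substeps, clipEvents = res$clipEvents))
      if (d %% snapshotEvery == 0L || d == nDays)
        snapshots[[length(snapshots) + 1L]] <- state
    }
  }
  list(snapshots = snapshots, log = log)
}
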