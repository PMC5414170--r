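# Experiment drivers behind the command-line front end: config-driven
# simulation runs with provenance, parameter JSON, and the seed
# displacement experiment.

.default_config <- function() {
  list(
    tensor_path = NULL, mask_path = NULL, phantom = NULL,
    params = list(rho = 0.33, c_m = 1e5, tau = 0.85, eta = 0.9, dt = 1,
                  growth_law = "logistic"),
    variant = list(diffusion = "tensor", necrosis = TRUE),
    seed_voxel = NULL, c0 = NULL,
    horizon_days = 30L, snapshot_every = 5L, cfl = 0.25,
    metric = list(bins = 64L), seed = 1L)
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a JSON run configuration and fills unset fields with package
#' defaults (the glioblastoma case-study parameters). Either
#' \code{tensor_path} (+ optional \code{mask_path}) or a \code{phantom}
#' block must describe the anatomy.
#'
#' @param path JSON file, or \code{NULL} for pure defaults.
#' @param overrides named list merged over the file values (CLI flags).
#' @return The resolved configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file does not exist: ", path)
    cfg <- .merge_config(cfg, jsonlite::read_json(path, simplifyVector = TRUE))
  }
  .merge_config(cfg, overrides)
}

.config_params <- function(cfg) {
  p <- cfg$params
  GrowthParams(rho = p$rho, cM = p$c_m, tau = p$tau, eta = p$eta,
               dt = p$dt, growthLaw = p$growth_law)
}

.config_variant <- function(cfg) {
  modelVariant(cfg$variant$diffusion, isTRUE(cfg$variant$necrosis),
               cfg$params$growth_law)
}

.config_anatomy <- function(cfg) {
  if (!is.null(cfg$phantom)) {
    ph <- cfg$phantom
    medium <- if (is.null(ph$medium)) "isotropic" else ph$medium
    shape <- if (is.null(ph$shape)) c(64, 64, 64) else unlist(ph$shape)
    spacing <- if (is.null(ph$spacing)) c(1, 1, 1) else unlist(ph$spacing)
    md <- if (is.null(ph$mean_diffusivity)) 0.0825 else ph$mean_diffusivity
    if (medium == "isotropic")
      return(isotropicPhantom(shape, spacing, md))
    fa <- if (is.null(ph$fa_target)) 0.8 else ph$fa_target
    ax <- if (is.null(ph$fiber_axis)) 1L else as.integer(ph$fiber_axis)
    return(fiberPhantom(shape, spacing, md, faTarget = fa, fiberAxis = ax))
  }
  if (is.null(cfg$tensor_path))
    stop("config must provide either tensor_path or a phantom block")
  if (!file.exists(cfg$tensor_path))
    stop("tensor file does not exist: ", cfg$tensor_path)
  if (!is.null(cfg$mask_path) && !file.exists(cfg$mask_path))
    stop("mask file does not exist: ", cfg$mask_path)
  tf <- readTensorField(cfg$tensor_path, maskPath = cfg$mask_path,
                        kind = "cell")
  list(grid = tf@grid, tensor = tf)
}

#' Run a configured simulation and write snapshots with provenance
#'
#' Resolves the configuration, builds or loads the anatomy, seeds the
#' tumor, integrates the model, and writes to \code{outDir}: one density
#' volume (float32 NIfTI) and one necrosis mask (uint8) per snapshot, a
#' per-step CSV log (time, total mass, peak density, necrotic voxels,
#' substeps, clip events), the resolved configuration, and a provenance
#' sidecar sufficient to re-execute the run bit-identically.
#'
#' @param config configuration list (see \code{\link{readRunConfig}}) or a
#'   JSON path.
#' @param outDir output directory, created if needed.
#' @return Invisibly, a list with \code{snapshots}, \code{log} and
#'   \code{outDir}.
#' @export
runSimulation <- function(config, outDir) {
  cfg <- if (is.character(config)) readRunConfig(config) else
    .merge_config(.default_config(), config)
  anat <- .config_anatomy(cfg)
  params <- .config_params(cfg)
  variant <- .config_variant(cfg)
  seedvox <- if (is.null(cfg$seed_voxel))
    as.integer((gridShape(anat$grid) + 1) %/% 2) else
    as.integer(unlist(cfg$seed_voxel))
  c0 <- if (is.null(cfg$c0)) NULL else cfg$c0
  st <- makeState(anat$grid, seedvox, c0 = c0, params = params)
  D <- if (variant@diffusion == "isotropic")
    meanDiffusivity(anat$tensor) else anat$tensor
  run <- simulateGrowth(st, D, params, variant,
                        nDays = cfg$horizon_days,
                        snapshotEvery = cfg$snapshot_every, cfl = cfg$cfl)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  spacing <- gridSpacing(anat$grid)
  files <- character(0)
  for (s in run$snapshots) {
    stem <- sprintf("density_t%04d", as.integer(round(stateTime(s))))
    writeNifti(densityValues(s), file.path(outDir, paste0(stem, ".nii.gz")),
               spacing = spacing, datatype = "float32")
    writeNifti(array(as.integer(necroticMask(s)), dim = dim(necroticMask(s))),
               file.path(outDir, sprintf("necrosis_t%04d.nii.gz",
                                         as.integer(round(stateTime(s))))),
               spacing = spacing, datatype = "uint8")
    files <- c(files, paste0(stem, ".nii.gz"))
  }
  utils::write.csv(run$log, file.path(outDir, "log.csv"), row.names = FALSE)
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  provenance <- list(
    package = "gliosim",
    version = as.character(utils::packageVersion("gliosim")),
    snapshots = files,
    times = vapply(run$snapshots, stateTime, numeric(1)),
    substeps_per_day = max(run$log$substeps),
    clip_events_total = sum(run$log$clipEvents),
    seed_voxel = seedvox)
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(snapshots = run$snapshots, log = run$log, outDir = outDir))
}

#' Serialize estimated parameters to the solver's config schema
#'
#' @param est an \linkS4class{EstimatedParams} or
#'   \linkS4class{GrowthParams}.
#' @param path JSON output path.
#' @param cM,dt,growthLaw fill-ins when \code{est} lacks them.
#' @return \code{path}, invisibly.
#' @export
writeParamsJson <- function(est, path, cM = 1e5, dt = 1,
                            growthLaw = "logistic") {
  if (is(est, "GrowthParams")) {
    block <- list(rho = est@rho, c_m = est@cM, tau = est@tau, eta = est@eta,
                  dt = est@dt, growth_law = est@growthLaw)
    extra <- list()
  } else if (is(est, "EstimatedParams")) {
    block <- list(rho = est@rho, c_m = cM,
                  tau = if (is.na(est@tau)) NULL else est@tau,
                  eta = if (is.na(est@eta)) NULL else est@eta,
                  dt = dt, growth_law = growthLaw)
    extra <- list(v_mm_per_day = est@v, d_mean_mm2_per_day = est@dMean)
  } else stop("est must be EstimatedParams or GrowthParams")
  jsonlite::write_json(c(list(params = block), extra), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Seed-displacement sensitivity experiment
#'
#' Runs the configured model from a reference seed voxel and from four
#' seeds displaced by \code{displacementVoxels} in the cardinal in-plane
#' directions (+x, -x, +y, -y), then reports the mutual information of
#' each final density field against the reference final density. The
#' reference row carries the self-MI (the binned marginal entropy), an
#' upper bound the displaced profiles stay below.
#'
#' @param tensor a \linkS4class{TensorField} of kind \code{"cell"}.
#' @param params a \linkS4class{GrowthParams}.
#' @param seedIndex reference seed voxel (1-based triple); defaults to the
#'   grid center.
#' @param displacementVoxels shift magnitude in voxels.
#' @param horizonDays simulated horizon.
#' @param variant a \linkS4class{ModelVariant}.
#' @param bins histogram bins for the MI computation.
#' @param cfl substep safety fraction.
#' @return A data.frame with one row per run (reference first):
#'   direction, seed indices and MI in bits.
#' @export
seedSensitivity <- function(tensor, params, seedIndex = NULL,
                            displacementVoxels = 1L, horizonDays = 30L,
                            variant = modelVariant(), bins = 64L,
                            cfl = 0.25) {
  stopifnot(is(tensor, "TensorField"), is(params, "GrowthParams"))
  grid <- tensor@grid
  if (is.null(seedIndex)) seedIndex <- as.integer((grid@shape + 1) %/% 2)
  shifts <- list(reference = c(0L, 0L, 0L),
                 right = c(displacementVoxels, 0L, 0L),
                 left = c(-displacementVoxels, 0L, 0L),
                 anterior = c(0L, displacementVoxels, 0L),
                 posterior = c(0L, -displacementVoxels, 0L))
  seeds <- lapply(shifts, function(s) as.integer(seedIndex + s))
  for (nm in names(seeds)) {
    sv <- seeds[[nm]]
    if (any(sv < 1L) || any(sv > grid@shape) ||
        !grid@mask[sv[1], sv[2], sv[3]])
      stop("displaced seed (", nm, ") at ", paste(sv, collapse = ","),
           " lies outside the brain mask")
  }
  finals <- lapply(seeds, function(sv) {
    st <- makeState(grid, sv, params = params)
    run <- simulateGrowth(st, tensor, params, variant, nDays = horizonDays,
                          snapshotEvery = max(1L, horizonDays), cfl = cfl)
    densityValues(run$snapshots[[length(run$snapshots)]])
  })
  ref <- finals$reference
  mi <- vapply(finals, function(f)
    mutualInformation(f, ref, mask = grid@mask, bins = bins), numeric(1))
  data.frame(direction = names(seeds),
             sx = vapply(seeds, `[`, integer(1), 1),
             sy = vapply(seeds, `[`, integer(1), 2),
             sz = vapply(seeds, `[`, integer(1), 3),
             mi_bits = as.numeric(mi), row.names = NULL)
}
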