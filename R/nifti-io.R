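# Minimal single-file NIfTI-1 (.nii / .nii.gz) reader and writer. No
# NIfTI-capable package ships with the supported environment, so only the
# subset this package needs is implemented: 3-D scalar volumes and 4-D
# tensor volumes, native types uint8 / int16 / int32 / float32 / float64,
# voxel spacing from pixdim, optional scl_slope/scl_inter on read. The
# affine (qform/sform) is not interpreted: simulation lives in voxel space
# with physical spacing.

.NIFTI_DT <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  name = c("uint8", "int16", "int32", "float32", "float64"),
  bytes = c(1L, 2L, 4L, 4L, 8L),
  stringsAsFactors = FALSE)

.open_nifti <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric or logical array, 3-D or 4-D.
#' @param path output path, \code{.nii} or \code{.nii.gz}.
#' @param spacing voxel spacing, mm (first three pixdims).
#' @param datatype on-disk type; densities default to \code{"float32"},
#'   masks should use \code{"uint8"}.
#' @return \code{path}, invisibly.
#' @export
writeNifti <- function(data, path, spacing = c(1, 1, 1),
                       datatype = c("float32", "uint8", "int16", "int32",
                                    "float64")) {
  datatype <- match.arg(datatype)
  dt <- .NIFTI_DT[.NIFTI_DT$name == datatype, ]
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("data must be a 3-D or 4-D array")
  con <- .open_nifti(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                  # sizeof_hdr
  writeBin(raw(36), con)                       # unused header fields
  dims <- rep(1L, 8)
  dims[1] <- length(d)
  dims[seq_along(d) + 1L] <- d
  wi(dims, 2)                                  # dim[8]
  writeBin(raw(14), con)                       # intent fields
  wi(dt$code, 2)                               # datatype
  wi(8L * dt$bytes, 2)                         # bitpix
  wi(0L, 2)                                    # slice_start
  pixdim <- c(1, spacing, rep(1, 4))
  wf(pixdim)                                   # pixdim[8]
  wf(352)                                      # vox_offset
  wf(1); wf(0)                                 # scl_slope, scl_inter
  writeBin(raw(348 - 120 - 4), con)            # remainder up to magic
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                        # extension flag
  vals <- as.vector(data)
  if (datatype %in% c("float32", "float64"))
    writeBin(as.numeric(vals), con, size = dt$bytes, endian = "little")
  else
    writeBin(as.integer(vals), con, size = dt$bytes, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path input path, \code{.nii} or \code{.nii.gz}.
#' @return A list with \code{data} (array, scl slope/intercept applied),
#'   \code{spacing} (first three pixdims) and \code{datatype}.
#' @export
readNifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file does not exist: ", path)
  con <- .open_nifti(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  if (hdr != 348L) {
    endian <- "big"
    if (!grepl("\\.gz$", path)) {
      close(con); con <- .open_nifti(path, "rb")
      seek(con, 0)
      hdr <- readBin(con, "integer", n = 1, size = 4, endian = endian)
    } else stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    if (hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  readBin(con, "raw", n = 36)
  dims <- readBin(con, "integer", n = 8, size = 2, endian = endian)
  readBin(con, "raw", n = 14)
  dtcode <- readBin(con, "integer", n = 1, size = 2, endian = endian)
  readBin(con, "integer", n = 2, size = 2, endian = endian)
  pixdim <- readBin(con, "numeric", n = 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", n = 1, size = 4, endian = endian)
  scl <- readBin(con, "numeric", n = 2, size = 4, endian = endian)
  dt <- .NIFTI_DT[.NIFTI_DT$code == dtcode, ]
  if (nrow(dt) == 0) stop("unsupported NIfTI datatype code ", dtcode)
  nd <- dims[1]
  if (!(nd %in% c(3L, 4L))) stop("only 3-D and 4-D volumes are supported")
  shape <- dims[2:(nd + 1)]
  # skip from byte 120 to vox_offset
  readBin(con, "raw", n = as.integer(round(vox_offset)) - 120L)
  n <- prod(shape)
  data <- if (dt$name %in% c("float32", "float64"))
    readBin(con, "numeric", n = n, size = dt$bytes, endian = endian)
  else
    readBin(con, "integer", n = n, size = dt$bytes, endian = endian,
            signed = dt$name != "uint8")
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    data <- data * scl[1] + scl[2]
  list(data = array(data, dim = shape), spacing = pixdim[2:4],
       datatype = dt$name)
}

#' Write/read a tensor field as 4-D NIfTI
#'
#' The six per-voxel components are stored along the fourth dimension in
#' lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) -- the common
#' FSL-style convention; the reader validates that exactly six components
#' are present and re-checks the positive semi-definiteness of the
#' reconstructed field.
#'
#' @param tensor a \linkS4class{TensorField}.
#' @param path file path (\code{.nii}/\code{.nii.gz}).
#' @return \code{writeTensorField}: \code{path}, invisibly.
#' @export
writeTensorField <- function(tensor, path) {
  stopifnot(is(tensor, "TensorField"))
  writeNifti(tensor@tensors, path, spacing = tensor@grid@spacing,
             datatype = "float64")
  invisible(path)
}

#' @rdname writeTensorField
#' @param maskPath path of the companion brain-mask volume (uint8); when
#'   missing, all voxels are in-mask.
#' @param kind tensor kind of the loaded field.
#' @return \code{readTensorField}: a \linkS4class{TensorField}.
#' @export
readTensorField <- function(path, maskPath = NULL, kind = "cell") {
  v <- readNifti(path)
  d <- dim(v$data)
  if (length(d) != 4L || d[4] != 6L)
    stop("tensor NIfTI must be 4-D with 6 components in lower-triangular ",
         "order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz); got dim ",
         paste(d, collapse = "x"))
  mask <- if (is.null(maskPath)) array(TRUE, dim = d[1:3]) else
    readNifti(maskPath)$data != 0
  grid <- VoxelGrid(d[1:3], v$spacing, array(as.logical(mask), dim = d[1:3]))
  TensorField(grid, v$data, kind = kind)
}
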