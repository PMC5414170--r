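#' Joint intensity histogram
#'
#' Two-dimensional histogram of paired voxel values over a mask, using
#' equal-width bins spanning each field's in-mask range. The basis of the
#' mutual-information metric.
#'
#' @slot counts integer matrix, binsC x binsS.
#' @slot edgesC,edgesS numeric bin edges for each axis.
#' @export
setClass("JointHistogram",
  representation(counts = "matrix", edgesC = "numeric", edgesS = "numeric"))

setValidity("JointHistogram", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (nrow(object@counts) != length(object@edgesC) - 1L ||
      ncol(object@counts) != length(object@edgesS) - 1L)
    msg <- c(msg, "edge lengths must match the count matrix dimensions")
  if (length(msg)) msg else TRUE
})

.bin_index <- function(v, edges) {
  # last bin is closed on the right so the maximum lands inside
  i <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' @rdname JointHistogram-class
#' @param c,s numeric fields of identical shape (arrays, or
#'   \linkS4class{DensityField}s).
#' @param mask optional logical array restricting the comparison (defaults
#'   to all voxels, or the grid mask when \code{c} is a
#'   \linkS4class{DensityField}).
#' @param bins number of equal-width bins per axis.
#' @return A \linkS4class{JointHistogram}.
#' @export
jointHistogram <- function(c, s, mask = NULL, bins = 64L) {
  if (is(c, "DensityField")) {
    if (is.null(mask)) mask <- c@grid@mask
    c <- c@values
  }
  if (is(s, "DensityField")) s <- s@values
  if (!identical(dim(c), dim(s)))
    stop("fields to compare have different shapes")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(c))
  if (!identical(dim(mask), dim(c)))
    stop("mask shape does not match the fields")
  cv <- c[mask]
  sv <- s[mask]
  edge <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1L)
  }
  ec <- edge(cv)
  es <- edge(sv)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(.bin_index(cv, ec), levels = seq_len(bins)),
               factor(.bin_index(sv, es), levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  new("JointHistogram", counts = counts, edgesC = ec, edgesS = es)
}

#' Mutual information between two voxel fields
#'
#' Histogram-based mutual information in bits,
#' MI = sum over occupied joint bins of p(C,S) log2[p(C,S) / (p(C) p(S))],
#' with equal-width bins spanning each field's in-mask range. Empty joint
#' bins contribute zero (the x log x limit). A field that is constant
#' within the mask yields MI = 0.
#'
#' @inheritParams jointHistogram
#' @return Mutual information in bits (non-negative).
#' @examples
#' a <- array(rep(c(0, 1), 32), dim = c(4, 4, 4))
#' mutualInformation(a, a, bins = 2)  # = marginal entropy = 1 bit
#' @export
mutualInformation <- function(c, s, mask = NULL, bins = 64L) {
  jh <- jointHistogram(c, s, mask = mask, bins = bins)
  mutualInformationFromHistogram(jh)
}

#' @rdname mutualInformation
#' @param histogram a \linkS4class{JointHistogram}.
#' @export
mutualInformationFromHistogram <- function(histogram) {
  stopifnot(is(histogram, "JointHistogram"))
  n <- sum(histogram@counts)
  if (n == 0) return(0)
  p <- histogram@counts / n
  pc <- rowSums(p)
  ps <- colSums(p)
  occ <- which(p > 0, arr.ind = TRUE)
  pj <- p[occ]
  max(0, sum(pj * log2(pj / (pc[occ[, 1]] * ps[occ[, 2]]))))
}

#' Imaging detection masks of a simulation state
#'
#' Thresholds the density at a fraction of the carrying capacity,
#' realizing the hypothesized imaging contours (0.16 c_m for the T2
#' margin, 0.80 c_m for contrast-enhanced T1). The \code{"enhancing"}
#' variant additionally excludes necrotic voxels (dead tissue does not
#' enhance); \code{"necrotic"} returns the necrotic core itself.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param fraction detection fraction of \code{cM}, in (0, 1).
#' @param cM carrying capacity, cells/mm^3.
#' @param type \code{"total"}, \code{"enhancing"} or \code{"necrotic"}.
#' @return Logical array.
#' @export
detectionMask <- function(state, fraction = 0.16, cM,
                          type = c("total", "enhancing", "necrotic")) {
  stopifnot(is(state, "SimulationState"), fraction > 0, fraction < 1)
  type <- match.arg(type)
  above <- state@c@values >= fraction * cM
  switch(type,
         total = above,
         enhancing = above & !state@necrotic,
         necrotic = state@necrotic)
}

#' Volume-equivalent radius of a voxel mask
#'
#' Radius of the sphere with the mask's volume, (3V / 4 pi)^(1/3) with
#' V = voxel count times voxel volume. For quasi-2-D grids (a singleton
#' axis) the disc-equivalent radius sqrt(A / pi) is used instead.
#'
#' @param mask logical array.
#' @param spacing voxel spacing, mm.
#' @return Radius in mm (0 for an empty mask).
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' equivalentRadius(m, c(1, 1, 1))  # (3/(4*pi))^(1/3)
#' @export
equivalentRadius <- function(mask, spacing = c(1, 1, 1)) {
  n <- sum(mask)
  if (n == 0) return(0)
  d <- dim(mask)
  if (any(d == 1L)) {
    flat <- which(d == 1L)[1]
    area <- n * prod(spacing[-flat])
    sqrt(area / pi)
  } else {
    vol <- n * prod(spacing)
    (3 * vol / (4 * pi))^(1 / 3)
  }
}

#' Width of the enhancing rim
#'
#' Equivalent radius of the full lesion (enhancing shell plus necrotic
#' core) minus the equivalent radius of the necrotic core. With no
#' necrosis the core radius is zero and the value equals the outer
#' enhancing radius.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param cM carrying capacity.
#' @param enhancingFraction detection fraction of the enhancing rim
#'   (default 0.80).
#' @return Rim width in mm.
#' @export
rimWidth <- function(state, cM, enhancingFraction = 0.80) {
  stopifnot(is(state, "SimulationState"))
  spacing <- state@c@grid@spacing
  enh <- detectionMask(state, enhancingFraction, cM, "enhancing")
  nec <- state@necrotic
  equivalentRadius(enh | nec, spacing) - equivalentRadius(nec, spacing)
}

#' Asymptotic front speed from a snapshot sequence
#'
#' Least-squares slope of the detection-mask equivalent radius versus time
#' over the last half of the snapshots, discarding the pre-asymptotic
#' transient of the traveling wave.
#'
#' @param snapshots list of \linkS4class{SimulationState} (>= 3, increasing
#'   times).
#' @param fraction detection fraction of \code{cM} defining the front.
#' @param cM carrying capacity.
#' @return Front speed in mm/day.
#' @export
frontSpeed <- function(snapshots, fraction = 0.16, cM) {
  if (length(snapshots) < 3L)
    stop("at least three snapshots are required")
  times <- vapply(snapshots, stateTime, numeric(1))
  spacing <- snapshots[[1]]@c@grid@spacing
  radii <- vapply(snapshots, function(s)
    equivalentRadius(detectionMask(s, fraction, cM, "total"), spacing),
    numeric(1))
  keep <- seq(from = floor(length(times) / 2) + 1L, to = length(times))
  t2 <- times[keep]
  r2 <- radii[keep]
  if (length(unique(t2)) < 2L || stats::var(t2) == 0)
    stop("degenerate fit: snapshot times do not span an interval")
  stats::cov(t2, r2) / stats::var(t2)
}
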