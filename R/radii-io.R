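#' Read and write serial radii as CSV
#'
#' The on-disk format is a plain CSV with header
#' \code{time_days,r_t1_mm,r_t2_mm}.
#'
#' @param path CSV file path.
#' @return \code{readRadiiCsv}: a \linkS4class{RadiiSeries}.
#' @export
readRadiiCsv <- function(path) {
  if (!file.exists(path)) stop("radii CSV does not exist: ", path)
  df <- utils::read.csv(path)
  need <- c("time_days", "r_t1_mm", "r_t2_mm")
  if (!all(need %in% names(df)))
    stop("radii CSV must have columns ", paste(need, collapse = ", "))
  RadiiSeries(df$time_days, df$r_t1_mm, df$r_t2_mm)
}

#' @rdname readRadiiCsv
#' @param radii a \linkS4class{RadiiSeries}.
#' @return \code{writeRadiiCsv}: \code{path}, invisibly.
#' @export
writeRadiiCsv <- function(radii, path) {
  stopifnot(is(radii, "RadiiSeries"))
  utils::write.csv(
    data.frame(time_days = radii@times, r_t1_mm = radii@rT1,
               r_t2_mm = radii@rT2),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
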