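#' Multi-echo magnitude image series
#'
#' Container for a multi-echo spin-echo acquisition: a 4-D array of magnitude
#' intensities indexed as `[row, col, slice, echo]` together with the echo
#' times and the voxel geometry needed for volume bookkeeping.
#'
#' @param data numeric 4-D array `[row, col, slice, echo]` of non-negative
#'   magnitude intensities.
#' @param te numeric vector of echo times in msec, strictly increasing, one
#'   entry per echo (length must equal `dim(data)[4]`).
#' @param spacing in-plane pixel spacing in mm (isotropic in-plane).
#' @param thickness slice thickness in mm.
#'
#' @return An object of class `echo_series`.
#' @examples
#' arr <- array(1000 * exp(-rep(c(13.8, 27.6, 41.4, 55.2, 69), each = 8) / 40),
#'              dim = c(2, 2, 2, 5))
#' es <- echo_series(arr, te = c(13.8, 27.6, 41.4, 55.2, 69))
#' n_echoes(es)
#' @export
echo_series <- function(data, te, spacing = 0.664, thickness = 2) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("`data` must be a 4-D array [row, col, slice, echo]")
  te <- as.numeric(te)
  if (length(te) < 2L || any(diff(te) <= 0))
    stopf("`te` must be >= 2 strictly increasing echo times (msec)")
  if (length(te) != dim(data)[4L])
    stopf("length(te) = %d does not match %d echoes in `data`",
          length(te), dim(data)[4L])
  if (any(data < 0)) stopf("magnitude data must be non-negative")
  if (spacing <= 0 || thickness <= 0)
    stopf("spacing and thickness must be positive (mm)")
  structure(
    list(data = data, te = te, spacing = spacing, thickness = thickness),
    class = "echo_series"
  )
}

#' @export
dim.echo_series <- function(x) dim(x$data)

#' Number of echoes in a series
#' @param series an `echo_series`.
#' @return integer count of echoes.
#' @export
n_echoes <- function(series) length(series$te)

#' Voxel volume of an image grid
#'
#' Computed as pixel spacing squared times slice thickness.
#'
#' @param x an `echo_series` or `t2map`, or a numeric pixel spacing in mm.
#' @param thickness slice thickness in mm (only when `x` is numeric).
#' @return voxel volume in mm^3.
#' @examples
#' voxel_volume(0.664, 2)   # the 0.664 mm / 2 mm protocol: 0.882 mm^3
#' @export
voxel_volume <- function(x, thickness = NULL) {
  if (is.numeric(x)) {
    if (is.null(thickness)) stopf("supply `thickness` with a numeric spacing")
    return(x^2 * thickness)
  }
  x$spacing^2 * x$thickness
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Multi-echo series: %d x %d x %d voxels, %d echoes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TE (msec): %s\n", paste(format(x$te), collapse = ", ")))
  cat(sprintf("  voxel: %.3f x %.3f x %.1f mm (%.3f mm^3)\n",
              x$spacing, x$spacing, x$thickness, voxel_volume(x)))
  invisible(x)
}

# Reshape the series to an E x N matrix of echo vectors (columns = voxels).
echo_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, nrow = prod(d[1:3]), ncol = d[4]))
}
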