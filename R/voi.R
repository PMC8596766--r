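#' Load a volume of interest onto a T2 map
#'
#' Restricts a voxel mask to the map grid, optionally after an integer
#' translation (manual alignment correction between the morphological series
#' the VOI was drawn on and the multi-echo grid), and records how many VOI
#' voxels carry valid T2 values.
#'
#' @param mask logical array on the map grid (or an integer array combined
#'   with `value`, keeping `mask == value`).
#' @param map a [t2map()].
#' @param shift integer translation `c(row, col, slice)` applied to the mask
#'   voxels before intersection with the grid.
#' @param label VOI label, conventionally `"TX"` (treated lesion) or
#'   `"CTRL"` (healthy control cartilage).
#' @param patient optional patient identifier.
#' @param value label value selected when `mask` is an integer label array.
#' @return A `voi` object: linear voxel indices `idx`, `n`, `n_valid`,
#'   `label`, `patient`, `shift`.
#' @export
load_voi <- function(mask, map, shift = c(0L, 0L, 0L), label = "VOI",
                     patient = NA_character_, value = NULL) {
  stopifnot(inherits(map, "t2map"))
  d <- dim(map$t2)
  if (!is.null(value)) mask <- mask == value
  if (!identical(dim(mask), d))
    stopf("mask grid %s does not match map grid %s",
          paste(dim(mask), collapse = "x"), paste(d, collapse = "x"))
  shift <- as.integer(round(shift))
  idx0 <- which(mask)
  if (length(idx0) == 0L) stopf("VOI '%s': mask is empty", label)
  pos <- arrayInd(idx0, d)
  pos <- sweep(pos, 2, shift, "+")
  keep <- pos[, 1] >= 1 & pos[, 1] <= d[1] &
          pos[, 2] >= 1 & pos[, 2] <= d[2] &
          pos[, 3] >= 1 & pos[, 3] <= d[3]
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) == 0L)
    stopf("VOI '%s': shift %s moves the mask entirely off-grid", label,
          paste(shift, collapse = ","))
  idx <- pos[, 1] + d[1] * (pos[, 2] - 1) + d[1] * d[2] * (pos[, 3] - 1)
  valid <- map$validity[idx] == VALID_OK
  if (!any(valid)) {
    bd <- colSums(map$flags[idx, , drop = FALSE])
    stopf("VOI '%s': no valid voxels (n = %d); exclusion flags: %s",
          label, length(idx),
          paste(sprintf("%s=%d", names(bd), bd), collapse = ", "))
  }
  structure(list(label = label, patient = patient, idx = idx,
                 n = length(idx), n_valid = sum(valid), shift = shift),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("VOI %s%s: %d voxels, %d valid\n", x$label,
              if (is.na(x$patient)) "" else paste0(" (", x$patient, ")"),
              x$n, x$n_valid))
  invisible(x)
}

voi_values <- function(voi, map) {
  v <- map$t2[voi$idx]
  v[!is.na(v)]
}

#' Quartile-based tissue thresholds
#'
#' @param ta,tb first and third quartile of pooled control-cartilage T2
#'   (msec); tissue classes are fibrocartilage (`T2 < ta`), hyaline-like
#'   (`ta <= T2 <= tb`) and remodeling (`T2 > tb`).
#' @return A `tissue_thresholds` object.
#' @export
tissue_thresholds <- function(ta, tb) {
  if (!(ta > 0 && tb >= ta)) stopf("need 0 < ta <= tb")
  structure(list(ta = ta, tb = tb), class = "tissue_thresholds")
}

#' @export
print.tissue_thresholds <- function(x, ...) {
  cat(sprintf("Tissue thresholds: Ta = %g msec, Tb = %g msec\n", x$ta, x$tb))
  invisible(x)
}

#' Derive tissue thresholds from pooled control T2 values
#'
#' The first and third quartiles of the T2 values pooled over all control
#' VOIs become the lower and upper bound of the hyaline-like class. The
#' quartiles use the inverse-empirical-CDF convention (an observed order
#' statistic, `quantile` type 1), so thresholds are attained data values; by
#' default they are additionally rounded to the nearest integer msec,
#' matching reporting practice for the thresholds.
#'
#' @param values pooled valid-voxel T2 values (numeric), a `t2_distribution`,
#'   or a list of either.
#' @param round round thresholds to integer msec (default `TRUE`).
#' @return A [tissue_thresholds()] object.
#' @examples
#' pooled_quartiles(1:100)   # Ta = 25, Tb = 75
#' @export
pooled_quartiles <- function(values, round = TRUE) {
  pool <- pool_t2_values(values)
  if (length(pool) < 4) stopf("need at least 4 pooled T2 values")
  q <- quantile(pool, c(0.25, 0.75), names = FALSE, type = 1)
  if (round) q <- round(q)
  tissue_thresholds(q[1], q[2])
}

pool_t2_values <- function(values) {
  if (inherits(values, "t2_distribution")) return(values$values)
  if (is.list(values)) return(unlist(lapply(values, pool_t2_values)))
  as.numeric(values)
}

#' T2 distribution of a VOI
#'
#' Histogram of valid-voxel T2 values on 1-msec bins over the 5-100 msec
#' articular window, plus a normalized frequency curve obtained with a
#' 10-msec (10-bin) moving-average filter; windows are truncated at the
#' edges and the curve is renormalized to unit area so VOIs of different
#' sizes are comparable.
#'
#' @param x a [load_voi()] object (with `map`), or a numeric vector of T2
#'   values.
#' @param map the [t2map()] the VOI indexes into (when `x` is a `voi`).
#' @param window moving-average window in msec (bins).
#' @param range histogram range in msec.
#' @return A `t2_distribution`: raw `values`, bin `mids`, `counts`,
#'   `smoothed` (sums to 1 over 1-msec bins).
#' @export
t2_distribution <- function(x, map = NULL, window = 10L, range = c(5, 100)) {
  values <- if (inherits(x, "voi")) {
    if (is.null(map)) stopf("supply `map` with a voi")
    voi_values(x, map)
  } else as.numeric(x)
  if (length(values) == 0L) stopf("no valid T2 values in VOI")
  breaks <- seq(range[1], range[2], by = 1)
  h <- hist(plot = FALSE, x = pmin(pmax(values, range[1]), range[2] - 1e-9),
            breaks = breaks, right = FALSE, include.lowest = TRUE)
  counts <- h$counts
  nb <- length(counts)
  half_lo <- as.integer(floor((window - 1) / 2))
  half_hi <- as.integer(window) - half_lo - 1L
  csum <- cumsum(c(0, counts))
  i <- seq_len(nb)
  lo <- pmax(i - half_lo, 1L); hi <- pmin(i + half_hi, nb)
  sm <- (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
  sm <- sm / sum(sm)
  structure(list(values = values, mids = h$mids, counts = counts,
                 smoothed = sm, window = window, range = range),
            class = "t2_distribution")
}

#' @export
print.t2_distribution <- function(x, ...) {
  cat(sprintf("T2 distribution: %d values, median %.1f msec (%d-msec moving average)\n",
              length(x$values), median(x$values), x$window))
  invisible(x)
}

#' @export
plot.t2_distribution <- function(x, type = c("smoothed", "histogram"), ...) {
  type <- match.arg(type)
  if (type == "histogram")
    plot(x$mids, x$counts, type = "h", xlab = "T2 (msec)", ylab = "voxels", ...)
  else
    plot(x$mids, x$smoothed, type = "l", xlab = "T2 (msec)",
         ylab = "normalized frequency", ...)
  invisible(x)
}

#' Tissue composition of a VOI
#'
#' Classifies each valid voxel by its T2 against the thresholds and reports
#' the fractions of fibrocartilage (`T2 < Ta`), hyaline-like tissue
#' (`Ta <= T2 <= Tb`, boundaries inclusive) and tissue under remodeling
#' (`T2 > Tb`), together with the tissue volume `n_valid * voxel_volume`.
#'
#' @param x a `voi` (with `map`) or a numeric vector of T2 values.
#' @param map the [t2map()] the VOI indexes into.
#' @param thr a [tissue_thresholds()].
#' @param voxel_volume voxel volume in mm^3; taken from the map geometry
#'   when available.
#' @return A `tissue_composition`: `frac_fibro`, `frac_hyaline`,
#'   `frac_remodel` (sum to 1), `n_valid`, `voxel_volume`, `tissue_volume`.
#' @examples
#' composition(c(20, 35, 50), thr = tissue_thresholds(25, 45))
#' @export
composition <- function(x, map = NULL, thr, voxel_volume = NULL) {
  stopifnot(inherits(thr, "tissue_thresholds"))
  values <- if (inherits(x, "voi")) {
    if (is.null(map)) stopf("supply `map` with a voi")
    voi_values(x, map)
  } else as.numeric(x)
  n <- length(values)
  if (n == 0L) stopf("no valid voxels to classify")
  if (is.null(voxel_volume))
    voxel_volume <- if (!is.null(map)) map$spacing^2 * map$thickness else NA_real_
  fib <- sum(values < thr$ta)
  hya <- sum(values >= thr$ta & values <= thr$tb)
  rem <- sum(values > thr$tb)
  structure(list(frac_fibro = fib / n, frac_hyaline = hya / n,
                 frac_remodel = rem / n, n_valid = n,
                 voxel_volume = voxel_volume,
                 tissue_volume = n * voxel_volume,
                 thresholds = thr),
            class = "tissue_composition")
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat(sprintf("Tissue composition (n = %d, %.0f mm^3):\n", x$n_valid,
              x$tissue_volume))
  cat(sprintf("  fibrocartilage  (T2 < %g):        %.1f%%\n", x$thresholds$ta,
              100 * x$frac_fibro))
  cat(sprintf("  hyaline-like    (%g <= T2 <= %g): %.1f%%\n", x$thresholds$ta,
              x$thresholds$tb, 100 * x$frac_hyaline))
  cat(sprintf("  remodeling      (T2 > %g):        %.1f%%\n", x$thresholds$tb,
              100 * x$frac_remodel))
  invisible(x)
}
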