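#' Write a multi-echo series to NIfTI with a JSON sidecar
#'
#' The series is stored as one 4-D NIfTI volume (row, col, slice, echo) and a
#' JSON sidecar carrying the echo times (msec), voxel geometry and any seed,
#' which is the authoritative source of acquisition metadata on read.
#'
#' @param series an [echo_series()].
#' @param prefix output path without extension; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @param seed optional generation seed recorded in the sidecar.
#' @return The NIfTI path, invisibly.
#' @export
write_echo_series <- function(series, prefix, seed = NULL) {
  stopifnot(inherits(series, "echo_series"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(series$data, datatype = "double",
                         pixdim = c(series$spacing, series$spacing,
                                    series$thickness, 1))
  RNifti::writeNifti(img, nii)
  side <- list(echo_times = series$te, te_units = "ms",
               pixel_spacing_mm = series$spacing,
               slice_thickness_mm = series$thickness)
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(nii)
}

#' Read a multi-echo series
#'
#' Accepts a 4-D NIfTI with a JSON sidecar (same path, `.json` extension), or
#' a character vector of per-echo 3-D NIfTI files with `te` given explicitly.
#' Echoes are returned sorted by ascending echo time and TE is normalised to
#' msec (`te_units = "s"` in the sidecar is converted).
#'
#' @param path NIfTI path (or vector of per-echo paths).
#' @param te echo times in msec, overriding/absent-from the sidecar.
#' @param spacing,thickness geometry overrides in mm.
#' @return An [echo_series()].
#' @export
read_echo_series <- function(path, te = NULL, spacing = NULL,
                             thickness = NULL) {
  if (length(path) > 1L) {
    vols <- lapply(path, function(f) {
      v <- plain_array(RNifti::readNifti(f))
      if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)  # single-slice echo
      v
    })
    d <- dim(vols[[1]])
    if (length(d) != 3L) stopf("per-echo volumes must be 3-D")
    for (v in vols) if (!identical(dim(v), d))
      stopf("per-echo volumes have inconsistent grids")
    dat <- array(unlist(vols), dim = c(d, length(vols)))
    if (is.null(te)) stopf("supply `te` with per-echo files")
  } else {
    dat <- plain_array(RNifti::readNifti(path))
    if (length(dim(dat)) == 3L) dat <- array(dat, dim = c(dim(dat), 1L))
    side_path <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (file.exists(side_path)) {
      side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
      if (is.null(te)) {
        te <- side$echo_times
        if (identical(side$te_units, "s")) te <- te * 1000
      }
      if (is.null(spacing)) spacing <- side$pixel_spacing_mm
      if (is.null(thickness)) thickness <- side$slice_thickness_mm
    }
  }
  if (is.null(te))
    stopf("echo times unavailable: no sidecar and no `te` argument")
  if (length(te) != dim(dat)[4])
    stopf("%d echo times for %d echo volumes", length(te), dim(dat)[4])
  ord <- order(te)
  if (any(ord != seq_along(te))) {
    dat <- dat[, , , ord, drop = FALSE]
    te <- te[ord]
  }
  echo_series(dat, te, spacing %||% 0.664, thickness %||% 2)
}

# strip NIfTI attributes down to a plain R array
plain_array <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim = dim(a))
}

#' Read or write an integer-label VOI mask
#'
#' Label conventions: 1 = TX (treated lesion), 2 = CTRL (control cartilage).
#'
#' @param mask integer or logical array.
#' @param path NIfTI path.
#' @return `read_mask`: an integer array; `write_mask`: `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                                     datatype = "int16"), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  arr <- plain_array(RNifti::readNifti(path))
  array(as.integer(round(arr)), dim = dim(arr))
}

#' Write a fitted T2 map
#'
#' Writes the T2 volume (float msec, invalid voxels `NaN`), the integer
#' validity-class volume and a JSON report with the noise estimate, exclusion
#' flag counts and the thresholds applied.
#'
#' @param map a [t2map()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_t2map <- function(map, dir) {
  stopifnot(inherits(map, "t2map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t2 <- map$t2; t2[is.na(t2)] <- NaN
  RNifti::writeNifti(RNifti::asNifti(t2, pixdim = c(map$spacing, map$spacing,
                                                    map$thickness)),
                     file.path(dir, "t2map.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$validity, datatype = "int16"),
                     file.path(dir, "validity.nii.gz"))
  rep <- list(sigma_rice = map$sigma, echo_times = map$te,
              weights_mode = map$weights_mode,
              thresholds = map$thresholds,
              flag_counts = as.list(map$flag_counts),
              n_valid = sum(map$validity == VALID_OK),
              n_voxels = length(map$validity))
  jsonlite::write_json(rep, file.path(dir, "t2map_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
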