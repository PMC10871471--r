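#' Write an offset stack as NIfTI plus an offset sidecar CSV
#'
#' Single-slice data are stored with a degenerate third dimension; the
#' offset axis is the fourth NIfTI dimension. The sidecar has the header
#' `frame,offset_ppm`.
#'
#' @param stack An [offset_stack()].
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param sidecar Sidecar CSV path; defaults to `path` with a
#'   `_offsets.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_offset_stack <- function(stack, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  d <- dim(stack$frames)
  arr <- array(stack$frames, dim = c(d[1], d[2], 1L, d[3]))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  utils::write.csv(data.frame(frame = seq_len(d[3]),
                              offset_ppm = stack$offsets),
                   sidecar, row.names = FALSE)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "_offsets.csv", path)
}

#' Read an offset stack from NIfTI plus its offset sidecar
#'
#' Frames are reordered so offsets come out ascending. A mismatch between
#' the frame count and the sidecar row count is an error naming both.
#'
#' @param path NIfTI file.
#' @param sidecar Sidecar CSV (`frame,offset_ppm`); defaults to the path
#'   [write_offset_stack()] uses.
#' @param scheme Optional [saturation_scheme()] to attach.
#' @return An [offset_stack()].
#' @export
read_offset_stack <- function(path, sidecar = NULL, scheme = NULL) {
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L) arr <- array(arr, dim = c(d[1], d[2], d[4]))
  if (length(dim(arr)) != 3L)
    stop("expected a 4D single-slice NIfTI stack", call. = FALSE)
  sc <- utils::read.csv(sidecar)
  if (nrow(sc) != dim(arr)[3])
    stop(sprintf("sidecar lists %d offsets but file has %d frames",
                 nrow(sc), dim(arr)[3]), call. = FALSE)
  offset_stack(arr, sc$offset_ppm, scheme)
}

#' Write a float map (e.g. B0, kappa, contrast) as single-slice NIfTI
#' @param map Numeric matrix (`NA` allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  arr <- array(map, dim = c(dim(map), 1L))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write a subject manifest CSV
#' @param manifest data.frame with subject_id, group, age, sex, seed.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(manifest[, c("subject_id", "group", "age", "sex", "seed")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a GluCEST map as NIfTI with a JSON meta sidecar
#'
#' The percent map goes to `path` (invalid voxels as `NA`) and the map's
#' provenance metadata (correction settings, calibration span, voxel
#' counts) to `path` with a `_meta.json` suffix.
#'
#' @param map A `glucest_map`.
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_glucest_map <- function(map, path) {
  stopifnot(inherits(map, "glucest_map"))
  write_map_nifti(map$percent, path)
  meta <- c(map$meta, list(n_valid = sum(map$valid),
                           n_invalid = sum(!map$valid)))
  jsonlite::write_json(meta, sub("\\.nii(\\.gz)?$", "_meta.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}
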