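#' Regional summaries of a GluCEST map
#'
#' Means and SDs of the valid-voxel contrast over the whole brain, gray and
#' white matter, and the seven cortical regions. Gray matter includes the
#' cortical patches. Regions with no valid voxels are flagged `missing`
#' (mean/sd are `NA`, never zero); regions with fewer than `min_voxels`
#' valid voxels are flagged `low_confidence`.
#'
#' @param map A [compute_glucest()] / [correct_b1()] map.
#' @param labels Integer label matrix (0 background, 1 gray matter, 2 white
#'   matter, 3-9 cortical regions).
#' @param min_voxels Low-confidence threshold.
#' @return data.frame with columns `region`, `mean_percent`, `sd_percent`,
#'   `n_voxels`, `missing`, `low_confidence`.
#' @export
regional_means <- function(map, labels, min_voxels = 10) {
  stopifnot(inherits(map, "glucest_map"))
  if (!all(dim(labels) == dim(map$percent)))
    stop("label map shape does not match contrast map", call. = FALSE)
  codes <- region_label_codes()
  sel <- list(
    WholeBrain = labels > 0L,
    GM = labels == 1L | labels >= 3L,
    WM = labels == 2L
  )
  for (nm in names(codes)) sel[[nm]] <- labels == codes[[nm]]

  rows <- lapply(region_names(), function(r) {
    use <- sel[[r]] & map$valid
    n <- sum(use)
    v <- map$percent[use]
    data.frame(region = r,
               mean_percent = if (n > 0) mean(v) else NA_real_,
               sd_percent = if (n > 1) stats::sd(v) else if (n == 1) 0 else NA_real_,
               n_voxels = n,
               missing = n == 0L,
               low_confidence = n < min_voxels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalized gray- and white-matter volumes
#'
#' Tissue voxel counts normalized to total brain voxel count (single-slice
#' data with uniform voxel size, so counts are proportional to volume).
#' Gray matter includes the cortical patches.
#'
#' @param labels Integer label matrix.
#' @return Named numeric vector `c(gm_fraction, wm_fraction)`.
#' @export
normalized_volumes <- function(labels) {
  brain <- sum(labels > 0L)
  if (brain == 0L) stop("empty brain: no nonzero labels", call. = FALSE)
  c(gm_fraction = sum(labels == 1L | labels >= 3L) / brain,
    wm_fraction = sum(labels == 2L) / brain)
}
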