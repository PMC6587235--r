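#' Compute the voxelwise fat-fraction map
#'
#' Fat fraction is the percentage of the total fat-plus-water signal
#' carried by the fat channel, `100 * fat / (fat + water)`, evaluated per
#' voxel.  Voxels with zero total signal have no defined fraction and are
#' marked `NA`; downstream summaries exclude (and count) them rather than
#' imputing 0% or 100%, either of which would bias regional means.
#'
#' @param vol a [fat_water_volume()].
#' @return A [fat_fraction_map()] on the same grid.
#' @examples
#' g <- vol_geometry(c(1, 1), 1, 1)
#' v <- fat_water_volume(array(c(50, 0, 7), c(1, 3, 1)),
#'                       array(c(50, 7, 0), c(1, 3, 1)), g)
#' compute_fat_fraction(v)$ff   # 50, 0, 100
#' @export
compute_fat_fraction <- function(vol) {
  stopifnot(inherits(vol, "fat_water_volume"))
  total <- vol$fat + vol$water
  ff <- array(NA_real_, dim = dim(vol$fat))
  ok <- total > 0
  ff[ok] <- 100 * vol$fat[ok] / total[ok]
  fat_fraction_map(ff, vol$geometry)
}

#' Whole-muscle mean fat fraction
#'
#' The image-wise (default) estimator averages each slice's in-muscle mean
#' and then averages across the slices that contain the muscle, i.e. every
#' image contributes equally regardless of cross-sectional area.  The
#' voxel-weighted estimator averages all labelled voxels directly and is
#' the self-consistent 3D mean.  Masked voxels with undefined fat fraction
#' are excluded from either average with a warning reporting their count.
#'
#' @param map a [fat_fraction_map()].
#' @param mask a [label_mask()] on the same grid.
#' @param label integer label or muscle name.
#' @param weighting `"slice_mean"` (default) or `"voxel"`.
#' @return Mean percent fat (scalar), with attribute `n_undefined_excluded`.
#' @export
muscle_mean_fat <- function(map, mask, label,
                            weighting = c("slice_mean", "voxel")) {
  weighting <- match.arg(weighting)
  lab <- resolve_label(mask, label)
  sel <- mask$labels == lab
  if (!any(sel)) {
    stop(sprintf("label %s is empty in this mask", label), call. = FALSE)
  }
  ff <- map$ff
  undef <- sel & is.na(ff)
  n_undef <- sum(undef)
  if (n_undef > 0) {
    warning(sprintf(
      "label %s: %d masked voxel(s) have undefined fat fraction; excluded",
      label, n_undef), call. = FALSE)
    sel <- sel & !is.na(ff)
    if (!any(sel)) {
      stop(sprintf("label %s has no voxels with defined fat fraction", label),
           call. = FALSE)
    }
  }
  value <- if (weighting == "voxel") {
    mean(ff[sel])
  } else {
    slice_has <- apply(sel, 3, any)
    per_slice <- vapply(which(slice_has), function(s) {
      m <- sel[, , s]
      mean(ff[, , s][m])
    }, numeric(1))
    mean(per_slice)
  }
  structure(value, n_undefined_excluded = n_undef)
}

#' Muscle volume from a label mask
#'
#' Sums per-slice cross-sectional areas (labelled voxel count times pixel
#' area) over slices and multiplies by the slice thickness, reported in
#' cubic centimetres.
#'
#' @inheritParams muscle_mean_fat
#' @return Volume in cm^3.
#' @examples
#' g <- vol_geometry(c(1.2, 1.2), 2.0, 1)
#' m <- label_mask(array(rep(1L, 1000), c(10, 100, 1)), geometry = g)
#' muscle_volume(m, 1)   # 1000 voxels x 2.88 mm^3 = 2.88 cm^3
#' @export
muscle_volume <- function(mask, label) {
  lab <- resolve_label(mask, label)
  n <- sum(mask$labels == lab)
  if (n == 0) {
    stop(sprintf("label %s is empty in this mask", label), call. = FALSE)
  }
  n * voxel_volume_mm3(mask$geometry) / 1000
}

#' Per-muscle summary of fat fraction and volume
#'
#' One row per muscle present in the mask, with both whole-muscle
#' fat-fraction estimators, volume, voxel and slice counts, and the number
#' of zero-signal voxels excluded from the means.
#'
#' @param map a [fat_fraction_map()].
#' @param mask a [label_mask()] on the same grid.
#' @param labels labels to summarise; defaults to every non-background
#'   label present.
#' @return A data frame of class `muscle_summary`.
#' @export
muscle_summary <- function(map, mask, labels = NULL) {
  present <- setdiff(sort(unique(as.vector(mask$labels))), 0L)
  if (is.null(labels)) labels <- present
  rows <- lapply(labels, function(lab) {
    lab <- resolve_label(mask, lab)
    sel <- mask$labels == lab
    ms <- suppressWarnings(muscle_mean_fat(map, mask, lab, "slice_mean"))
    mv <- suppressWarnings(muscle_mean_fat(map, mask, lab, "voxel"))
    data.frame(
      label = label_display_name(mask, lab),
      mean_fat_pct_slice = as.numeric(ms),
      mean_fat_pct_voxel = as.numeric(mv),
      volume_cm3 = muscle_volume(mask, lab),
      n_voxels = sum(sel),
      n_slices = sum(apply(sel, 3, any)),
      n_undefined_excluded = attr(ms, "n_undefined_excluded"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("muscle_summary", "data.frame")
  out
}
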