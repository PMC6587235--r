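#' Partition a muscle into superior-inferior quartile bands
#'
#' Divides the muscle cross-section into four bands from superior (Q1) to
#' inferior (Q4).  By default each slice is banded from its own occupied
#' row extent, because a muscle's cross-section shifts superiorly and
#' inferiorly across sagittal slices; `extent = "global"` uses the single
#' 3D row extent instead.  With occupied rows `r_min..r_max` and band
#' height `h = (r_max - r_min + 1)/4`, the voxel at row `r` falls in band
#' `min(4, floor((r - r_min)/h) + 1)` — deterministic, exhaustive, and
#' independent of iteration order.  Band row-counts within a slice differ
#' by at most one.
#'
#' @param mask a [label_mask()].
#' @param label integer label or muscle name.
#' @param extent `"slice"` (per-slice row extent, default) or `"global"`.
#' @return A `region_partition`: an integer array matching the mask (0
#'   outside the muscle) with attributes `scheme`, `label`, `region_names`.
#' @export
partition_quartiles <- function(mask, label, extent = c("slice", "global")) {
  extent <- match.arg(extent)
  lab <- resolve_label(mask, label)
  sel <- mask$labels == lab
  if (!any(sel)) {
    stop(sprintf("label %s is empty in this mask", label), call. = FALSE)
  }
  part <- array(0L, dim = dim(mask$labels))
  idx <- which(sel, arr.ind = TRUE)
  if (extent == "global") {
    r_min <- min(idx[, 1]); r_max <- max(idx[, 1])
    h <- (r_max - r_min + 1) / 4
    part[sel] <- pmin(4L, as.integer(floor((idx[, 1] - r_min) / h)) + 1L)
  } else {
    for (s in unique(idx[, 3])) {
      in_s <- idx[, 3] == s
      rows <- idx[in_s, 1]
      r_min <- min(rows); r_max <- max(rows)
      h <- (r_max - r_min + 1) / 4
      q <- pmin(4L, as.integer(floor((rows - r_min) / h)) + 1L)
      part[idx[in_s, , drop = FALSE]] <- q
    }
  }
  new_region_partition(part, "quartile_SI", label_display_name(mask, lab),
                       c("Q1", "Q2", "Q3", "Q4"))
}

#' Partition a muscle into lateral/intermediate/medial slice tertiles
#'
#' Splits the contiguous span of slices the muscle occupies — which
#' operationalises "from the glenoid to the medial scapular border", since
#' segmentation is bounded by those landmarks — into three contiguous
#' slice groups of near-equal size.  With `n` occupied-span slices the
#' groups get `floor(n/3)` slices each and the `n mod 3` remainder slices
#' are handed out one per group, lateral-first by default.
#'
#' @param mask a [label_mask()].
#' @param label integer label or muscle name.
#' @param remainder which groups receive the extra slices first:
#'   `"lateral"` (default), `"medial"`, or `"intermediate"`.
#' @return A `region_partition` with regions lateral/intermediate/medial
#'   coded 1/2/3.
#' @export
partition_tertiles <- function(mask, label,
                               remainder = c("lateral", "medial",
                                             "intermediate")) {
  remainder <- match.arg(remainder)
  lab <- resolve_label(mask, label)
  sel <- mask$labels == lab
  if (!any(sel)) {
    stop(sprintf("label %s is empty in this mask", label), call. = FALSE)
  }
  occ <- which(apply(sel, 3, any))
  L <- min(occ); M <- max(occ)
  n <- M - L + 1L
  if (n < 3L) {
    stop(sprintf("label %s spans only %d slice(s); tertiles need at least 3",
                 label, n), call. = FALSE)
  }
  sizes <- rep(n %/% 3L, 3)                 # lateral, intermediate, medial
  names(sizes) <- c("lateral", "intermediate", "medial")
  extra_order <- switch(remainder,
    lateral = c("lateral", "intermediate", "medial"),
    medial = c("medial", "intermediate", "lateral"),
    intermediate = c("intermediate", "lateral", "medial"))
  r <- n %% 3L
  if (r > 0) sizes[extra_order[seq_len(r)]] <- sizes[extra_order[seq_len(r)]] + 1L
  bounds <- L + cumsum(c(0L, unname(sizes)))   # group g covers [bounds[g], bounds[g+1])
  slice_group <- integer(dim(sel)[3])
  for (g in 1:3) {
    slice_group[seq.int(bounds[g], bounds[g + 1] - 1L)] <- g
  }
  part <- array(0L, dim = dim(mask$labels))
  idx <- which(sel, arr.ind = TRUE)
  part[sel] <- slice_group[idx[, 3]]
  new_region_partition(part, "tertile_ML", label_display_name(mask, lab),
                       c("lateral", "intermediate", "medial"))
}

new_region_partition <- function(part, scheme, label, region_names) {
  structure(part, scheme = scheme, label = label,
            region_names = region_names,
            class = c("region_partition", "array"))
}

#' @export
print.region_partition <- function(x, ...) {
  counts <- tabulate(x[x > 0L], nbins = length(attr(x, "region_names")))
  cat(sprintf("Region partition (%s) of %s: %s\n",
              attr(x, "scheme"), attr(x, "label"),
              paste(sprintf("%s=%d", attr(x, "region_names"), counts),
                    collapse = ", ")))
  invisible(x)
}

#' Regional fat fraction and volume
#'
#' Applies the whole-muscle estimators restricted to each region of a
#' partition: slice-mean and voxel-weighted percent fat, volume from voxel
#' counts, and voxel/slice counts.  Regions whose voxels all have
#' undefined fat fraction are reported with `NA` means and a warning.
#'
#' @param map a [fat_fraction_map()].
#' @param mask a [label_mask()] the partition was built from.
#' @param partition a `region_partition` from [partition_quartiles()] or
#'   [partition_tertiles()].
#' @return A data frame with one row per region: `label`, `scheme`,
#'   `region`, `mean_fat_pct_slice`, `mean_fat_pct_voxel`, `volume_cm3`,
#'   `n_voxels`, `n_slices`, `n_undefined_excluded`.
#' @export
regional_stats <- function(map, mask, partition) {
  stopifnot(inherits(partition, "region_partition"))
  region_names <- attr(partition, "region_names")
  ff <- map$ff
  vox_mm3 <- voxel_volume_mm3(mask$geometry)
  rows <- lapply(seq_along(region_names), function(g) {
    sel <- unclass(partition) == g
    n_vox <- sum(sel)
    def <- sel & !is.na(ff)
    n_undef <- n_vox - sum(def)
    if (n_vox > 0 && sum(def) == 0) {
      warning(sprintf("region %s of %s has no defined fat-fraction voxels",
                      region_names[g], attr(partition, "label")),
              call. = FALSE)
      mfs <- NA_real_; mfv <- NA_real_
    } else if (n_vox == 0) {
      mfs <- NA_real_; mfv <- NA_real_
    } else {
      if (n_undef > 0) {
        warning(sprintf(
          "region %s of %s: %d voxel(s) with undefined fat fraction excluded",
          region_names[g], attr(partition, "label"), n_undef), call. = FALSE)
      }
      mfv <- mean(ff[def])
      slice_has <- apply(def, 3, any)
      per_slice <- vapply(which(slice_has), function(s) {
        m <- def[, , s]
        mean(ff[, , s][m])
      }, numeric(1))
      mfs <- mean(per_slice)
    }
    data.frame(
      label = attr(partition, "label"),
      scheme = attr(partition, "scheme"),
      region = region_names[g],
      mean_fat_pct_slice = mfs,
      mean_fat_pct_voxel = mfv,
      volume_cm3 = n_vox * vox_mm3 / 1000,
      n_voxels = n_vox,
      n_slices = sum(apply(sel, 3, any)),
      n_undefined_excluded = n_undef,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
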