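#' Paired fat/water intensity volumes
#'
#' The raw measurement this package consumes: two co-registered 3D magnitude
#' images from a fat-water (Dixon-type) reconstruction, on the same grid.
#'
#' @param fat,water 3D numeric arrays of non-negative, finite intensities
#'   with identical dimensions, in canonical `(row, col, slice)` order.
#' @param geometry a [vol_geometry()] matching the arrays.
#' @return An object of class `fat_water_volume`.
#' @export
fat_water_volume <- function(fat, water, geometry) {
  fat <- as_num_array3(fat, "fat")
  water <- as_num_array3(water, "water")
  if (!identical(dim(fat), dim(water))) {
    stop(sprintf("fat (%s) and water (%s) volumes have different shapes",
                 paste(dim(fat), collapse = "x"),
                 paste(dim(water), collapse = "x")), call. = FALSE)
  }
  check_array_geometry(fat, geometry, "fat volume")
  if (any(!is.finite(fat)) || any(!is.finite(water))) {
    stop("fat/water intensities must be finite", call. = FALSE)
  }
  if (any(fat < 0) || any(water < 0)) {
    stop("fat/water intensities must be non-negative", call. = FALSE)
  }
  structure(list(fat = fat, water = water, geometry = geometry),
            class = "fat_water_volume")
}

#' @export
print.fat_water_volume <- function(x, ...) {
  d <- dim(x$fat)
  cat(sprintf("Fat-water volume %d x %d x %d\n", d[1], d[2], d[3]))
  print(x$geometry)
  invisible(x)
}

#' Multi-label muscle segmentation mask
#'
#' A voxel labelling of muscle regions of interest (filled ROIs, not
#' contours) aligned to a fat-water grid.  Label 0 is background.
#'
#' @param labels 3D integer array; 0 = background.
#' @param label_names named character vector mapping label values (as names)
#'   to muscle names.  Defaults to the three rotator cuff ROIs:
#'   1 = supraspinatus (SS), 2 = combined infraspinatus/teres minor (IS),
#'   3 = subscapularis (SC).
#' @param geometry a [vol_geometry()] matching the array.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels,
                       label_names = c(`1` = "SS", `2` = "IS", `3` = "SC"),
                       geometry) {
  if (is.null(dim(labels)) || length(dim(labels)) != 3L) {
    stop("labels must be a 3D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  check_array_geometry(labels, geometry, "label mask")
  if (any(is.na(labels)) || any(labels < 0L)) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  unknown <- setdiff(present, as.integer(names(label_names)))
  if (length(unknown)) {
    stop(sprintf("mask contains labels not in the label map: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  structure(list(labels = labels, label_names = label_names,
                 geometry = geometry),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  present <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("Label mask %d x %d x %d; labels: %s\n", d[1], d[2], d[3],
              paste(sprintf("%d=%s", present,
                            x$label_names[as.character(present)]),
                    collapse = ", ")))
  invisible(x)
}

#' Voxelwise fat-fraction map
#'
#' Percent fat per voxel in \[0, 100\]; voxels where fat + water = 0 carry
#' `NA` (the fraction is undefined there).
#'
#' @param ff 3D numeric array of percent fat, `NA` where undefined.
#' @param geometry a [vol_geometry()] matching the array.
#' @return An object of class `fat_fraction_map`.
#' @export
fat_fraction_map <- function(ff, geometry) {
  ff <- as_num_array3(ff, "ff", allow_na = TRUE)
  check_array_geometry(ff, geometry, "fat-fraction map")
  defined <- ff[!is.na(ff)]
  if (length(defined) && (min(defined) < -1e-9 || max(defined) > 100 + 1e-9)) {
    stop("defined fat fractions must lie in [0, 100]", call. = FALSE)
  }
  structure(list(ff = ff, geometry = geometry), class = "fat_fraction_map")
}

#' @export
print.fat_fraction_map <- function(x, ...) {
  d <- dim(x$ff)
  nd <- sum(is.na(x$ff))
  cat(sprintf("Fat-fraction map %d x %d x %d (%d undefined voxels)\n",
              d[1], d[2], d[3], nd))
  invisible(x)
}

# label lookup: accept either the integer label or the muscle name
resolve_label <- function(mask, label) {
  if (is.character(label)) {
    hit <- names(mask$label_names)[mask$label_names == label]
    if (!length(hit)) {
      stop(sprintf("muscle '%s' not in the label map", label), call. = FALSE)
    }
    as.integer(hit[1])
  } else {
    as.integer(label)
  }
}

label_display_name <- function(mask, label_value) {
  nm <- mask$label_names[as.character(label_value)]
  if (is.na(nm)) as.character(label_value) else unname(nm)
}

as_num_array3 <- function(x, what, allow_na = FALSE) {
  if (is.null(dim(x)) || length(dim(x)) != 3L) {
    stop(sprintf("%s must be a 3D array", what), call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (!allow_na && any(is.na(x))) {
    stop(sprintf("%s must not contain NA", what), call. = FALSE)
  }
  x
}
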