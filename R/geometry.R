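#' Volume geometry
#'
#' Describes the physical grid of a scan volume in the package's canonical
#' axis convention: array axis 1 (rows) runs superior to inferior, axis 2
#' (columns) anterior to posterior, axis 3 (slices) lateral to medial.
#'
#' @param in_plane_spacing numeric length 2, physical pixel size
#'   `(row_mm, col_mm)` in millimetres.
#' @param slice_thickness slice thickness in millimetres.
#' @param n_slices number of slices in the volume.
#' @param axis_roles named character vector mapping array axes to anatomical
#'   roles; fixed to the canonical convention and stored for reporting.
#' @return An object of class `vol_geometry`.
#' @examples
#' vol_geometry(c(1.2, 1.2), 2.0, 24)
#' @export
vol_geometry <- function(in_plane_spacing = c(1.2, 1.2),
                         slice_thickness = 2.0,
                         n_slices,
                         axis_roles = c(row = "superior_to_inferior",
                                        col = "anterior_to_posterior",
                                        slice = "lateral_to_medial")) {
  in_plane_spacing <- as.numeric(in_plane_spacing)
  if (length(in_plane_spacing) != 2L || any(!is.finite(in_plane_spacing)) ||
      any(in_plane_spacing <= 0)) {
    stop("in_plane_spacing must be two strictly positive values (row_mm, col_mm)",
         call. = FALSE)
  }
  if (!is.finite(slice_thickness) || slice_thickness <= 0) {
    stop("slice_thickness must be strictly positive", call. = FALSE)
  }
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L) {
    stop("n_slices must be a positive integer", call. = FALSE)
  }
  if (!setequal(names(axis_roles), c("row", "col", "slice")) ||
      anyDuplicated(axis_roles)) {
    stop("axis_roles must be a bijection over the axes row, col, slice",
         call. = FALSE)
  }
  structure(
    list(in_plane_spacing = in_plane_spacing,
         slice_thickness = as.numeric(slice_thickness),
         n_slices = n_slices,
         axis_roles = axis_roles),
    class = "vol_geometry"
  )
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat(sprintf("Volume geometry: %.4g x %.4g mm in plane, %.4g mm slices, %d slices\n",
              x$in_plane_spacing[1], x$in_plane_spacing[2],
              x$slice_thickness, x$n_slices))
  invisible(x)
}

#' Voxel volume in mm^3 implied by a geometry
#' @param geometry a [vol_geometry()].
#' @return scalar voxel volume in cubic millimetres.
#' @export
voxel_volume_mm3 <- function(geometry) {
  stopifnot(inherits(geometry, "vol_geometry"))
  prod(geometry$in_plane_spacing) * geometry$slice_thickness
}

geometry_equal <- function(a, b, tol = 1e-9) {
  inherits(a, "vol_geometry") && inherits(b, "vol_geometry") &&
    all(abs(a$in_plane_spacing - b$in_plane_spacing) < tol) &&
    abs(a$slice_thickness - b$slice_thickness) < tol &&
    a$n_slices == b$n_slices
}

check_array_geometry <- function(arr, geometry, what = "volume") {
  d <- dim(arr)
  if (is.null(d) || length(d) != 3L) {
    stop(sprintf("%s must be a 3D array", what), call. = FALSE)
  }
  if (d[3] != geometry$n_slices) {
    stop(sprintf("%s has %d slices but geometry declares %d",
                 what, d[3], geometry$n_slices), call. = FALSE)
  }
  invisible(TRUE)
}
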