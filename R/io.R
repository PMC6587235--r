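#' Read a co-registered fat/water/mask triplet from NIfTI files
#'
#' Reads the two Dixon channel volumes and the muscle label mask, checks
#' that all three share one grid, and re-orients each to the package's
#' canonical `(row, col, slice)` order (superior-inferior, anterior-
#' posterior, lateral-medial).  When a file carries a valid qform/sform the
#' header orientation is used for the re-orientation; the imaged side
#' decides which patient direction is "lateral" (`config$axes$side`,
#' default `"right"`).  Headerless or unconventionally stored files can be
#' forced with an explicit `config$axes$order`/`flip` override.
#'
#' @param fat_path,water_path,mask_path paths to single-channel 3D NIfTI
#'   files (`.nii` or `.nii.gz`).
#' @param config optional configuration: a list, or path to a YAML file,
#'   with optional sections `labels` (mapping integer label to muscle name)
#'   and `axes` (`side: right|left`, or `order:` a permutation of
#'   `[row, col, slice]` naming the role of each stored axis plus `flip:` a
#'   subset of roles whose index direction must be reversed).
#' @return A list with elements `volume` (a [fat_water_volume()]) and
#'   `mask` (a [label_mask()]).
#' @export
read_volume_pair <- function(fat_path, water_path, mask_path, config = NULL) {
  config <- load_config(config)
  fat <- read_nifti_canonical(fat_path, config)
  water <- read_nifti_canonical(water_path, config)
  msk <- read_nifti_canonical(mask_path, config)

  if (!identical(dim(fat$array), dim(water$array)) ||
      !identical(dim(fat$array), dim(msk$array))) {
    stop(sprintf(
      "volumes are not on one grid: fat %s, water %s, mask %s",
      paste(dim(fat$array), collapse = "x"),
      paste(dim(water$array), collapse = "x"),
      paste(dim(msk$array), collapse = "x")), call. = FALSE)
  }
  if (!geometry_equal(fat$geometry, water$geometry) ||
      !geometry_equal(fat$geometry, msk$geometry)) {
    stop("volumes disagree on voxel spacing", call. = FALSE)
  }

  label_names <- config_label_names(config)
  list(
    volume = fat_water_volume(fat$array, water$array, fat$geometry),
    mask = label_mask(round_to_int(msk$array), label_names, msk$geometry)
  )
}

#' Write a volume or mask as NIfTI in canonical orientation
#'
#' Integer arrays (masks, partitions) are stored losslessly as `int32`;
#' floating-point arrays (fat-fraction maps) as `float64`.  The header
#' records the canonical anatomical orientation so [read_volume_pair()]
#' round-trips without re-permutation.
#'
#' @param array 3D array in canonical `(row, col, slice)` order.
#' @param geometry a [vol_geometry()] for the array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param side `"right"` or `"left"`: which patient side the lateral-to-
#'   medial slice axis points away from; sets the header orientation code.
#' @return `path`, invisibly.
#' @export
write_volume <- function(array, geometry, path, side = "right") {
  if (!inherits(geometry, "vol_geometry")) {
    stop("geometry must be a vol_geometry", call. = FALSE)
  }
  check_array_geometry(array, geometry, "array")
  if (any(!is.finite(array))) {
    stop("array must be finite; write fat-fraction maps with NA replaced first",
         call. = FALSE)
  }
  integral <- is.integer(array) || all(array == round(array))
  sp <- c(geometry$in_plane_spacing, geometry$slice_thickness)
  img <- RNifti::asNifti(array)
  RNifti::pixdim(img) <- sp
  aff <- canonical_affine(sp, side)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (integral) "int32" else "double")
  invisible(path)
}

# Affine whose orientation code is IPL (right side) / IPR (left):
# row axis increases toward Inferior, col toward Posterior, slice toward
# the medial direction (patient Left for a right shoulder).
canonical_affine <- function(spacing, side = "right") {
  side <- match.arg(side, c("right", "left"))
  aff <- matrix(0, 4, 4)
  aff[3, 1] <- -spacing[1]
  aff[2, 2] <- -spacing[2]
  aff[1, 3] <- if (side == "right") -spacing[3] else spacing[3]
  aff[4, 4] <- 1
  aff
}

read_nifti_canonical <- function(path, config = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("%s: expected a single-channel 3D volume, got %d dims",
                 path, length(d)), call. = FALSE)
  }

  axes <- config$axes
  if (!is.null(axes$order)) {
    img <- apply_axis_override(img, axes)
  } else {
    code <- tryCatch(attr(RNifti::xform(img), "code"), error = function(e) 0L)
    if (!is.null(code) && length(code) && code > 0L) {
      side <- if (is.null(axes$side)) "right" else
        match.arg(axes$side, c("right", "left"))
      target <- if (side == "right") "IPL" else "IPR"
      RNifti::orientation(img) <- target
    } else {
      warning(sprintf(
        "%s: no valid qform/sform; assuming canonical (row,col,slice) layout",
        path), call. = FALSE)
    }
  }

  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop(sprintf("%s: header voxel spacing missing or non-positive", path),
         call. = FALSE)
  }
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img))
  geometry <- vol_geometry(in_plane_spacing = sp[1:2], slice_thickness = sp[3],
                           n_slices = dim(arr)[3])
  list(array = arr, geometry = geometry)
}

# Manual axis override: `order` names the anatomical role of each STORED
# axis; `flip` lists roles whose stored index runs opposite to canonical.
apply_axis_override <- function(img, axes) {
  roles <- c("row", "col", "slice")
  ord <- as.character(axes$order)
  if (!setequal(ord, roles) || length(ord) != 3L) {
    stop("axes$order must be a permutation of row, col, slice", call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  perm <- match(roles, ord)       # stored axis feeding each canonical axis
  arr <- aperm(arr, perm)
  sp <- sp[perm]
  for (role in as.character(axes$flip %||% character())) {
    ax <- match(role, roles)
    if (is.na(ax)) stop(sprintf("unknown axis role in flip: %s", role),
                        call. = FALSE)
    idx <- rev(seq_len(dim(arr)[ax]))
    arr <- switch(ax, arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
  }
  out <- RNifti::asNifti(arr)
  RNifti::pixdim(out) <- sp
  out
}

#' Load a pipeline configuration
#'
#' @param config `NULL`, a list already in config form, or a path to a YAML
#'   file with optional `labels:` and `axes:` sections.
#' @return A (possibly empty) configuration list.
#' @export
load_config <- function(config = NULL) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  config
}

config_label_names <- function(config) {
  if (is.null(config$labels)) {
    c(`1` = "SS", `2` = "IS", `3` = "SC")
  } else {
    stats::setNames(as.character(unlist(config$labels)),
                    names(config$labels))
  }
}

round_to_int <- function(arr) {
  out <- round(arr)
  if (max(abs(arr - out)) > 1e-6) {
    stop("mask volume contains non-integer values", call. = FALSE)
  }
  storage.mode(out) <- "integer"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
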