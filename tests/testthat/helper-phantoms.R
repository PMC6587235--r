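# Small hand-built masks and volumes for unit tests.

toy_geometry <- function(dims, spacing = c(1, 1), thick = 1) {
  vol_geometry(spacing, thick, dims[3])
}

# mask with a single label occupying explicit (row, col, slice) index sets
box_mask <- function(dims, rows, cols, slices, label = 1L,
                     spacing = c(1, 1), thick = 1) {
  arr <- array(0L, dim = dims)
  arr[rows, cols, slices] <- label
  label_mask(arr, stats::setNames("M", as.character(label)),
             toy_geometry(dims, spacing, thick))
}

# fat-fraction map holding an arbitrary field
map_from_field <- function(field, geometry) {
  fat_fraction_map(field, geometry)
}

# random cuboid mask: one label, random contiguous extents per axis
random_box_mask <- function(dims = c(24, 24, 12), min_len = c(4, 4, 3),
                            label = 1L) {
  pick <- function(n, mn) {
    len <- sample(mn:n, 1)
    start <- sample(seq_len(n - len + 1), 1)
    seq.int(start, start + len - 1)
  }
  box_mask(dims, pick(dims[1], min_len[1]), pick(dims[2], min_len[2]),
           pick(dims[3], min_len[3]), label = label)
}

# random blobby mask built from a phantom-style ellipse stack
random_ellipse_mask <- function(dims = c(32, 32, 14)) {
  sl <- sort(sample(seq_len(dims[3]), 2))
  while (sl[2] - sl[1] < 3) sl <- sort(sample(seq_len(dims[3]), 2))
  m <- phantom_muscle(
    1L, "M", sl,
    center_start = c(runif(1, 10, dims[1] - 10), runif(1, 10, dims[2] - 10)),
    center_end = c(runif(1, 10, dims[1] - 10), runif(1, 10, dims[2] - 10)),
    semi_start = c(runif(1, 3, 7), runif(1, 3, 7)),
    semi_end = c(runif(1, 3, 7), runif(1, 3, 7)),
    base_ff = 12)
  sp <- phantom_spec(shape = dims, muscles = list(m))
  make_phantom(sp)$mask
}

reflect_rows <- function(arr) arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]

# bare integer array of region ids, no partition metadata
partition_array <- function(p) {
  p <- unclass(p)
  attributes(p) <- list(dim = dim(p))
  p
}
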