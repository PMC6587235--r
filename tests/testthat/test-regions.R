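quartile_sizes <- function(part) tabulate(part[part > 0L], 4)

test_that("quartile bands follow the floor-of-fractional-band rule", {
  # 8 occupied rows: exact division, Q1 = first two rows
  m8 <- box_mask(c(12, 3, 1), 1:8, 2, 1)
  p8 <- partition_quartiles(m8, 1)
  expect_equal(quartile_sizes(p8), c(2L, 2L, 2L, 2L))
  expect_equal(unclass(p8)[1:8, 2, 1], rep(1:4, each = 2))

  # 10 occupied rows: h = 2.5 gives band sizes (3, 2, 3, 2)
  m10 <- box_mask(c(12, 3, 1), 1:10, 2, 1)
  p10 <- partition_quartiles(m10, 1)
  expect_equal(quartile_sizes(p10), c(3L, 2L, 3L, 2L))
  expect_equal(unclass(p10)[1:3, 2, 1], rep(1L, 3))   # Q1 = first 3 rows
})

test_that("per-slice quartiles use each slice's own row extent", {
  dims <- c(20, 4, 2)
  arr <- array(0L, dims)
  arr[1:8, 2, 1] <- 1L        # slice 1 occupies rows 1..8
  arr[9:16, 2, 2] <- 1L       # slice 2 occupies rows 9..16
  mask <- label_mask(arr, c(`1` = "M"), toy_geometry(dims))
  p <- partition_quartiles(mask, 1)
  expect_equal(unclass(p)[1:2, 2, 1], c(1L, 1L))
  expect_equal(unclass(p)[9:10, 2, 2], c(1L, 1L))
  # image row 9 is Q1 on slice 2; would be outside the band on slice 1
  expect_equal(unclass(p)[9, 2, 1], 0L)
  # global extent instead spans rows 1..16 across both slices
  pg <- partition_quartiles(mask, 1, extent = "global")
  expect_equal(unclass(pg)[9:12, 2, 2], rep(3L, 4))
})

test_that("tertile slice groups are near-equal, contiguous, remainder-configurable", {
  m24 <- box_mask(c(6, 6, 24), 2:5, 2:5, 1:24)
  p24 <- partition_tertiles(m24, 1)
  per_slice <- apply(unclass(p24), 3, function(sl) unique(sl[sl > 0]))
  expect_equal(unname(lengths(per_slice)), rep(1L, 24))
  expect_equal(tabulate(unlist(per_slice), 3), c(8L, 8L, 8L))

  m10 <- box_mask(c(6, 6, 12), 2:5, 2:5, 2:11)
  grp <- function(p) apply(unclass(p), 3, function(sl) {
    u <- unique(sl[sl > 0]); if (length(u)) u else NA_integer_
  })
  g_lat <- grp(partition_tertiles(m10, 1))
  expect_equal(g_lat[2:11], rep(1:3, times = c(4, 3, 3)))
  g_med <- grp(partition_tertiles(m10, 1, remainder = "medial"))
  expect_equal(g_med[2:11], rep(1:3, times = c(3, 3, 4)))
  g_int <- grp(partition_tertiles(m10, 1, remainder = "intermediate"))
  expect_equal(g_int[2:11], rep(1:3, times = c(3, 4, 3)))

  # grouping starts at the first occupied slice, not slice 1
  m_off <- box_mask(c(6, 6, 12), 2:5, 2:5, 6:11)
  g_off <- grp(partition_tertiles(m_off, 1))
  expect_true(all(is.na(g_off[1:5])))
  expect_equal(g_off[6:11], rep(1:3, each = 2))

  expect_error(partition_tertiles(box_mask(c(6, 6, 4), 2:5, 2:5, 1:2), 1),
               "at least 3")
  expect_error(partition_quartiles(m24, 2), "empty")
})

test_that("partitions are disjoint and exhaustive with tight band-size bounds", {
  set.seed(202)
  for (rep in 1:15) {
    mask <- if (rep %% 2) random_box_mask() else random_ellipse_mask()
    sel <- mask$labels == 1L
    for (p in list(partition_quartiles(mask, 1),
                   partition_tertiles(mask, 1))) {
      pp <- unclass(p)
      expect_true(all(pp[sel] >= 1L))        # exhaustive over the muscle
      expect_true(all(pp[!sel] == 0L))       # nothing outside it
    }
    # quartile row-counts within each slice differ by at most one
    pq <- unclass(partition_quartiles(mask, 1))
    for (s in which(apply(sel, 3, any))) {
      rows_per_band <- vapply(1:4, function(q)
        length(unique(which(pq[, , s] == q, arr.ind = TRUE)[, 1])),
        integer(1))
      expect_lte(diff(range(rows_per_band[rows_per_band > 0])), 1L)
    }
    # tertile slice-group sizes differ by at most one and are contiguous
    pt <- unclass(partition_tertiles(mask, 1))
    grp <- apply(pt, 3, function(sl) {
      u <- unique(sl[sl > 0]); if (length(u)) u else NA_integer_
    })
    occ <- which(!is.na(grp))
    expect_true(all(diff(grp[occ]) %in% c(0L, 1L)))   # contiguous, ordered
    expect_lte(diff(range(tabulate(grp[occ], 3))), 1L)
    # region volumes sum exactly to the whole-muscle volume
    map <- map_from_field(array(10, dim(mask$labels)), mask$geometry)
    rs <- regional_stats(map, mask, partition_tertiles(mask, 1))
    expect_equal(sum(rs$volume_cm3), muscle_volume(mask, 1),
                 tolerance = 1e-12)
  }
})

test_that("superior-inferior reflection swaps Q1/Q4 and Q2/Q3 on 4-divisible extents", {
  set.seed(303)
  for (rep in 1:10) {
    h <- 4L * sample(1:5, 1)
    r0 <- sample(1:(24 - h), 1)
    mask <- box_mask(c(24, 10, 6), r0:(r0 + h - 1),
                     sample(2:8, 1):9, 1:6)
    p <- partition_array(partition_quartiles(mask, 1))
    refl_mask <- label_mask(reflect_rows(mask$labels), c(`1` = "M"),
                            mask$geometry)
    p_refl <- partition_array(partition_quartiles(refl_mask, 1))
    remapped <- reflect_rows(p_refl)
    remapped[remapped > 0L] <- 5L - remapped[remapped > 0L]
    expect_identical(remapped, p)
  }
})

test_that("regional means track constructed fields", {
  # uniform field: every region mean equals the constant
  ph <- make_phantom(phantom_spec(muscles = list(phantom_muscle(
    1L, "M", c(2, 21), c(20, 20), c(20, 30), c(8, 10), c(8, 10),
    base_ff = 11))))
  map <- compute_fat_fraction(ph$volume)
  for (p in list(partition_quartiles(ph$mask, 1),
                 partition_tertiles(ph$mask, 1))) {
    rs <- regional_stats(map, ph$mask, p)
    expect_equal(rs$mean_fat_pct_slice, rep(11, nrow(rs)), tolerance = 1e-9)
    expect_equal(rs$mean_fat_pct_voxel, rep(11, nrow(rs)), tolerance = 1e-9)
  }

  # superior-inferior gradient: strictly increasing quartile means
  ph2 <- make_phantom(phantom_spec(muscles = list(phantom_muscle(
    1L, "M", c(2, 21), c(20, 20), c(20, 30), c(8, 10), c(8, 10),
    base_ff = 12, si_gradient = 0.4))))
  rs2 <- regional_stats(compute_fat_fraction(ph2$volume), ph2$mask,
                        partition_quartiles(ph2$mask, 1))
  expect_true(all(diff(rs2$mean_fat_pct_voxel) > 0))
  expect_true(all(diff(rs2$mean_fat_pct_slice) > 0))

  # piecewise-constant tertile field recovered exactly, noise-free
  ph3 <- make_phantom(phantom_spec(muscles = list(phantom_muscle(
    1L, "M", c(3, 22), c(20, 24), c(20, 40), c(8, 10), c(8, 10),
    tertile_ff = c(10, 12, 14)))))
  rs3 <- regional_stats(compute_fat_fraction(ph3$volume), ph3$mask,
                        partition_tertiles(ph3$mask, 1))
  expect_equal(rs3$mean_fat_pct_slice, c(10, 12, 14), tolerance = 1e-6)
  expect_equal(rs3$mean_fat_pct_voxel, c(10, 12, 14), tolerance = 1e-6)
})

test_that("regions with only undefined fat fraction are flagged", {
  dims <- c(8, 4, 6)
  mask <- box_mask(dims, 2:7, 2:3, 1:6)
  field <- array(12, dims)
  field[, , 1:2] <- NA                      # lateral tertile undefined
  map <- map_from_field(field, mask$geometry)
  expect_warning(
    rs <- regional_stats(map, mask, partition_tertiles(mask, 1)),
    "no defined")
  expect_true(is.na(rs$mean_fat_pct_voxel[rs$region == "lateral"]))
  expect_false(anyNA(rs$mean_fat_pct_voxel[rs$region != "lateral"]))
})
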