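test_that("volume I/O round-trips data and geometry across formats", {
  vol <- random_volume(c(8, 8, 8), spacing = c(1, 1, 2.5), seed = 3)
  vol$origin <- c(10, -5, 2)
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    write_volume(vol, f)
    back <- read_volume(f)
    expect_equal(back$data, vol$data, tolerance = 0, info = ext)
    expect_equal(back$spacing, vol$spacing, info = ext)
    expect_equal(back$origin, vol$origin, info = ext)
  }
})

test_that("constant volume round-trip is exact and gzipped NIfTI matches the in-memory phantom", {
  vol <- scalar_volume(array(42, c(8, 8, 8)), spacing = c(1, 1, 1))
  f <- tempfile(fileext = ".mha")
  write_volume(vol, f)
  expect_identical(read_volume(f)$data, vol$data)

  ph <- make_reference_phantom(phantom_spec(shape = c(16, 16, 12),
                                            body_radii = c(12, 12, 14),
                                            mandible = list(center_offset = c(0, -2, -4),
                                                            arc_radius = 6,
                                                            tube_radius = 2,
                                                            half_angle = 70),
                                            parotid = list(offset_lr = 8,
                                                           offset_ap = 1,
                                                           offset_si = -3,
                                                           radii = c(2, 3, 3)),
                                            spine = list(offset_ap = 6, radius = 2),
                                            noise_sd = 5))
  g <- tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, g)
  expect_equal(read_volume(g)$data, ph$volume$data, tolerance = 1e-12)
})

test_that("label masks round-trip with their label histogram and sidecar names", {
  a <- array(0L, c(6, 6, 6))
  a[2:3, 2:3, 2:3] <- 1L; a[5, 5, 5] <- 2L; a[1, 6, 3] <- 3L
  m <- label_mask(a, list(`1` = "body", `2` = "node", `3` = "marker"),
                  spacing = c(2, 2, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_label_mask(m, f)
  back <- read_label_mask(f)
  expect_identical(table(back$data), table(m$data))
  expect_equal(back$label_names, m$label_names)
})

test_that("vector-field I/O round-trips exactly at 32-bit precision", {
  z <- zero_field(c(6, 6, 4), spacing = c(2, 2, 3))
  f <- tempfile(fileext = ".mha")
  write_vector_field(z, f)
  expect_fields_equal(read_vector_field(f), z)

  cf <- const_field(c(1, -2, 3), c(6, 6, 4), spacing = c(2, 2, 3))
  write_vector_field(cf, f)
  expect_fields_equal(read_vector_field(f), cf)

  sf <- smooth_field(seed = 7)
  for (ext in c(".mha", ".nii.gz")) {
    g <- tempfile(fileext = ext)
    write_vector_field(sf, g)
    back <- read_vector_field(g)
    # float32 quantization bound
    expect_fields_equal(back, sf, tol = max(abs(c(sf$dx, sf$dy, sf$dz))) *
                          2^-23 * 2)
    expect_equal(back$spacing, sf$spacing)
  }
})

test_that("readers reject wrong content with format errors", {
  f <- tempfile(fileext = ".xyz")
  writeLines("junk", f)
  expect_error(read_volume(f), "format error")
  expect_error(read_volume(tempfile(fileext = ".nii")), "format error")
  # a scalar file is not a vector field
  v <- random_volume(c(4, 4, 4))
  g <- tempfile(fileext = ".mha")
  write_volume(v, g)
  expect_error(read_vector_field(g), "format error")
  # a vector file is not a scalar volume
  h <- tempfile(fileext = ".mha")
  write_vector_field(zero_field(c(4, 4, 4)), h)
  expect_error(read_volume(h), "format error")
})

test_that("warp_volume: identity, integer shift, and closed-form ramp", {
  v <- random_volume(c(10, 10, 8), spacing = c(1, 1, 2), seed = 5)
  expect_identical(warp_volume(v, zero_field(c(10, 10, 8),
                                             spacing = c(1, 1, 2)))$data,
                   v$data)
  # +1 voxel along LR (spacing 1 -> 1 mm)
  sh1 <- warp_volume(v, const_field(c(1, 0, 0), c(10, 10, 8),
                                    spacing = c(1, 1, 2)))
  expect_equal(sh1$data[1:9, , ], v$data[2:10, , ], tolerance = 1e-13)
  # out-of-grid voxels take the fill value
  expect_true(all(sh1$data[10, , ] == -1000))

  # half-voxel shift on a linear ramp equals the ramp at shifted coordinates
  ramp <- scalar_volume(array(rep(3 * (1:10), times = 80), c(10, 10, 8)),
                        spacing = c(1, 1, 2))
  hw <- warp_volume(ramp, const_field(c(0.5, 0, 0), c(10, 10, 8),
                                      spacing = c(1, 1, 2)))
  expect_equal(hw$data[2:9, , ], ramp$data[2:9, , ] + 1.5, tolerance = 1e-12)
})

test_that("warp with nearest mode preserves label values", {
  m <- cube_mask(c(8, 8, 8), c(3, 3, 3), c(6, 6, 6))
  shifted <- warp_mask(m, const_field(c(1, 0, 0), c(8, 8, 8)))
  expect_true(all(shifted$data %in% c(0L, 1L)))
  expect_equal(sum(shifted$data), sum(m$data))  # interior shift, no clipping
})

test_that("rigid_align recovers constructed shifts, with and without noise", {
  a <- random_volume(c(12, 12, 12), seed = 11)
  expect_identical(rigid_align(a, a, search_radius = 2), c(0L, 0L, 0L))

  shift_by <- function(vol, s) {
    out <- vol
    out$data[] <- 0
    src_lo <- pmax(1, 1 - s); src_hi <- pmin(dim(vol$data), dim(vol$data) - s)
    dst_lo <- src_lo + s; dst_hi <- src_hi + s
    out$data[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      vol$data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    out
  }
  s <- c(3L, -2L, 1L)
  moved <- shift_by(a, s)
  expect_identical(rigid_align(moved, a, search_radius = 4), -s)

  set.seed(42)
  noisy <- moved
  noisy$data <- noisy$data + rnorm(length(noisy$data), 0, 5)  # 5% of sd(a)
  expect_identical(rigid_align(noisy, a, search_radius = 4), -s)
})

test_that("crop_to_common_space equals brute-force interval intersection", {
  sh <- c(10, 12, 8)
  vols <- lapply(1:3, function(k) random_volume(sh, seed = k))
  # zero translations: unchanged
  out0 <- crop_to_common_space(vols, list(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_identical(out0[[1]]$data, vols[[1]]$data)

  set.seed(9)
  for (rep in 1:5) {
    tr <- lapply(1:3, function(k) sample(-2:2, 3, replace = TRUE))
    # brute-force world-box intersection in reference indices
    lo <- apply(do.call(rbind, lapply(tr, function(t) 1 + t)), 2, max)
    hi <- apply(do.call(rbind, lapply(tr, function(t) sh + t)), 2, min)
    out <- crop_to_common_space(vols, tr)
    for (k in 1:3) {
      expect_identical(grid_shape(out[[k]]), as.integer(hi - lo + 1))
      w <- lo - tr[[k]]
      expect_identical(out[[k]]$data,
                       vols[[k]]$data[w[1]:(w[1] + hi[1] - lo[1]),
                                      w[2]:(w[2] + hi[2] - lo[2]),
                                      w[3]:(w[3] + hi[3] - lo[3]),
                                      drop = FALSE])
    }
    expect_true(all(vapply(out[-1], same_geometry, logical(1), b = out[[1]])))
  }
  expect_error(crop_to_common_space(vols[1:2],
                                    list(c(0, 0, 0), c(20, 0, 0))),
               "empty intersection")
})

test_that("crop_like extracts the matching window of companion objects", {
  v <- random_volume(c(10, 10, 10), seed = 2)
  cropped <- crop_to_common_space(list(v, v),
                                  list(c(0L, 0L, 0L), c(2L, -1L, 0L)))[[1]]
  w <- crop_like(v, cropped)
  expect_true(same_geometry(w, cropped))
  expect_identical(w$data, cropped$data)
})
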