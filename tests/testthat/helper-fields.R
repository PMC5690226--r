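# Shared fixture builders: everything is generated in code at test time.

zero_arr <- function(sh) array(0, sh)

zero_field <- function(sh = c(6, 6, 6), spacing = c(1, 1, 1)) {
  vector_field(zero_arr(sh), zero_arr(sh), zero_arr(sh), spacing)
}

const_field <- function(v, sh = c(6, 6, 6), spacing = c(1, 1, 1)) {
  vector_field(array(v[1], sh), array(v[2], sh), array(v[3], sh), spacing)
}

random_volume <- function(sh = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  scalar_volume(array(rnorm(prod(sh), 0, 100), sh), spacing)
}

# smooth random field with approximate peak magnitude `peak_mm`
smooth_field <- function(sh = c(12, 12, 10), spacing = c(2, 2, 3),
                         peak_mm = 3, sigma_vox = 2.5, seed = 1) {
  set.seed(seed)
  mk <- function() {
    a <- deformgen:::cpp_gauss3(array(rnorm(prod(sh)), sh),
                                rep(sigma_vox, 3))
    a
  }
  dx <- mk(); dy <- mk(); dz <- mk()
  m <- max(sqrt(dx^2 + dy^2 + dz^2))
  vector_field(dx * peak_mm / m, dy * peak_mm / m, dz * peak_mm / m, spacing)
}

# smooth blob with intensity gradients everywhere in its foreground;
# offx translates it analytically along LR (mm)
blob_volume <- function(sh = c(48, 48, 32), spacing = c(2, 2, 3), offx = 0) {
  ctr <- (sh - 1) / 2 * spacing
  ix <- (0:(sh[1] - 1)) * spacing[1] - ctr[1]
  iy <- (0:(sh[2] - 1)) * spacing[2] - ctr[2]
  iz <- (0:(sh[3] - 1)) * spacing[3] - ctr[3]
  a <- array(0, sh)
  for (k in seq_len(sh[3]))
    a[, , k] <- 1000 * exp(-2 * (outer((ix - offx)^2 / 40^2, iy^2 / 40^2, "+") +
                                   iz[k]^2 / 40^2))
  scalar_volume(a, spacing)
}

# tiny two-label cubes for metric tests
cube_mask <- function(sh, lo, hi, label = 1L, spacing = c(1, 1, 1),
                      names = list(`1` = "cube")) {
  a <- array(0L, sh)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- label
  label_mask(a, names, spacing)
}

expect_fields_equal <- function(a, b, tol = 1e-12) {
  expect_lte(max(abs(a$dx - b$dx)), tol)
  expect_lte(max(abs(a$dy - b$dy)), tol)
  expect_lte(max(abs(a$dz - b$dz)), tol)
}
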