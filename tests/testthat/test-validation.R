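test_that("error_map matches the sqrt-of-squares oracle", {
  a <- smooth_field(peak_mm = 3, seed = 1)
  expect_true(all(error_map(a, a)$data == 0))

  sh <- grid_shape(a)
  b <- vector_field(a$dx + 3, a$dy + 4, a$dz, a$spacing)
  expect_equal(error_map(b, a)$data, array(5, sh), tolerance = 1e-12)

  c2 <- smooth_field(peak_mm = 2, seed = 2)
  em <- error_map(a, c2)
  oracle <- sqrt((a$dx - c2$dx)^2 + (a$dy - c2$dy)^2 + (a$dz - c2$dz)^2)
  expect_equal(em$data, oracle, tolerance = 1e-14)
  expect_true(all(em$data >= 0))
})

test_that("structure_stats and deformation magnitude match flat-loop oracles", {
  sh <- c(6, 6, 6)
  m <- cube_mask(sh, c(2, 2, 2), c(4, 4, 4))
  const2 <- scalar_volume(array(2, sh))
  s <- structure_stats(const2, m, 1)
  expect_equal(unname(s[c("mean", "sd")]), c(2, 0))

  two <- label_mask(array(c(5L, rep(0L, 214), 5L), sh),
                    list(`5` = "pair"))
  vals <- array(0, sh); vals[1, 1, 1] <- 1; vals[6, 6, 6] <- 3
  s2 <- structure_stats(scalar_volume(vals), two, 5)
  expect_equal(unname(s2["mean"]), 2)
  expect_equal(unname(s2["sd"]), sqrt(2))
  expect_equal(unname(s2["n"]), 2)

  set.seed(4)
  vol <- random_volume(sh, seed = 4)
  lab <- label_mask(array(sample(0:2, prod(sh), TRUE), sh),
                    list(`1` = "a", `2` = "b"))
  st <- structure_stats(vol, lab, 2)
  sel <- vol$data[lab$data == 2]
  expect_equal(unname(st["mean"]), mean(sel))
  expect_equal(unname(st["sd"]), sd(sel))
  expect_equal(unname(st["max"]), max(sel))

  z <- zero_field(sh)
  expect_equal(unname(mean_deformation_magnitude(z, lab, 1)), c(0, 0))
  cf <- const_field(c(0, 0, 2), sh)
  expect_equal(unname(mean_deformation_magnitude(cf, lab, 1)), c(2, 0))
  f <- smooth_field(sh, spacing = c(1, 1, 1), peak_mm = 4, seed = 5)
  md <- mean_deformation_magnitude(f, lab, 1)
  mags <- sqrt(f$dx^2 + f$dy^2 + f$dz^2)[lab$data == 1]
  expect_equal(unname(md), c(mean(mags), sd(mags)))

  expect_error(structure_stats(vol, lab, 9), "empty")
})

test_that("dice covers identity, disjoint, half-overlap and errors on empty", {
  sh <- c(12, 12, 12)
  a <- cube_mask(sh, c(2, 2, 2), c(5, 5, 5))
  expect_equal(dice(a, a), 100)
  b <- cube_mask(sh, c(7, 7, 7), c(10, 10, 10))
  expect_equal(dice(a, b), 0)
  # equal-volume cubes overlapping exactly half: 2*32/(64+64) = 50%
  c1 <- cube_mask(sh, c(1, 1, 1), c(4, 4, 4))
  c2 <- cube_mask(sh, c(3, 1, 1), c(6, 4, 4))
  expect_equal(dice(c1, c2), 50)
  empty <- label_mask(array(0L, sh), list(`1` = "x"))
  expect_error(dice(empty, empty), "empty")
  expect_true(abs(dice(c1, c2) - dice(c2, c1)) < 1e-12)
})

test_that("mean surface distance: plates and all-pairs brute force", {
  sh <- c(10, 10, 10)
  # two 1-voxel plates 3 voxels apart at 2 mm spacing -> 6 mm
  pa <- cube_mask(sh, c(2, 1, 1), c(2, 10, 10), spacing = c(2, 2, 2))
  pb <- cube_mask(sh, c(5, 1, 1), c(5, 10, 10), spacing = c(2, 2, 2))
  expect_equal(mean_surface_distance(pa, pb), 6, tolerance = 1e-12)
  expect_equal(mean_surface_distance(pa, pa), 0)

  brute_msd <- function(a, b, la = 1, lb = 1) {
    surf <- function(m, l) {
      sel <- m$data == l
      sh <- dim(sel)
      out <- NULL
      for (i in 1:sh[1]) for (j in 1:sh[2]) for (k in 1:sh[3]) {
        if (!sel[i, j, k]) next
        nb <- c(if (i > 1) sel[i - 1, j, k] else FALSE,
                if (i < sh[1]) sel[i + 1, j, k] else FALSE,
                if (j > 1) sel[i, j - 1, k] else FALSE,
                if (j < sh[2]) sel[i, j + 1, k] else FALSE,
                if (k > 1) sel[i, j, k - 1] else FALSE,
                if (k < sh[3]) sel[i, j, k + 1] else FALSE)
        if (length(nb) < 6 || !all(nb))
          out <- rbind(out, (c(i, j, k) - 1) * m$spacing)
      }
      out
    }
    sa <- surf(a, la); sb <- surf(b, lb)
    dmin <- function(p, q) mean(apply(p, 1, function(x)
      min(sqrt(colSums((t(q) - x)^2)))))
    (dmin(sa, sb) + dmin(sb, sa)) / 2
  }
  set.seed(6)
  for (rep in 1:3) {
    shs <- c(9, 8, 7)
    blob <- function(seed) {
      set.seed(seed)
      ctr <- runif(3, 3, 6)
      r <- runif(1, 1.5, 3)
      a <- array(0L, shs)
      for (i in 1:shs[1]) for (j in 1:shs[2]) for (k in 1:shs[3])
        if (sum((c(i, j, k) - ctr)^2) <= r^2) a[i, j, k] <- 1L
      label_mask(a, list(`1` = "blob"), spacing = c(1, 2, 1.5))
    }
    m1 <- blob(rep * 10); m2 <- blob(rep * 10 + 1)
    if (sum(m1$data) && sum(m2$data))
      expect_equal(mean_surface_distance(m1, m2), brute_msd(m1, m2),
                   tolerance = 1e-10)
  }
  empty <- label_mask(array(0L, sh), list(`1` = "x"), spacing = c(2, 2, 2))
  expect_error(mean_surface_distance(pa, empty), "empty")
})

test_that("mode coverage curve is the cumulative-sum oracle", {
  expect_equal(mode_coverage_curve(c(1, 1, 1, 1))$pct, c(25, 50, 75, 100))
  expect_equal(mode_coverage_curve(c(7, 0, 0))$pct, c(100, 100, 100))
  set.seed(8)
  lam <- sort(rexp(9), decreasing = TRUE)
  crv <- mode_coverage_curve(lam)
  expect_equal(crv$pct, 100 * cumsum(lam) / sum(lam))
  expect_true(all(diff(crv$pct) >= -1e-12))
  expect_equal(crv$pct[9], 100, tolerance = 1e-9)
  expect_error(mode_coverage_curve(numeric(0)), "zero total")
})

test_that("interpolated mode count reproduces the printed worked example", {
  crv <- data.frame(modes = c(4, 5), pct = c(88, 91))
  expect_equal(round(modes_needed_interpolated(crv, 90), 1), 4.7)
  # a target on a curve point returns that integer
  crv2 <- mode_coverage_curve(c(4, 3, 2, 1))
  expect_equal(modes_needed_interpolated(crv2, 70), 2)
  # below the first point: interpolate from (0, 0)
  expect_equal(modes_needed_interpolated(crv2, 20), 0.5)
  expect_error(modes_needed_interpolated(crv, 99.5), "above the curve")

  # fine-grid piecewise-linear oracle on random monotone curves
  set.seed(11)
  for (rep in 1:10) {
    lam <- sort(rexp(6), decreasing = TRUE)
    crv3 <- mode_coverage_curve(lam)
    xs <- c(0, crv3$modes); ys <- c(0, crv3$pct)
    target <- runif(1, 5, 99)
    oracle <- approx(ys, xs, xout = target, ties = "ordered")$y
    expect_equal(modes_needed_interpolated(crv3, target), oracle,
                 tolerance = 1e-6)
  }
})

test_that("modes_vs_training_size plateaus at the latent rank and is seeded", {
  # rank-3 population: all fields are combinations of 3 basis fields
  set.seed(12)
  sh <- c(5, 5, 5)
  basis <- lapply(1:3, function(k) rnorm(3 * prod(sh)))
  grid <- list(shape = sh, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  dvfs <- lapply(1:14, function(i)
    devectorize_field(basis[[1]] * rnorm(1) + basis[[2]] * rnorm(1) +
                        basis[[3]] * rnorm(1), grid))
  tab <- modes_vs_training_size(dvfs, alpha = 99, subset_sizes = c(5, 10, 14),
                                seed = 3)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$modes_needed <= 3 + 1e-9))
  full <- fit_shape_model(dvfs, alpha = 99)
  expect_equal(tab$modes_needed[3],
               modes_needed_interpolated(mode_coverage_curve(full$eigenvalues),
                                         99))
  tab2 <- modes_vs_training_size(dvfs, alpha = 99, subset_sizes = c(5, 10, 14),
                                 seed = 3)
  expect_identical(tab, tab2)
})
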