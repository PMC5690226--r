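random_field_list <- function(n, sh = c(6, 6, 6), seed = 1, scale = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    vector_field(array(rnorm(prod(sh), 0, scale), sh),
                 array(rnorm(prod(sh), 0, scale), sh),
                 array(rnorm(prod(sh), 0, scale), sh)))
}

test_that("training matrix vectorization order is frozen and invertible", {
  z <- zero_field(c(4, 4, 4))
  D <- build_training_matrix(list(z, z))
  expect_equal(dim(D$columns), c(192, 2))
  expect_true(all(D$columns == 0))

  f <- smooth_field(c(4, 4, 4), spacing = c(1, 1, 1), peak_mm = 2, seed = 3)
  back <- devectorize_field(vectorize_field(f),
                            list(shape = c(4, 4, 4), spacing = f$spacing,
                                 origin = f$origin))
  expect_fields_equal(back, f, tol = 0)

  # element-indexing oracle: component-major blocks, first axis fastest
  v <- vectorize_field(f)
  expect_identical(v[1:64], as.vector(f$dx))
  expect_identical(v[65:128], as.vector(f$dy))
  expect_identical(v[2], f$dx[2, 1, 1])
  expect_identical(v[64 + 5], f$dy[1, 2, 1])

  expect_error(build_training_matrix(list(z)), "at least 2")
  expect_error(build_training_matrix(list(z, zero_field(c(5, 4, 4)))),
               "geometry mismatch")
})

test_that("degenerate and two-point populations have closed-form fits", {
  f <- smooth_field(c(5, 5, 5), spacing = c(1, 1, 1), peak_mm = 2, seed = 9)
  same <- fit_shape_model(list(f, f, f), alpha = 90)
  expect_equal(same$T_hat, 0L)
  expect_equal(same$total_variance, 0)
  expect_fields_equal(devectorize_field(same$mean, same$grid), f, tol = 1e-12)

  # d_bar +/- v: single mode with eigenvalue 2*||v||^2 / (N-1) = ||v||^2 * 2
  v <- smooth_field(c(5, 5, 5), spacing = c(1, 1, 1), peak_mm = 1, seed = 10)
  vv <- vectorize_field(v)
  plus <- devectorize_field(vectorize_field(f) + vv, same$grid)
  minus <- devectorize_field(vectorize_field(f) - vv, same$grid)
  two <- fit_shape_model(list(plus, minus), alpha = 90)
  expect_equal(length(two$eigenvalues), 1L)
  expect_equal(two$eigenvalues[1], 2 * sum(vv^2), tolerance = 1e-10)
  expect_equal(abs(sum(two$modes[, 1] * vv / sqrt(sum(vv^2)))), 1,
               tolerance = 1e-10)
  expect_equal(two$T_hat, 1L)
})

test_that("Gram-trick eigenpairs equal the dense covariance decomposition", {
  for (seed in 1:3) {
    n <- 8
    dvfs <- random_field_list(n, c(6, 6, 6), seed = seed)
    fit <- fit_shape_model(dvfs, alpha = 100)
    D <- vapply(dvfs, vectorize_field, numeric(648))
    S <- stats::cov(t(D))   # dense 648 x 648 covariance
    ed <- eigen(S, symmetric = TRUE)
    k <- length(fit$eigenvalues)
    expect_equal(k, n - 1)
    expect_lt(max(abs(fit$eigenvalues - ed$values[1:k]) / ed$values[1:k]),
              1e-8)
    dots <- abs(colSums(fit$modes * ed$vectors[, 1:k]))
    expect_true(all(dots > 1 - 1e-8))
  }
})

test_that("modes are orthonormal and span the centered training data", {
  dvfs <- random_field_list(7, c(6, 6, 6), seed = 5)
  fit <- fit_shape_model(dvfs, alpha = 100)
  G <- crossprod(fit$modes)
  expect_lt(max(abs(G - diag(ncol(fit$modes)))), 1e-8)
  # reconstruction: project-and-expand reproduces each centered column
  D <- vapply(dvfs, vectorize_field, numeric(648))
  C <- D - rowMeans(D)
  proj <- fit$modes %*% crossprod(fit$modes, C)
  expect_lt(max(abs(proj - C)) / max(abs(C)), 1e-6)
})

test_that("select_principal_modes is minimal and matches a linear scan", {
  expect_equal(select_principal_modes(c(4, 3, 2, 1), 90), 3L)
  expect_equal(select_principal_modes(c(5, 0, 0), 100), 1L)
  expect_equal(select_principal_modes(numeric(0), 90), 0L)
  expect_error(select_principal_modes(c(1, 2), 90), "sorted")

  scan_oracle <- function(lam, alpha) {
    total <- sum(lam)
    for (t in seq_along(lam))
      if (sum(lam[1:t]) >= alpha / 100 * total) return(t)
    length(lam)
  }
  set.seed(7)
  for (i in 1:25) {
    lam <- sort(rexp(sample(2:12, 1)), decreasing = TRUE)
    alpha <- runif(1, 50, 100)
    expect_equal(select_principal_modes(lam, alpha), scan_oracle(lam, alpha))
  }
})

test_that("retention satisfies the alpha bound minimally", {
  dvfs <- random_field_list(9, c(6, 6, 6), seed = 12)
  fit <- fit_shape_model(dvfs, alpha = 90)
  lam <- fit$eigenvalues
  expect_gte(sum(lam[seq_len(fit$T_hat)]) / sum(lam), 0.9)
  expect_lt(sum(lam[seq_len(fit$T_hat - 1)]) / sum(lam), 0.9)
})

test_that("variation-space reduction reproduces the printed worked examples", {
  expect_equal(round(space_reduction(11, 5)), 55)
  expect_equal(round(space_reduction(396, 12)), 97)
  expect_equal(space_reduction(7, 7), 0)
  expect_error(space_reduction(5, 6), "T_hat")
})

test_that("mahalanobis_distance matches term-by-term summation", {
  expect_equal(mahalanobis_distance(numeric(0), numeric(0)), 0)
  expect_equal(mahalanobis_distance(c(2), c(4)), 1)
  set.seed(3)
  for (i in 1:10) {
    k <- sample(1:6, 1)
    lam <- rexp(k) + 0.1
    b <- rnorm(k)
    expect_equal(mahalanobis_distance(b, lam), sqrt(sum(b^2 / lam)))
  }
  expect_error(mahalanobis_distance(c(1, 1), c(2, 0)), "contract error")
})

test_that("sampling honours D_max, the mean at D_max = 0, and seeding", {
  dvfs <- random_field_list(6, c(5, 5, 5), seed = 20)
  model <- fit_shape_model(dvfs, alpha = 95)

  s0 <- sample_deformation(model, D_max = 0, rng_seed = 1)
  expect_true(all(s0$weights$b == 0))
  expect_fields_equal(s0$field, devectorize_field(model$mean, model$grid),
                      tol = 0)

  a <- sample_deformation(model, D_max = 3, rng_seed = 99)
  b <- sample_deformation(model, D_max = 3, rng_seed = 99)
  expect_identical(a$weights$b, b$weights$b)
  expect_identical(a$field$dx, b$field$dx)

  # the sampler must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(sample_deformation(model, 3, rng_seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("10,000 bounded draws never violate the Mahalanobis constraint", {
  dvfs <- random_field_list(6, c(4, 4, 4), seed = 30)
  model <- fit_shape_model(dvfs, alpha = 100)
  lam <- model$eigenvalues[seq_len(model$T_hat)]
  for (i in seq_len(10000)) {
    # weights-only replica of the sampler's accept/reject loop, seeded
    s <- sample_deformation(model, D_max = 3, rng_seed = i)
    if (mahalanobis_distance(s$weights$b, lam) > 3 + 1e-12)
      fail(sprintf("draw %d violates D_max", i))
  }
  succeed()
})

test_that("single-mode truncated draws match the numeric truncated-normal sd", {
  # one dominant mode: lambda = 1
  sh <- c(4, 4, 4)
  unit <- c(1, rep(0, 3 * prod(sh) - 1))
  grid <- list(shape = sh, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  model <- structure(list(mean = rep(0, 3 * prod(sh)), eigenvalues = 1,
                          modes = matrix(unit, ncol = 1), T_hat = 1L,
                          alpha = 95, total_variance = 1, grid = grid,
                          n_train = 2L),
                     class = "shape_model")
  bs <- vapply(1:10000, function(i)
    sample_deformation(model, D_max = 3, rng_seed = i)$weights$b,
    numeric(1))
  # oracle: sd of N(0,1) truncated to |b| <= 3 by numeric integration
  f2 <- integrate(function(x) x^2 * dnorm(x), -3, 3)$value
  mass <- integrate(dnorm, -3, 3)$value
  sd_oracle <- sqrt(f2 / mass)
  expect_lt(abs(sd(bs) - sd_oracle) / sd_oracle, 0.05)
})

test_that("unbounded per-mode variances converge to the eigenvalues", {
  dvfs <- random_field_list(5, c(4, 4, 4), seed = 44)
  model <- fit_shape_model(dvfs, alpha = 100)
  t_hat <- model$T_hat
  B <- vapply(1:10000, function(i)
    sample_deformation(model, D_max = Inf, rng_seed = i)$weights$b,
    numeric(t_hat))
  emp <- apply(B, 1, var)
  expect_true(all(abs(emp - model$eigenvalues[1:t_hat]) /
                    model$eigenvalues[1:t_hat] < 0.1))
})

test_that("model serialization round-trips exactly", {
  dvfs <- random_field_list(5, c(5, 5, 5), seed = 50)
  model <- fit_shape_model(dvfs, alpha = 92)
  dir <- tempfile("model_")
  write_shape_model(model, dir)
  back <- read_shape_model(dir)
  expect_identical(back$mean, model$mean)
  expect_identical(back$modes, model$modes)
  expect_identical(back$eigenvalues, model$eigenvalues)
  expect_equal(back$T_hat, model$T_hat)
  expect_equal(back$alpha, model$alpha)
  expect_equal(back$grid$shape, model$grid$shape)
  # a reloaded model samples identically
  expect_identical(sample_deformation(back, 2, rng_seed = 5)$field$dx,
                   sample_deformation(model, 2, rng_seed = 5)$field$dx)
})

test_that("fitted-model methods expose the model consistently", {
  dvfs <- random_field_list(6, c(5, 5, 5), seed = 60)
  model <- fit_shape_model(dvfs, alpha = 90)
  expect_output(print(model), "shape_model")
  s <- summary(model)
  expect_s3_class(s, "summary.shape_model")
  expect_equal(nrow(s$coverage), length(model$eigenvalues))
  expect_equal(s$coverage$cum_pct[nrow(s$coverage)], 100, tolerance = 1e-9)
  expect_equal(unname(coef(model)), model$eigenvalues)

  # predict() is the deterministic counterpart of sampling
  b <- c(1.5, -0.5)
  pf <- predict(model, b)
  manual <- model$mean + model$modes[, 1:2] %*% b
  expect_equal(vectorize_field(pf), as.vector(manual), tolerance = 1e-12)
  expect_fields_equal(predict(model),
                      devectorize_field(model$mean, model$grid), tol = 0)

  sims <- simulate(model, nsim = 2, seed = 4, D_max = 2)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$weights$b, sims[[2]]$weights$b))
})
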