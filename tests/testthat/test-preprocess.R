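test_that("PSF application and correction are inverse to each other", {
  psf <- psf_model(z_R = 0.3, z_f = 0.5)
  expect_equal(psf_factor(psf, 0.5), 1)              # in focus
  expect_equal(psf_factor(psf, 0.8), 0.5)            # one Rayleigh length out
  g <- depth_grid(0.001, 700)
  a <- ascan(exp(-2 * depths(g)), g)
  back <- psf_correct(psf_apply(a, psf), psf)
  expect_equal(back$values, a$values, tolerance = 1e-9)
  # in-focus pixel is untouched by correction
  b <- psf_correct(a, psf)
  i_f <- which.min(abs(depths(g) - 0.5))
  expect_equal(b$values[i_f], a$values[i_f], tolerance = 1e-12)
})

test_that("B-scan averaging reduces speckle variance about n-fold", {
  g <- depth_grid(0.001, 10000)
  base <- exp(-0.3 * depths(g))
  set.seed(42)
  stack <- lapply(1:5, function(i)
    bscan(matrix(base * rexp(g$n), ncol = 1), g))
  avg <- average_bscans(stack, 5)
  # identical frames average to themselves
  same <- average_bscans(list(stack[[1]], stack[[1]]), 2)
  expect_equal(same$values, stack[[1]]$values)
  v1 <- var(stack[[1]]$values[, 1] / base)
  v5 <- var(avg$values[, 1] / base)
  expect_lt(abs(v5 / (v1 / 5) - 1), 0.3)
  # geometry mismatch is refused
  g2 <- depth_grid(0.002, 10000)
  expect_error(average_bscans(list(stack[[1]],
                                   bscan(stack[[2]]$values, g2))),
               "geometry")
})

test_that("exhaustive PSF calibration recovers on-grid truth exactly", {
  g <- depth_grid(0.001, 600)
  z <- depths(g)
  true_psf <- psf_model(z_R = 0.3, z_f = 0.25)
  refl <- exp(-((z - 0.05) / 0.02)^2) + 0.5 * exp(-3 * z)
  delta_z <- 0.15
  i1 <- matrix(refl * psf_factor(true_psf, z), ncol = 4, nrow = g$n)
  refl2 <- c(rep(0, 150), refl)[1:g$n]
  i2 <- matrix(refl2 * psf_factor(true_psf, z), ncol = 4, nrow = g$n)
  pair <- calibration_pair(bscan(i1, g), bscan(i2, g), delta_z)
  fit <- calibrate_psf(pair, grid_zR = seq(0.1, 0.6, 0.05),
                       grid_zf = seq(0, 1, 0.05))
  expect_equal(fit$psf$z_R, 0.3)
  expect_equal(fit$psf$z_f, 0.25)
  # a zero shift is degenerate
  expect_error(calibration_pair(bscan(i1, g), bscan(i1, g), 0),
               "degenerate")
})

test_that("PSF calibration stays within one grid step under 1% noise", {
  g <- depth_grid(0.001, 600)
  z <- depths(g)
  true_psf <- psf_model(z_R = 0.3, z_f = 0.25)
  refl <- exp(-((z - 0.05) / 0.02)^2) + 0.5 * exp(-3 * z)
  refl2 <- c(rep(0, 150), refl)[1:g$n]
  step <- 0.05
  set.seed(7)
  for (trial in 1:10) {
    n1 <- matrix(refl * psf_factor(true_psf, z), ncol = 4, nrow = g$n)
    n2 <- matrix(refl2 * psf_factor(true_psf, z), ncol = 4, nrow = g$n)
    n1 <- n1 + rnorm(length(n1), sd = 0.01 * max(n1))
    n2 <- n2 + rnorm(length(n2), sd = 0.01 * max(n2))
    pair <- calibration_pair(bscan(pmax(n1, 0), g), bscan(pmax(n2, 0), g),
                             0.15)
    fit <- calibrate_psf(pair, grid_zR = seq(0.1, 0.6, step),
                         grid_zf = seq(0, 1, step))
    expect_lte(abs(fit$psf$z_R - 0.3), step + 1e-12)
    expect_lte(abs(fit$psf$z_f - 0.25), step + 1e-12)
  }
})

test_that("noise-floor fitting recovers exponential decay rates", {
  g <- depth_grid(0.001, 2200)
  z <- depths(g)
  for (mu in c(2, 4, 8)) {
    vals <- 1e8 * exp(-2 * mu * z)
    keep <- vals > 1e3                  # stay above numerical junk
    a <- ascan(vals, g)
    fit <- fit_noise_floor(a, preprocess_config())
    expect_equal(fit$mu_tilde, mu, tolerance = 1e-6)
    expect_lt(fit$z_nf0, fit$z_nf1)
  }
  # profile that never reaches the thresholds is refused with guidance
  a_hi <- ascan(1e8 * exp(-0.1 * z), g)
  expect_error(fit_noise_floor(a_hi, preprocess_config()),
               "full profile as signal")
})

test_that("floor crossing and decay fit survive an additive 50 dB floor", {
  g <- depth_grid(0.001, 3500)
  z <- depths(g)
  mu <- 2
  vals <- 1e8 * exp(-2 * mu * z) + 1e5
  a <- ascan(vals, g)
  fit <- fit_noise_floor(a, preprocess_config())
  # crossing located where the signal meets the floor level
  expect_equal(fit$floor_level, 1e5, tolerance = 0.02)
  expect_equal(fit$mu_tilde, mu, tolerance = 0.05)
  ex <- extrapolate_tail(a, fit)
  # deep values replaced by a decaying exponential, not the flat floor
  expect_lt(ex$values[g$n], 1e5 / 10)
  expect_false(is.null(ex$tail))
  # self-consistency on a pure exponential: extrapolation is a no-op
  pure <- ascan(1e8 * exp(-2 * mu * z), g)
  fit2 <- fit_noise_floor(pure, preprocess_config())
  ex2 <- extrapolate_tail(pure, fit2)
  expect_equal(ex2$values, pure$values, tolerance = 1e-6)
})

test_that("tail integrals use the closed-form exponential remainder", {
  g <- depth_grid(0.001, 1000)
  z <- depths(g)
  A <- 5; mu <- 1.5
  a <- ascan(A * exp(-2 * mu * z), g,
             tail = list(prefactor = A, mu = mu))
  z_end <- z[g$n]
  expect_equal(tail_integral(a), A * exp(-2 * mu * z_end) / (2 * mu),
               tolerance = 1e-12)
})
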