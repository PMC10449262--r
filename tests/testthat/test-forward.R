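test_that("irradiance follows the piecewise Lambert-Beer closed form", {
  g <- depth_grid(0.001, 1500)
  # no attenuation
  ph0 <- homogeneous_phantom(mu = 0.0, R = 0.005)
  ph0$layers$mu <- 0
  expect_equal(irradiance(ph0, g), rep(ph0$beta_L0, g$n))
  # single layer: e^(-1) at 0.5 mm below the surface
  ph1 <- homogeneous_phantom(mu = 1, R = 0.005, beta_L0 = 1, surface = 0.1)
  bl <- irradiance(ph1, g)
  i <- which.min(abs(depths(g) - 0.6))
  expect_equal(bl[i], exp(-1), tolerance = 1e-12)
  expect_true(all(diff(bl) <= 0))
  # two layers: e^(-1) * e^(-2) at 1.0 mm below the surface
  ph2 <- two_layer_phantom(mu = c(1, 2), thickness1 = 0.5, surface = 0)
  bl2 <- irradiance(ph2, g)
  j <- which.min(abs(depths(g) - 1.0))
  expect_equal(bl2[j], exp(-1) * exp(-2), tolerance = 1e-12)
})

test_that("irradiance agrees with fine-step quadrature", {
  ph <- phantom_two()
  fine <- depth_grid(0.0001, 20001)
  z <- depths(fine)
  # midpoint-rule oracle (exact for a piecewise-constant integrand)
  mid <- phantom_profile(ph, depth_grid(0.0001, 20000, z0 = 0.00005))$mu
  bl_quad <- ph$beta_L0 * exp(-2 * c(0, cumsum(mid * 0.0001)))
  expect_equal(irradiance(ph, fine), bl_quad, tolerance = 1e-9)
})

test_that("simulated A-lines obey the single-scattering model", {
  ph <- homogeneous_phantom(mu = 1, R = 0.005, beta_L0 = 1, surface = 0)
  a <- simulate_aline(ph, depth_grid(0.001, 2000))
  expect_equal(a$values[1], 0.01)             # 2 R mu betaL0 at the surface
  # log-linear decay with slope -2 mu inside the layer
  z <- depths(a$grid)
  fit <- lm.fit(cbind(1, z[10:1990]), log(a$values[10:1990]))
  expect_equal(-coef(fit)[[2]] / 2, 1, tolerance = 1e-9)
  # zero-scattering phantom gives zero intensity
  ph0 <- homogeneous_phantom(mu = 1, R = 0.005)
  ph0$layers$mu <- 0
  expect_true(all(simulate_aline(ph0, depth_grid(0.001, 500))$values == 0))
})

test_that("per-layer log-slopes of the four-layer phantom equal -2 mu", {
  ph <- phantom_two()
  a <- simulate_aline(ph)
  z <- depths(a$grid)
  bounds <- c(0.125, 0.625, 1.125, 1.625, 2.4)
  for (j in 1:4) {
    idx <- which(z > bounds[j] + 0.005 & z < bounds[j + 1] - 0.005)
    fit <- lm.fit(cbind(1, z[idx]), log(a$values[idx]))
    expect_equal(-coef(fit)[[2]] / 2, ph$layers$mu[j], tolerance = 1e-6)
  }
})

test_that("energy identity: integral of I/R recovers beta_L0", {
  ph <- homogeneous_phantom(mu = 1, R = 0.005, beta_L0 = 2.5, surface = 0.05)
  a <- simulate_aline(ph)
  z <- depths(a$grid)
  prof <- phantom_profile(ph, a$grid)
  i0 <- which(a$values > 0)[1]
  g <- (a$values / ifelse(is.na(prof$R), 1, prof$R))[i0:a$grid$n]
  total <- pracma::trapz(z[i0:a$grid$n], g) + tail_integral(a) / 0.005
  expect_equal(total, ph$beta_L0, tolerance = 1e-6)
  # layered case, looser tolerance from trapezoid error at larger mu
  ph2 <- phantom_two()
  a2 <- simulate_aline(ph2)
  prof2 <- phantom_profile(ph2, a2$grid)
  j0 <- which(a2$values > 0)[1]
  g2 <- (a2$values / ifelse(is.na(prof2$R), 1, prof2$R))[j0:a2$grid$n]
  total2 <- pracma::trapz(depths(a2$grid)[j0:a2$grid$n], g2) +
    tail_integral(a2) / ph2$layers$R[4]
  # trapezoid straddles the on-grid attenuation steps: O(d mu * dz) error
  expect_equal(total2, ph2$beta_L0, tolerance = 5e-4)
})

test_that("the four-layer fixture matches its printed configuration", {
  ph <- phantom_two()
  expect_equal(nrow(ph$layers), 4)
  expect_equal(ph$layers$R[2], 0.007)
  expect_equal(ph$layers$R, c(0.005, 0.007, 0.006, 0.004))
  expect_equal(ph$layers$thickness[1:3], rep(0.5, 3))
  expect_equal(ph$surface_depth, 0.125)
  expect_equal(ph$beta_L0, 2.07e-5)
  # overridable attenuation stays a valid phantom
  ph_flat <- phantom_two(mu = rep(2, 4))
  expect_s3_class(ph_flat, "phantom_spec")
  expect_equal(ph_flat$layers$mu, rep(2, 4))
})

test_that("phantom_grid reaches the requested decay floor", {
  ph <- phantom_two()
  g <- phantom_grid(ph, decay_floor = 1e-12)
  bl <- irradiance(ph, g)
  expect_lt(bl[g$n] / ph$beta_L0, 1e-11)
  expect_gt(bl[g$n - 50] / ph$beta_L0, 1e-13)
})
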