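test_that("baseline attenuation is exact for constant backscatter", {
  for (mu in c(0.3, 1, 4)) {
    ph <- homogeneous_phantom(mu = mu, R = 0.005)
    a <- simulate_aline(ph)
    m <- vermeer_mu(a)
    interior <- depths(a$grid) > 0.12 & depths(a$grid) < 2
    expect_lt(max(abs(m[interior] - mu) / mu), 1e-4)
  }
  # all-zero profile degrades gracefully
  g <- depth_grid(0.001, 50)
  expect_warning(m0 <- vermeer_mu(ascan(numeric(50), g)), "all-zero")
  expect_true(all(m0 == 0))
})

test_that("baseline attenuation is biased above a backscatter step", {
  ph <- two_layer_phantom(mu = c(1, 1), R = c(0.005, 0.007))
  a <- simulate_aline(ph)
  m <- vermeer_mu(a)
  z <- depths(a$grid)
  above <- z > 0.15 & z < 0.55                  # R steps up below
  below <- z > 0.75 & z < 2.5
  expect_lt(mean(m[above]), 1)                  # underestimates upstream
  expect_equal(mean(m[below]), 1, tolerance = 1e-4)  # exact downstream
})

test_that("pointwise backscatter inversion recovers R given true mu", {
  ph <- homogeneous_phantom(mu = 2, R = 0.0045, beta_L0 = 3)
  a <- simulate_aline(ph)
  prof <- phantom_profile(ph, a$grid)
  R0 <- init_R(a, prof$mu, 3)
  interior <- depths(a$grid) > 0.12 & depths(a$grid) < 2.5
  expect_lt(max(abs(R0[interior] - 0.0045) / 0.0045), 1e-4)
  expect_error(init_R(a, prof$mu, -1), "beta_L0")
  expect_error(init_R(a, rep(0, a$grid$n), 3), "undefined")
})

test_that("backscatter inversion with the biased baseline flattens R", {
  # the coefficient of variation across layers collapses relative to truth
  ph <- phantom_two()
  a <- simulate_aline(ph)
  R0 <- init_R(a, vermeer_mu(a), ph$beta_L0)
  truth <- phantom_profile(ph, a$grid)$R
  z <- depths(a$grid)
  sel <- z > 0.15 & z < 2.2
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(R0[sel]), 0.1 * cv(truth[sel]))
})

test_that("mean backscatter is the irradiance-weighted layer average", {
  ph <- homogeneous_phantom(mu = 1.7, R = 0.005)
  a <- simulate_aline(ph)
  expect_equal(mean_R(a, ph$beta_L0), 0.005, tolerance = 1e-4)
  expect_equal(mean_R(ascan(numeric(100), depth_grid(0.001, 100)), 1), 0)
  ph2 <- phantom_two()
  a2 <- simulate_aline(ph2)
  rt <- mean_R(a2, ph2$beta_L0)
  expect_gt(rt, min(ph2$layers$R))
  expect_lt(rt, max(ph2$layers$R))
  # brute-force weighted-mean oracle
  prof <- phantom_profile(ph2, a2$grid)
  w <- irradiance(ph2, a2$grid) * prof$mu
  oracle <- sum(w * prof$R, na.rm = TRUE) / sum(w[!is.na(prof$R)])
  expect_equal(rt, oracle, tolerance = 0.02)
})

test_that("layer-resolved fits recover attenuation and backscatter", {
  ph <- homogeneous_phantom(mu = 3, R = 0.005, beta_L0 = 1, surface = 0.1)
  a <- simulate_aline(ph)
  win <- layer_window(0.2, 0.8)
  expect_equal(layer_mu_fit(a, win), 3, tolerance = 1e-6)
  bl_z1 <- irradiance(ph, a$grid)[which.min(abs(depths(a$grid) - 0.2))]
  expect_equal(layer_R_fit(a, win, 3, bl_z1), 0.005, tolerance = 1e-4)
  expect_equal(layer_R_fit(a, win, 3, bl_z1, convention = "as-printed"),
               0.010, tolerance = 1e-4)
  expect_error(layer_R_fit(a, win, -1, bl_z1), "mu_g")
  expect_error(layer_mu_fit(a, layer_window(0.2, 0.202)), "5")
})

test_that("a window straddling an attenuation step fits in between", {
  # R chosen so the product R*mu (hence the intensity) is continuous at
  # the interface and only the decay rate changes
  ph <- two_layer_phantom(mu = c(1, 3), R = c(0.006, 0.002),
                          thickness1 = 0.5, surface = 0)
  a <- simulate_aline(ph)
  m <- layer_mu_fit(a, layer_window(0.25, 0.75))
  expect_gt(m, 1); expect_lt(m, 3)
})

test_that("phase-function backscatter matches the cone closed form", {
  iso <- function(th) rep(1, length(th))
  closed <- function(na) (1 - sqrt(1 - na^2)) / 2
  expect_equal(phase_R(iso, 0.05), closed(0.05), tolerance = 1e-9)
  expect_equal(phase_R(iso, 0.999), closed(0.999), tolerance = 1e-6)
  # forward-only scattering contributes nothing to the backward cone
  fwd <- function(th) exp(-(th / 0.1)^2)
  expect_lt(phase_R(fwd, 0.05), 1e-12)
  # monotone in the aperture
  hg <- hg_phase(0.8)
  nas <- c(0.02, 0.05, 0.1, 0.3, 0.6)
  vals <- vapply(nas, function(na) phase_R(hg, na), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("anisotropy quadrature reproduces known mean cosines", {
  iso <- function(th) rep(1, length(th))
  expect_equal(phase_g(iso), 0, tolerance = 1e-12)
  for (g in c(0.3, 0.9, 0.97)) {
    expect_equal(phase_g(hg_phase(g)), g, tolerance = 1e-6)
  }
  near_delta <- function(th) exp(-(th / 0.01)^2)
  expect_gt(phase_g(near_delta), 0.999)
  # tabulated form works too
  th <- seq(0, pi, length.out = 2000)
  expect_equal(phase_g(data.frame(theta = th, gamma = hg_phase(0.5)(th))),
               0.5, tolerance = 1e-3)
})
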