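test_that("fuzzy processing keeps large steps and averages small ones", {
  dz <- 0.001
  # constant profile: one segment, untouched
  fz0 <- fuzzy_process_R(rep(0.005, 200), dz)
  expect_equal(nrow(fz0$segments), 1)
  expect_equal(fz0$values, rep(0.005, 200))
  # clean two-step profile with small jitter: exactly two segments
  set.seed(1)
  prof <- c(rep(0.005, 100), rep(0.007, 100)) + runif(200, -1e-5, 1e-5)
  fz <- fuzzy_process_R(prof, dz)
  expect_equal(nrow(fz$segments), 2)
  expect_equal(sort(fz$segments$mean), c(0.005, 0.007), tolerance = 1e-2)
  expect_equal(fz$segments$mean[1], 0.005, tolerance = 1e-5 / 0.005)
  expect_equal(fz$segments$mean[2], 0.007, tolerance = 1e-5 / 0.007)
  # an overgrown threshold factor misses the step entirely
  fz80 <- fuzzy_process_R(prof, dz, deriv_factor = 80)
  expect_equal(nrow(fz80$segments), 1)
})

test_that("breakpoint zones join the deeper segment", {
  dz <- 0.001
  ramp <- c(rep(0.005, 80), seq(0.005, 0.007, length.out = 6),
            rep(0.007, 80))
  fz <- fuzzy_process_R(ramp, dz)
  expect_equal(nrow(fz$segments), 2)
  # the transition pixels carry the deeper segment's label
  trans <- 81:86
  expect_true(all(fz$seg_id[trans] == fz$seg_id[120]))
  # and do not contaminate the shallow mean
  expect_equal(fz$segments$mean[1], 0.005, tolerance = 1e-9)
})

test_that("attenuation update is exact given the true backscatter", {
  ph <- phantom_two()
  a <- simulate_aline(ph)
  prof <- phantom_profile(ph, a$grid)
  z <- depths(a$grid)
  sup <- a$values > 0
  R_true <- prof$R
  R_true[!sup] <- ph$layers$R[1]
  mu1 <- update_mu(a, R_true, mode = "ratio", support = sup)
  interior <- z > 0.15 & z < 2.2 &
    !(abs(z - 0.625) < 0.05 | abs(z - 1.125) < 0.05 |
        abs(z - 1.625) < 0.05)
  # residual O(dz) trapezoid error from integrating across the on-grid
  # intensity jumps propagates to depths above each interface
  expect_lt(max(abs(mu1[interior] - prof$mu[interior]) / prof$mu[interior]),
            2e-3)
  # constant backscatter collapses the update onto the baseline
  R_flat <- rep(0.005, a$grid$n)
  mu_flat <- update_mu(a, R_flat, mode = "ratio", support = sup)
  v <- vermeer_mu(a)
  idx <- sup & v > 0 & a$values > max(a$values) * 1e-9
  expect_equal(mu_flat[idx], v[idx], tolerance = 1e-6)
})

test_that("correction-mode bias term follows the sign of the R step", {
  ph_up <- two_layer_phantom(mu = c(1, 1), R = c(0.005, 0.007))
  ph_dn <- two_layer_phantom(mu = c(1, 1), R = c(0.007, 0.005))
  for (case in list(list(ph = ph_up, sign = 1),
                    list(ph = ph_dn, sign = -1))) {
    a <- simulate_aline(case$ph)
    prof <- phantom_profile(case$ph, a$grid)
    sup <- a$values > 0
    R <- prof$R; R[!sup] <- case$ph$layers$R[1]
    base <- vermeer_mu(a)
    mu_corr <- update_mu(a, R, mode = "correction", mu_prev = base,
                         support = sup)
    z <- depths(a$grid)
    above <- z > 0.2 & z < 0.55
    # upward R step deepens the correction above it and vice versa
    expect_equal(sign(mean(mu_corr[above] - base[above])), case$sign)
  }
})

test_that("ratio and correction updates agree on two-layer fixtures", {
  ph <- two_layer_phantom(mu = c(1, 2), R = c(0.005, 0.007))
  a <- simulate_aline(ph)
  prof <- phantom_profile(ph, a$grid)
  sup <- a$values > 0
  R <- prof$R; R[!sup] <- ph$layers$R[1]
  mu_r <- update_mu(a, R, mode = "ratio", support = sup)
  mu_c <- update_mu(a, R, mode = "correction",
                    mu_prev = phantom_profile(ph, a$grid)$mu, support = sup)
  z <- depths(a$grid)
  interior <- z > 0.2 & z < 2 & abs(z - 0.6) > 0.05
  expect_lt(max(abs(mu_r[interior] - mu_c[interior]) / mu_c[interior]),
            0.05)
})

test_that("constant backscatter degenerates the solver to the baseline", {
  set.seed(99)
  for (i in 1:20) {
    mu <- runif(1, 0.3, 4)
    R <- runif(1, 0.002, 0.02)
    bl0 <- 10^runif(1, -4, 1)
    ph <- homogeneous_phantom(mu = mu, R = R, beta_L0 = bl0,
                              surface = runif(1, 0.02, 0.3))
    a <- simulate_aline(ph)
    st <- solve_aline(a, bl0)
    expect_equal(st$stop_reason, "converged")
    expect_equal(st$k, 1)
    expect_equal(nrow(st$segments), 1)
    sup <- st$support
    expect_equal(st$mu[sup], st$mu0[sup], tolerance = 1e-12)
  }
})

test_that("the iteration recovers layered optical properties", {
  res <- solve_layer_errors(phantom_two())
  expect_true(all(res$R_err < 0.1))
  expect_true(all(res$mu_err < 0.1))
  # and tightly in the noise-free setting
  expect_true(all(res$R_err < 0.03))
  expect_true(all(res$mu_err < 0.03))
  # recovery holds for the companion phantom too
  res1 <- solve_layer_errors(phantom_one())
  expect_true(all(res1$R_err < 0.1))
  expect_true(all(res1$mu_err < 0.1))
})

test_that("iteration state always satisfies its invariants", {
  for (ph in list(phantom_two(), phantom_one(),
                  two_layer_phantom(mu = c(2, 0.8), R = c(0.004, 0.009)))) {
    a <- simulate_aline(ph)
    st <- solve_aline(a, ph$beta_L0)
    cfg <- iteration_config()
    expect_lte(st$k, cfg$E)
    expect_true(all(is.finite(st$history)))
    sup <- st$support
    expect_true(all(st$R[sup] > 0 & st$R[sup] < 1))
    expect_true(all(st$segments$mean > 0))
    expect_true(all(st$mu[sup] >= cfg$C * st$mu0[sup] - 1e-12))
    expect_true(all(st$mu[sup] <= cfg$D * st$mu0[sup] + 1e-12))
    expect_true(all(st$mu[!sup] == 0))
  }
})

test_that("invalid iteration configurations are rejected", {
  expect_error(iteration_config(E = 0))
  expect_error(iteration_config(A = 2))
  expect_error(iteration_config(C = 1.5))
})

test_that("columnwise solving maps B-scans and records failures", {
  ph <- phantom_two()
  a <- simulate_aline(ph, depth_grid(0.001, 3000))
  vals <- cbind(a$values, a$values, 0)
  b <- bscan(vals, a$grid)
  out <- suppressWarnings(solve_bscan(b, ph$beta_L0))
  expect_equal(out$mu[, 1], out$mu[, 2])
  expect_equal(out$R[, 1], out$R[, 2])
  expect_equal(out$failed, 3L)
  expect_true(all(out$mu[, 3] == 0))
  expect_gt(max(out$mu[, 1]), 0)
})
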