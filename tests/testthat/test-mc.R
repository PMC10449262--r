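test_that("the retinal scene carries the layered tissue model", {
  sc <- retina_scene()
  expect_equal(nrow(sc$layers), 13)
  ilm <- sc$layers[1, ]
  expect_equal(ilm$d_um, 6)
  expect_equal(ilm$n, 1.47)
  expect_equal(ilm$mua_percm, 0.37)
  expect_equal(ilm$mus_percm, 120)
  expect_equal(ilm$g, 0.97)
  onl <- sc$layers[sc$layers$name == "ONL", ]
  expect_equal(onl$d_um, 60)
  expect_equal(onl$mus_percm, 110)
  expect_equal(onl$g, 0.98)
  expect_equal(sc$detector_na, 0.05)
  expect_equal(sc$l_coh_um, 5)
  expect_equal(sc$lateral_step_mm, 0.01)
})

test_that("free propagation transmits every packet", {
  sc <- mc_scene(mc_layer(1000, 1, 0, 0, 0), detector_na = 0.05)
  res <- mc_transport(sc, 500, seed = 3)
  expect_equal(res$transmitted, 500)
  expect_equal(res$reflected + res$absorbed + res$specular, 0)
})

test_that("the photon weight ledger balances to machine precision", {
  for (args in list(list(sc = retina_scene(), n = 20000),
                    list(sc = mc_scene(mc_layer(500, 1.4, 5, 100, 0.8)),
                         n = 10000))) {
    res <- mc_transport(args$sc, args$n, seed = 5)
    budget <- res$specular + res$reflected + res$transmitted + res$absorbed
    expect_lt(abs(budget - args$n) / args$n, 1e-6)
  }
})

test_that("transport is bit-reproducible for a fixed seed", {
  sc <- retina_scene()
  r1 <- mc_transport(sc, 5000, seed = 42)
  r2 <- mc_transport(sc, 5000, seed = 42)
  expect_identical(r1$detected, r2$detected)
  expect_identical(r1$absorbed, r2$absorbed)
  r3 <- mc_transport(sc, 5000, seed = 43)
  expect_false(identical(r1$detected, r3$detected))
})

test_that("detected weight grows with the numerical aperture", {
  base <- retina_scene()
  got <- vapply(c(0.02, 0.05, 0.1, 0.2), function(na) {
    sc <- mc_scene(base$layers, detector_na = na)
    sum(mc_transport(sc, 5000, seed = 11)$detected$weight)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("an absorbing slab over a mirror follows Beer-Lambert", {
  # analog detection; attenuation of the double pass fitted across mua
  muas <- c(1, 3, 6)     # 1/cm over a 0.5 mm slab
  d <- 0.05              # cm
  got <- vapply(muas, function(mua) {
    sc <- mc_scene(rbind(mc_layer(500, 1.47, mua, 0, 0),
                         mc_layer(50, 9999, 0, 0, 0)),
                   detector_na = 0.05)
    res <- mc_transport(sc, 20000, seed = 8, local_est = FALSE)
    sum(res$detected$weight)
  }, numeric(1))
  fit <- lm.fit(cbind(1, muas), log(got))
  slope <- -coef(fit)[[2]]
  expect_equal(slope, 2 * d, tolerance = 0.05)
})

test_that("coherence envelopes land at half the optical path", {
  g <- depth_grid(0.0007, 800)
  res <- fake_mc_result(delta_z = 0.3, weight = 1, n_group = 1.5)
  al <- synthesize_aline(res, g, l_coh = 0.005)
  peak_depth <- depths(g)[which.max(al$values)]
  expect_lt(abs(peak_depth - 0.3 / (2 * 1.5)), 0.0008)
  # 1/e half-width of the bump equals l_coh on the optical axis
  half <- al$values > max(al$values) * exp(-1)
  width_opt <- sum(half) * 0.0007 * 2 * 1.5
  expect_equal(width_opt, 2 * 0.005, tolerance = 0.15)
  # two well-separated equal photons give two equal bumps
  res2 <- fake_mc_result(delta_z = c(0.3, 0.9), weight = c(1, 1),
                         n_group = 1.5)
  al2 <- synthesize_aline(res2, g, l_coh = 0.005)
  z <- depths(g)
  # compare bump integrals (peak samples fall off-grid differently)
  b1 <- sum(al2$values[abs(z - 0.1) < 0.02])
  b2 <- sum(al2$values[abs(z - 0.3) < 0.02])
  expect_equal(b1, b2, tolerance = 1e-3)
  # empty detected set synthesizes silence
  expect_true(all(synthesize_aline(fake_mc_result(numeric(0), numeric(0)),
                                   g)$values == 0))
})

test_that("fringe-mode synthesis demodulates onto the envelope", {
  g <- depth_grid(0.0007, 400)
  res <- fake_mc_result(delta_z = 0.3, weight = 1, n_group = 1.5)
  env <- synthesize_aline(res, g, l_coh = 0.005, mode = "envelope")
  fr <- synthesize_aline(res, g, l_coh = 0.005, mode = "fringe")
  expect_lt(abs(depths(g)[which.max(fr$values)] -
                  depths(g)[which.max(env$values)]), 0.002)
})

test_that("B-scan simulation is reproducible and shows the bright band", {
  sc <- retina_scene()
  sim <- simulate_mc_bscan(sc, 20000, 2, seed = 9)
  expect_equal(dim(sim$bscan$values), c(800L, 2L))
  sim2 <- simulate_mc_bscan(sc, 20000, 2, seed = 9)
  expect_identical(sim$bscan$values, sim2$bscan$values)
  # per-layer mean intensity ranks with the scattering coefficient for
  # the three strongest scatterers: RPE > choroid > sclera
  avg <- rowMeans(sim$bscan$values)
  bands <- scene_bands(sc)
  m <- vapply(c("RPE", "Choroid", "Sclera"), function(nm) {
    b <- bands[bands$name == nm, ]
    z <- depths(sim$bscan$grid)
    mean(avg[z >= b$top & z < min(b$bottom, max(z))])
  }, numeric(1))
  expect_true(m["RPE"] > m["Choroid"])
  expect_true(m["Choroid"] > m["Sclera"])
})
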