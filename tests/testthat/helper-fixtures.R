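# Shared builders for test fixtures (all generated in code).

homogeneous_phantom <- function(mu = 1, R = 0.005, beta_L0 = 1,
                                surface = 0.1) {
  phantom_spec(layer_spec(Inf, mu = mu, R = R), surface_depth = surface,
               beta_L0 = beta_L0)
}

two_layer_phantom <- function(mu = c(1, 1), R = c(0.005, 0.007),
                              thickness1 = 0.5, beta_L0 = 1,
                              surface = 0.1) {
  layers <- rbind(layer_spec(thickness1, mu[1], R[1]),
                  layer_spec(Inf, mu[2], R[2]))
  phantom_spec(layers, surface_depth = surface, beta_L0 = beta_L0)
}

# interior per-layer evaluation of a solved state against a phantom
solve_layer_errors <- function(phantom, config = iteration_config()) {
  a <- simulate_aline(phantom)
  st <- solve_aline(a, phantom$beta_L0, config)
  truth_mu <- phantom$layers$mu
  truth_R <- phantom$layers$R
  mu_hat <- layer_means(st$mu, phantom, a$grid, max_depth = 2.5)
  R_hat <- layer_means(st$R, phantom, a$grid, max_depth = 2.5)
  list(state = st, mu_hat = mu_hat, R_hat = R_hat,
       mu_err = abs(mu_hat - truth_mu) / truth_mu,
       R_err = abs(R_hat - truth_R) / truth_R)
}

# manual Monte Carlo result for synthesis tests
fake_mc_result <- function(delta_z, weight, n_group = 1.47) {
  structure(list(detected = data.frame(delta_z = delta_z, weight = weight),
                 specular = 0, reflected = sum(weight), transmitted = 0,
                 absorbed = 0, n_launched = length(delta_z), seed = 0L,
                 n_group = n_group),
            class = "mc_result")
}

# geometric bands of the five thick retinal layers used for evaluation
retina_eval_bands <- function() {
  data.frame(name = c("GCL", "IPL", "ONL", "OPR", "Choroid"),
             top = c(0.011, 0.030, 0.097, 0.173, 0.210),
             bot = c(0.030, 0.057, 0.157, 0.200, 0.280))
}

band_means <- function(values, grid, bands, margin = 0.003) {
  z <- depths(grid)
  vapply(seq_len(nrow(bands)), function(i) {
    sel <- z > bands$top[i] + margin & z < bands$bot[i] - margin
    mean(values[sel], na.rm = TRUE)
  }, numeric(1))
}
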