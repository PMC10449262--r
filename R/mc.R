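# Monte Carlo simulation of OCT A-lines for layered tissue.
#
# Photon packets are transported through horizontal layers by the
# classical weighted-walk scheme; packets that leave the top surface
# inside the detector radius and acceptance cone contribute their
# cumulative optical path and residual weight, and the A-line is the sum
# of coherence-gated Gaussian envelopes centred at each detected path.

#' Monte Carlo layer
#'
#' One layer of a transport scene, in the customary tissue-optics units
#' (thickness in micrometres, absorption/scattering per centimetre).
#'
#' @param d_um thickness, um.
#' @param n refractive index (>= 1).
#' @param mua_percm absorption coefficient, 1/cm.
#' @param mus_percm scattering coefficient, 1/cm.
#' @param g Henyey-Greenstein anisotropy, in (-1, 1).
#' @param name optional layer label.
#' @return A one-row data frame.
#' @export
mc_layer <- function(d_um, n, mua_percm, mus_percm, g, name = NA_character_) {
  stopifnot(d_um > 0, n >= 1, mua_percm >= 0, mus_percm >= 0,
            g > -1, g < 1)
  data.frame(name = name, d_um = d_um, n = n, mua_percm = mua_percm,
             mus_percm = mus_percm, g = g)
}

#' Monte Carlo scene
#'
#' Layered medium (air above) plus detection geometry.  Table units are
#' converted to mm and 1/mm internally.
#'
#' @param layers data frame of [mc_layer()] rows, top first.
#' @param detector_na acceptance numerical aperture, in (0, 1).
#' @param detector_radius_mm detector radius around the launch axis, mm
#'   (default one lateral step, 0.01 mm).
#' @param lateral_step_mm transversal scanning step, mm.
#' @param l_coh_um coherence length of the source, um.
#' @return An object of class `mc_scene`.
#' @export
mc_scene <- function(layers, detector_na = 0.05, detector_radius_mm = 0.01,
                     lateral_step_mm = 0.01, l_coh_um = 5) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1L,
            detector_na > 0, detector_na < 1, detector_radius_mm > 0)
  structure(list(layers = layers, detector_na = detector_na,
                 detector_radius_mm = detector_radius_mm,
                 lateral_step_mm = lateral_step_mm, l_coh_um = l_coh_um),
            class = "mc_scene")
}

#' @export
print.mc_scene <- function(x, ...) {
  cat(sprintf("<mc_scene> %d layers, NA = %g, l_coh = %g um\n",
              nrow(x$layers), x$detector_na, x$l_coh_um))
  invisible(x)
}

#' Thirteen-layer retinal scene
#'
#' The layered bovine-retina model used for end-to-end validation: inner
#' limiting membrane through sclera, with thicknesses and optical
#' properties (absorption, scattering, anisotropy) of each sublayer, a
#' detection numerical aperture of 0.05, a 5 um coherence length and a
#' 10 um transversal step.
#'
#' @return An [mc_scene()].
#' @export
retina_scene <- function() {
  layers <- rbind(
    mc_layer(6,   1.47, 0.37, 120,  0.97, "ILM"),
    mc_layer(5,   1.47, 0.37, 120,  0.97, "RNFL"),
    mc_layer(19,  1.47, 0.40, 114,  0.97, "GCL"),
    mc_layer(27,  1.47, 0.37, 134,  0.98, "IPL"),
    mc_layer(20,  1.47, 0.34, 130,  0.97, "INL"),
    mc_layer(20,  1.47, 0.38, 166,  0.98, "OPL"),
    mc_layer(60,  1.47, 0.31, 110,  0.98, "ONL"),
    mc_layer(4,   1.47, 0.38, 136,  0.97, "ELM"),
    mc_layer(12,  1.47, 0.29, 134,  0.97, "IPR"),
    mc_layer(27,  1.47, 0.90, 357,  0.93, "OPR"),
    mc_layer(10,  1.47, 80,   1700, 0.84, "RPE"),
    mc_layer(250, 1.47, 0.75, 500,  0.94, "Choroid"),
    mc_layer(700, 1.47, 0.10, 420,  0.90, "Sclera"))
  mc_scene(layers, detector_na = 0.05, detector_radius_mm = 0.01,
           lateral_step_mm = 0.01, l_coh_um = 5)
}

#' Transport photon packets through a scene
#'
#' Launches `n_photons` pencil-beam packets at the top surface and
#' returns the detected packets (cumulative optical path difference and
#' residual weight) together with the weight ledger.  Deterministic for a
#' fixed seed.  The Russian-roulette weight boost is booked against the
#' absorbed tally, so the ledger `specular + reflected + transmitted +
#' absorbed = n_launched` holds exactly per run, not just in expectation.
#'
#' @param scene an [mc_scene()].
#' @param n_photons number of packets (>= 1).
#' @param seed RNG seed (integer); set before the run.
#' @param roulette_thresh weight below which roulette triggers.
#' @param roulette_surv survival probability of roulette.
#' @param local_est use the local (point-detector) estimator: at every
#'   scattering event inside the detector radius, tally the analytic
#'   expectation of backscattering into the acceptance cone and escaping
#'   ballistically.  This classical variance-reduction estimator makes
#'   the path-resolved signal usable at desk-scale photon counts; the
#'   tiny analog acceptance of a low-NA gate would otherwise detect
#'   almost nothing.  Set to `FALSE` for fully analog detection.
#' @param opl_bin optical-path bin width for the local estimator, mm
#'   (default one fifth of the coherence length, well below the gate).
#' @return An object of class `mc_result`: `detected` (data frame with
#'   `delta_z` in optical mm and `weight`), totals `specular`,
#'   `reflected`, `transmitted`, `absorbed`, plus `n_launched` and
#'   `seed`.  With `local_est` the detected set holds expected weights
#'   per optical-path bin; the analog ledger is unaffected either way.
#' @export
mc_transport <- function(scene, n_photons, seed = 1L,
                         roulette_thresh = 1e-4, roulette_surv = 0.1,
                         local_est = TRUE, opl_bin = NULL) {
  stopifnot(inherits(scene, "mc_scene"), n_photons >= 1)
  set.seed(seed)
  lay <- scene$layers
  if (is.null(opl_bin)) opl_bin <- scene$l_coh_um / 5000
  opl_max <- 2 * sum(lay$n * lay$d_um / 1000) + 0.5
  res <- mc_transport_cpp(lay$d_um / 1000, lay$n, lay$mua_percm / 10,
                          lay$mus_percm / 10, lay$g, as.integer(n_photons),
                          scene$detector_radius_mm, scene$detector_na,
                          roulette_thresh, roulette_surv,
                          isTRUE(local_est), opl_bin, opl_max)
  out <- structure(list(
    detected = data.frame(delta_z = res$delta_z, weight = res$weight),
    specular = res$specular, reflected = res$reflected,
    transmitted = res$transmitted, absorbed = res$absorbed,
    n_launched = as.integer(n_photons), seed = seed,
    n_group = lay$n[1L]), class = "mc_result")
  budget <- res$specular + res$reflected + res$transmitted + res$absorbed
  if (abs(budget - n_photons) > 1e-6 * n_photons)
    warning(sprintf("weight ledger off by %.3g", budget - n_photons))
  out
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %d launched: %.1f%% reflected, %.1f%% transmitted, %.1f%% absorbed; %d detected\n",
    x$n_launched, 100 * x$reflected / x$n_launched,
    100 * x$transmitted / x$n_launched, 100 * x$absorbed / x$n_launched,
    nrow(x$detected)))
  invisible(x)
}

#' Coherence-gated A-line from detected photons
#'
#' Sums, over detected packets `i`, the Gaussian coherence envelope
#' `i0 * w_i * exp(-((z - delta_z_i) / l_coh)^2)` (reference-arm weight
#' taken as 1) onto the depth grid; the optional `"fringe"` mode keeps
#' the literal interferometric carrier `cos(k (z - delta_z_i))` and
#' demodulates the squared fringe signal with a Gaussian low-pass.  The
#' grid is geometric depth below the surface; each optical path maps to
#' geometric depth `delta_z / (2 n_group)` (round trip, group index).
#'
#' @param result an [mc_result()].
#' @param grid a [depth_grid()] of geometric depths, mm.
#' @param l_coh coherence length, mm (optical units).
#' @param i0 source intensity constant.
#' @param n_group group refractive index used for the depth mapping;
#'   defaults to the index of the scene's first layer.
#' @param mode `"envelope"` (default) or `"fringe"`.
#' @param wavenumber carrier wavenumber `k` for `"fringe"`, 1/mm.
#' @return An [ascan()].
#' @export
synthesize_aline <- function(result, grid, l_coh = 0.005, i0 = 1,
                             n_group = NULL,
                             mode = c("envelope", "fringe"),
                             wavenumber = 2 * pi / 1.06e-3) {
  stopifnot(inherits(result, "mc_result"), inherits(grid, "depth_grid"))
  mode <- match.arg(mode)
  if (is.null(n_group)) n_group <- result$n_group
  if (nrow(result$detected) == 0L)
    return(ascan(numeric(grid$n), grid))
  z_opt <- 2 * n_group * depths(grid)
  dzv <- result$detected$delta_z
  beyond <- dzv > max(z_opt) + 3 * l_coh
  if (sum(result$detected$weight[beyond]) >
        0.05 * sum(result$detected$weight))
    warning("grid truncates a non-negligible part of the detected paths")
  if (mode == "envelope") {
    vals <- synth_envelope_cpp(dzv, result$detected$weight, z_opt, l_coh, i0)
  } else {
    w <- result$detected$weight
    fr <- vapply(z_opt, function(zo) {
      u <- (zo - dzv) / l_coh
      sum(i0 * w * cos(wavenumber * (zo - dzv)) * exp(-u * u))
    }, numeric(1))
    sq <- fr^2
    # Gaussian low-pass over one coherence length removes the carrier
    half <- max(1L, ceiling(3 * l_coh / (2 * n_group * grid$dz)))
    kern <- exp(-((-half:half) * 2 * n_group * grid$dz / l_coh)^2)
    kern <- kern / sum(kern)
    vals <- 2 * as.numeric(stats::filter(sq, kern, sides = 2))
    vals[is.na(vals)] <- sq[is.na(vals)] * 2
  }
  ascan(pmax(vals, 0), grid)
}

#' Simulate a Monte Carlo B-scan
#'
#' Repeats [mc_transport()] plus [synthesize_aline()] for `n_alines`
#' lateral positions with independently seeded streams (`seed + j - 1`
#' for column `j`); the scene is laterally homogeneous, so columns are
#' statistically independent replicates.  No axial focus or sensitivity
#' roll-off is applied.
#'
#' @param scene an [mc_scene()].
#' @param n_photons photon packets per A-line.
#' @param n_alines number of A-lines.
#' @param seed base RNG seed.
#' @param grid depth grid; defaults to 800 samples at 0.7 um.
#' @param i0 source intensity constant.
#' @return A list with the [bscan()] (`bscan`) and the per-column
#'   [mc_transport()] results (`results`).
#' @export
simulate_mc_bscan <- function(scene, n_photons, n_alines, seed = 1L,
                              grid = depth_grid(0.0007, 800L), i0 = 1) {
  stopifnot(inherits(scene, "mc_scene"), n_alines >= 1)
  l_coh <- scene$l_coh_um / 1000
  vals <- matrix(0, grid$n, n_alines)
  results <- vector("list", n_alines)
  for (j in seq_len(n_alines)) {
    res <- mc_transport(scene, n_photons, seed = seed + j - 1L)
    results[[j]] <- res
    vals[, j] <- synthesize_aline(res, grid, l_coh = l_coh, i0 = i0)$values
  }
  list(bscan = bscan(vals, grid, scene$lateral_step_mm), results = results)
}

#' Geometric depth bands of a scene's layers
#'
#' Cumulative layer boundaries in mm below the surface, convenient for
#' defining evaluation windows on synthesized A-lines.
#'
#' @param scene an [mc_scene()].
#' @return Data frame with `name`, `top`, `bottom` (mm).
#' @export
scene_bands <- function(scene) {
  d <- scene$layers$d_um / 1000
  top <- c(0, cumsum(d)[-length(d)])
  data.frame(name = scene$layers$name, top = top, bottom = top + d)
}
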