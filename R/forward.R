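# Single-scattering forward model.
#
# Within the single-scattering picture the irradiance obeys Lambert-Beer,
#   L(z) = L(0) exp(-2 int_0^z mu(u) du),
# and the detected linear intensity is
#   I(z) = 2 R(z) mu(z) beta L(z).
# For piecewise-constant layers both are available in closed form, which
# makes this module the exact oracle against which the estimators are
# validated.  No speckle, noise floor or focus effects are produced here;
# those degradations are composed on top by the fixtures module.

#' Layered digital phantom
#'
#' @param layers data frame with columns `thickness` (mm), `mu` (1/mm) and
#'   `R` (unitless), ordered from the surface downwards; build rows with
#'   [layer_spec()].  Only the final layer may have infinite thickness.
#' @param surface_depth depth of the sample surface below the detector
#'   reference, mm (non-negative).
#' @param beta_L0 digitized incident irradiance `beta * L(0)`, A.U. * mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(layers, surface_depth = 0, beta_L0 = 1) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1L,
            all(c("thickness", "mu", "R") %in% names(layers)))
  if (any(layers$thickness <= 0)) stop("layer thicknesses must be positive")
  if (any(!is.finite(layers$thickness[-nrow(layers)])))
    stop("only the final layer may be unbounded")
  stopifnot(all(layers$mu >= 0), all(layers$R > 0), all(layers$R < 1))
  stopifnot(surface_depth >= 0, beta_L0 > 0)
  structure(list(layers = layers, surface_depth = surface_depth,
                 beta_L0 = beta_L0),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d layers, surface at %g mm, beta_L0 = %g\n",
              nrow(x$layers), x$surface_depth, x$beta_L0))
  print(x$layers)
  invisible(x)
}

# Layer interface depths: surface, then each internal boundary.
layer_bounds <- function(phantom) {
  th <- phantom$layers$thickness
  phantom$surface_depth + c(0, cumsum(th[-length(th)]))
}

# Closed-form cumulative attenuation int_0^z mu(u) du for arbitrary z.
cumulative_mu <- function(phantom, z) {
  bounds <- layer_bounds(phantom)
  mu <- phantom$layers$mu
  upper <- c(bounds[-1], Inf)
  vapply(z, function(zz)
    sum(mu * pmax(0, pmin(zz, upper) - bounds)), numeric(1))
}

# Layer index at each depth (0 above the surface).
layer_index <- function(phantom, z) {
  bounds <- layer_bounds(phantom)
  findInterval(z, bounds)
}

#' Closed-form irradiance profile
#'
#' Evaluates `beta L(z) = beta L(0) exp(-2 int_0^z mu)` on a grid.  Above
#' the surface the irradiance equals `beta L(0)`; inside it follows the
#' piecewise-exponential closed form and is strictly non-increasing.
#'
#' @param phantom a [phantom_spec()].
#' @param grid a [depth_grid()] covering the phantom surface.
#' @return Numeric vector of `beta L(z)` values (A.U. * mm).
#' @export
irradiance <- function(phantom, grid) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(grid, "depth_grid"))
  z <- depths(grid)
  if (max(z) < phantom$surface_depth)
    stop("grid does not reach the phantom surface")
  phantom$beta_L0 * exp(-2 * cumulative_mu(phantom, z))
}

#' Grid deep enough for a phantom's decay
#'
#' Chooses the number of samples so that the irradiance at the deepest
#' sample has fallen below `decay_floor * beta_L0`.  An unbounded bottom
#' layer is thereby realized with a finite array plus the analytic
#' exponential tail attached by [simulate_aline()].
#'
#' @param phantom a [phantom_spec()].
#' @param dz axial pitch, mm.
#' @param z0 first sample depth, mm.
#' @param decay_floor irradiance fraction at which the grid may stop.
#' @return A [depth_grid()].
#' @export
phantom_grid <- function(phantom, dz = 0.001, z0 = 0, decay_floor = 1e-12) {
  stopifnot(decay_floor > 0, decay_floor < 1)
  bounds <- layer_bounds(phantom)
  mu <- phantom$layers$mu
  need <- -log(decay_floor) / 2                 # required int mu
  acc <- cumulative_mu(phantom, max(bounds))
  mu_bot <- mu[length(mu)]
  z_end <- if (acc >= need) {
    # enough attenuation before the bottom layer: invert piecewise
    upper <- c(bounds[-1], Inf)
    cum <- cumsum(mu * (pmin(upper, max(bounds)) - bounds))
    j <- which(c(0, cum[-length(cum)]) < need & cum >= need)[1]
    bounds[j] + (need - c(0, cum)[j]) / mu[j]
  } else if (mu_bot > 0) {
    max(bounds) + (need - acc) / mu_bot
  } else {
    sum(phantom$layers$thickness[is.finite(phantom$layers$thickness)]) +
      phantom$surface_depth + 1
  }
  depth_grid(dz, ceiling((z_end - z0) / dz) + 1L, z0)
}

#' Simulate a noise-free single-scattering A-line
#'
#' Evaluates `I(z) = 2 R(z) mu(z) beta L(z)` pointwise from the
#' closed-form irradiance (no finite differencing, so the only error is
#' the grid sampling itself).  `I` is zero above the surface and, within
#' each layer, `log I` is linear in depth with slope `-2 mu`.  The
#' returned A-scan carries the exact analytic tail of the bottom layer so
#' that semi-infinite integrals are available in closed form.
#'
#' @param phantom a [phantom_spec()].
#' @param grid optional [depth_grid()]; defaults to [phantom_grid()] at
#'   pitch `dz`.
#' @param dz axial pitch used when `grid` is not supplied, mm.
#' @return An [ascan()] with an analytic tail.
#' @examples
#' ph <- phantom_spec(layer_spec(Inf, mu = 1, R = 0.005), beta_L0 = 1)
#' a <- simulate_aline(ph, dz = 0.002)
#' a$values[1] # 2 * 0.005 * 1 * 1 = 0.01 at the surface
#' @export
simulate_aline <- function(phantom, grid = NULL, dz = 0.001) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (is.null(grid)) grid <- phantom_grid(phantom, dz = dz)
  z <- depths(grid)
  li <- layer_index(phantom, z)
  mu <- ifelse(li > 0, phantom$layers$mu[pmax(li, 1L)], 0)
  R <- ifelse(li > 0, phantom$layers$R[pmax(li, 1L)], NA_real_)
  bL <- irradiance(phantom, grid)
  vals <- ifelse(li > 0, 2 * R * mu * bL, 0)
  nl <- nrow(phantom$layers)
  mu_bot <- phantom$layers$mu[nl]
  tail <- NULL
  if (mu_bot > 0 && li[grid$n] == nl) {
    # I(z) = pref * exp(-2 mu_bot z) beyond the grid end
    pref <- vals[grid$n] * exp(2 * mu_bot * z[grid$n])
    tail <- list(prefactor = pref, mu = mu_bot)
  }
  ascan(vals, grid, tail = tail)
}

#' Ground-truth optical profile of a phantom
#'
#' Per-depth `mu` and `R` of a phantom sampled on a grid; `R` is `NA`
#' above the surface.
#'
#' @param phantom a [phantom_spec()].
#' @param grid a [depth_grid()].
#' @return An [optical_profile()].
#' @export
phantom_profile <- function(phantom, grid) {
  z <- depths(grid)
  li <- layer_index(phantom, z)
  mu <- ifelse(li > 0, phantom$layers$mu[pmax(li, 1L)], 0)
  R <- ifelse(li > 0, phantom$layers$R[pmax(li, 1L)], NA_real_)
  optical_profile(grid, mu, R)
}

#' Four-layer validation phantom with printed backscattering fractions
#'
#' The second of the two four-layer digital phantoms used to validate the
#' joint estimator: per-layer backscattering fractions 0.005, 0.007,
#' 0.006 and 0.004, the top three layers 0.5 mm thick, an unbounded
#' bottom layer, the surface at 0.125 mm, and `beta L(0) = 2.07e-2`
#' A.U. * pixel.  With the 1 um pitch this digitized irradiance converts
#' to `2.07e-5` A.U. * mm, which is the unit all integrals here use.  The
#' per-layer attenuation values are not part of the printed configuration
#' and default to 1, 2, 3 and 1.5 1/mm; they are exposed as parameters
#' because backscattering recovery is insensitive to the exact choice in
#' the noise-free model.
#'
#' @param mu per-layer attenuation coefficients, 1/mm.
#' @param R per-layer backscattering fractions.
#' @return A [phantom_spec()].
#' @export
phantom_two <- function(mu = c(1, 2, 3, 1.5),
                        R = c(0.005, 0.007, 0.006, 0.004)) {
  stopifnot(length(mu) == 4L, length(R) == 4L)
  layers <- data.frame(thickness = c(0.5, 0.5, 0.5, Inf), mu = mu, R = R)
  phantom_spec(layers, surface_depth = 0.125, beta_L0 = 2.07e-2 * 1e-3)
}

#' Companion four-layer phantom with rising-then-falling backscatter
#'
#' A synthetic companion to [phantom_two()] with the same geometry but a
#' different, unprinted property set (its published counterpart is shown
#' only graphically).  Used as a second scene when averaging recovery
#' errors over phantoms.
#'
#' @inheritParams phantom_two
#' @export
phantom_one <- function(mu = c(2, 1, 2.5, 1.2),
                        R = c(0.004, 0.0065, 0.008, 0.005)) {
  stopifnot(length(mu) == 4L, length(R) == 4L)
  layers <- data.frame(thickness = c(0.5, 0.5, 0.5, Inf), mu = mu, R = R)
  phantom_spec(layers, surface_depth = 0.125, beta_L0 = 2.07e-2 * 1e-3)
}
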