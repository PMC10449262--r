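# Closed-form and baseline estimators.
#
# The depth-resolved baseline attenuation estimate divides the intensity
# by twice its integral to infinity; it is exact whenever the
# backscattering fraction is constant in depth and biased otherwise.  The
# remaining operations invert the single-scattering intensity model for R
# (pointwise and layer-resolved) and derive R and the anisotropy g from a
# scattering phase function.

#' Depth-resolved baseline attenuation estimate
#'
#' `mu0(z) = I(z) / (2 * int_z^inf I(u) du)`, with the semi-infinite
#' integral taken as the trapezoid sum over the grid plus the analytic
#' exponential remainder carried by the A-scan.  Exact for constant
#' backscattering; under- or over-estimates the attenuation above depths
#' where the backscattering fraction changes.
#'
#' @param a an [ascan()], normally tail-extrapolated (see
#'   [extrapolate_tail()]) so that the infinite integral is defined.
#' @return Numeric vector of attenuation coefficients, 1/mm.  Where the
#'   integral denominator vanishes the estimate is set to 0 with a
#'   warning.
#' @export
vermeer_mu <- function(a) {
  stopifnot(inherits(a, "ascan"))
  if (max(a$values) <= 0) {
    warning("all-zero profile: attenuation undefined, returning zeros")
    return(numeric(a$grid$n))
  }
  den <- integral_to_inf(a)
  mu <- numeric(a$grid$n)
  ok <- den > 0
  mu[ok] <- a$values[ok] / (2 * den[ok])
  # zero denominators at depths with real signal deserve a warning;
  # floating-point cancellation in the fully decayed tail does not
  if (any(!ok & a$values > max(a$values) * 1e-9))
    warning("zero integral denominator: mu set to 0 at ", sum(!ok),
            " depth(s)")
  mu
}

#' Pointwise backscattering initialization
#'
#' Inverts the single-scattering intensity model for R given an
#' attenuation profile:
#' `R(z) = I(z) / (2 beta_L0 mu(z)) * exp(+2 int_0^z mu(u) du)`,
#' the cumulative integral running from the detector reference (the
#' attenuation profile is zero above the surface, so this equals the
#' integral from the surface).  Depths with `mu = 0` or zero intensity
#' are filled from the nearest defined neighbour.
#'
#' With `lag = 1` (the default used by the solver for segmentation), the
#' locally homogeneous portion behind the discrete model is taken as the
#' pixel pair `[z_i, z_i+1)`: the intensity one pixel deeper is divided
#' by the attenuation at `z_i`.  This reading leaves single-pixel marks
#' at layer interfaces, where the intensity jump between neighbouring
#' pixels is not explained by the local attenuation -- exactly the
#' change-point signal the fuzzy processing thresholds on.  `lag = 0`
#' evaluates both factors at the same pixel.
#'
#' @param a an [ascan()].
#' @param mu attenuation profile, 1/mm (vector on the same grid).
#' @param beta_L0 digitized initial irradiance, A.U. * mm (positive).
#' @param lag intensity look-ahead in pixels (0 or 1).
#' @return Numeric vector of backscattering fractions.
#' @export
init_R <- function(a, mu, beta_L0, lag = 0L) {
  stopifnot(inherits(a, "ascan"), length(mu) == a$grid$n)
  if (!(is.numeric(beta_L0) && beta_L0 > 0))
    stop("beta_L0 must be positive")
  if (any(mu < 0)) stop("mu must be non-negative")
  z <- depths(a$grid)
  cmu <- as.numeric(pracma::cumtrapz(z, mu))
  # anchor at the first attenuating sample: the trapezoid ramp across the
  # surface discontinuity would otherwise leak half a pixel of attenuation
  first_mu <- which(mu > 0)[1L]
  if (!is.na(first_mu)) cmu <- cmu - cmu[first_mu]
  I_use <- if (lag >= 1L) c(a$values[-1L], a$values[a$grid$n]) else a$values
  R <- rep(NA_real_, a$grid$n)
  ok <- mu > 0 & I_use > 0
  if (!any(ok)) stop("mu and intensity are zero everywhere: R is undefined")
  R[ok] <- I_use[ok] / (2 * beta_L0 * mu[ok]) * exp(2 * cmu[ok])
  # nearest-neighbour fill of undefined depths
  idx <- which(ok)
  as.numeric(approx(z[idx], R[idx], z, method = "constant", rule = 2)$y)
}

#' Mean backscattering fraction
#'
#' `R_tilde = int_0^inf I(z) dz / beta_L0`, the irradiance-weighted
#' average backscattering of the whole sample; anchors the plausibility
#' band for the iterated profile.
#'
#' @param a a tail-extrapolated [ascan()].
#' @param beta_L0 digitized initial irradiance, A.U. * mm.
#' @return Scalar mean backscattering fraction.
#' @export
mean_R <- function(a, beta_L0) {
  stopifnot(inherits(a, "ascan"), beta_L0 > 0)
  i0 <- which(a$values > 0)[1L]
  if (is.na(i0)) return(0)
  z <- depths(a$grid)
  idx <- i0:a$grid$n
  # integrate from the surface sample: the ramp pixel across the surface
  # discontinuity belongs to the air side
  (pracma::trapz(z[idx], a$values[idx]) + tail_integral(a)) / beta_L0
}

#' Depth window inside a grid
#'
#' @param z1,z2 window bounds in mm, `z1 < z2`, both inside the grid.
#' @export
layer_window <- function(z1, z2) {
  stopifnot(is.numeric(z1), is.numeric(z2), z1 < z2)
  structure(list(z1 = z1, z2 = z2), class = "layer_window")
}

window_indices <- function(grid, window) {
  z <- depths(grid)
  if (window$z1 < z[1] - grid$dz / 2 || window$z2 > z[grid$n] + grid$dz / 2)
    stop("window lies outside the grid")
  which(z >= window$z1 & z <= window$z2)
}

#' Layer-resolved attenuation by exponential fitting
#'
#' Least-squares fit of `log I` against depth inside a window assumed to
#' be homogeneous; returns `-slope / 2`.  Non-positive intensities inside
#' the window are excluded; at least 5 usable samples are required.
#'
#' @param a an [ascan()].
#' @param window a [layer_window()].
#' @return Fitted attenuation coefficient, 1/mm.
#' @export
layer_mu_fit <- function(a, window) {
  stopifnot(inherits(a, "ascan"), inherits(window, "layer_window"))
  idx <- window_indices(a$grid, window)
  idx <- idx[a$values[idx] > 0]
  if (length(idx) < 5L)
    stop("need at least 5 positive samples inside the window")
  z <- depths(a$grid)
  fit <- lm.fit(cbind(1, z[idx]), log(a$values[idx]))
  -coef(fit)[[2L]] / 2
}

#' Layer-resolved backscattering fraction
#'
#' Amplitude matching over a homogeneous window:
#' `R_g = int_z1^z2 I(z) dz / (beta_L(z1) * (1 - exp(-2 mu_g (z2 - z1))))`.
#' Under the intensity convention `I = 2 R mu beta L` this recovers the R
#' used to generate the data; `convention = "as-printed"` doubles the
#' numerator (some layer-resolved formulations keep the leading round-trip
#' factor 2, which then returns twice the generating fraction).
#'
#' @param a an [ascan()].
#' @param window a [layer_window()] with at least 5 samples.
#' @param mu_g attenuation of the window, 1/mm (positive), typically from
#'   [layer_mu_fit()].
#' @param beta_L_at_z1 irradiance remaining at the window top, A.U. * mm.
#' @param convention `"consistent"` (default) or `"as-printed"`.
#' @return Backscattering fraction of the window.
#' @export
layer_R_fit <- function(a, window, mu_g, beta_L_at_z1,
                        convention = c("consistent", "as-printed")) {
  stopifnot(inherits(a, "ascan"), inherits(window, "layer_window"))
  convention <- match.arg(convention)
  if (!(mu_g > 0)) stop("mu_g must be positive")
  if (!(beta_L_at_z1 > 0)) stop("beta_L_at_z1 must be positive")
  idx <- window_indices(a$grid, window)
  if (length(idx) < 5L) stop("window must contain at least 5 samples")
  z <- depths(a$grid)
  num <- pracma::trapz(z[idx], a$values[idx])
  if (convention == "as-printed") num <- 2 * num
  span <- z[idx[length(idx)]] - z[idx[1L]]
  num / (beta_L_at_z1 * (1 - exp(-2 * mu_g * span)))
}

# ---------------------------------------------------------------------------
# Phase-function-derived quantities
# ---------------------------------------------------------------------------

as_phase_function <- function(pf) {
  if (is.function(pf)) return(pf)
  if (is.data.frame(pf) || (is.list(pf) && all(c("theta", "gamma") %in% names(pf)))) {
    theta <- pf$theta; gam <- pf$gamma
    stopifnot(all(gam >= 0), all(theta >= 0), all(theta <= pi))
    return(function(th) approx(theta, gam, th, rule = 2)$y)
  }
  stop("phase function must be a function of theta or a theta/gamma table")
}

gauss_int <- function(f, a, b, n_nodes) {
  gl <- pracma::gaussLegendre(n_nodes, a, b)
  sum(gl$w * f(gl$x))
}

#' Backscattering fraction from a scattering phase function
#'
#' Fraction of scattered light collected by an objective of numerical
#' aperture `na`:
#' the integral of `gamma(theta) sin(theta)` over the backward cone
#' `theta` in `[pi - asin(na), pi]`, divided by the integral over the full
#' sphere `[0, pi]`.  The backward cone (rather than a bound measured from
#' `theta = 0`) is used because only light scattered into the collection
#' cone around the reversed propagation direction re-enters the detector.
#' Fixed-order Gauss-Legendre quadrature is used on both integrals.
#'
#' @param pf phase function: either a function `gamma(theta)` on
#'   `[0, pi]` or a data frame/list with `theta` and `gamma` columns
#'   (arbitrary scale; it normalizes out).
#' @param na numerical aperture, in (0, 1).
#' @param n_nodes quadrature order (at least 256).
#' @return Backscattering fraction in [0, 1).
#' @examples
#' phase_R(function(th) rep(1, length(th)), na = 0.05)
#' # closed form for isotropic scattering: (1 - sqrt(1 - na^2)) / 2
#' @export
phase_R <- function(pf, na, n_nodes = 512L) {
  stopifnot(na > 0, na < 1, n_nodes >= 256L)
  g <- as_phase_function(pf)
  f <- function(th) g(th) * sin(th)
  num <- gauss_int(f, pi - asin(na), pi, n_nodes)
  den <- gauss_int(f, 0, pi, n_nodes)
  if (den <= 0) stop("phase function integrates to zero")
  num / den
}

#' Scattering anisotropy from a phase function
#'
#' Mean cosine of the scattering angle,
#' `g = int gamma(theta) sin(theta) cos(theta) dtheta / int gamma(theta)
#' sin(theta) dtheta`, by Gauss-Legendre quadrature.
#'
#' @inheritParams phase_R
#' @return Anisotropy in [-1, 1].
#' @export
phase_g <- function(pf, n_nodes = 512L) {
  stopifnot(n_nodes >= 256L)
  g <- as_phase_function(pf)
  num <- gauss_int(function(th) g(th) * sin(th) * cos(th), 0, pi, n_nodes)
  den <- gauss_int(function(th) g(th) * sin(th), 0, pi, n_nodes)
  if (den <= 0) stop("phase function integrates to zero")
  num / den
}

#' Henyey-Greenstein phase function
#'
#' `gamma(theta) = (1 - g^2) / (4 pi (1 + g^2 - 2 g cos(theta))^(3/2))`,
#' the standard single-parameter forward-peaked phase function whose mean
#' cosine equals `g`.
#'
#' @param g anisotropy parameter in (-1, 1).
#' @return A function of `theta` usable with [phase_R()] / [phase_g()].
#' @export
hg_phase <- function(g) {
  stopifnot(g > -1, g < 1)
  function(theta) (1 - g^2) / (4 * pi * (1 + g^2 - 2 * g * cos(theta))^1.5)
}
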