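#' @useDynLib octoprops, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm.fit median runmed sd var
#' @importFrom utils head read.table tail write.table
"_PACKAGE"

# ---------------------------------------------------------------------------
# Depth grid
# ---------------------------------------------------------------------------

#' Uniform axial depth grid
#'
#' A depth grid places `n` samples at `z0 + (i - 1) * dz` millimetres,
#' `i = 1, ..., n`, with depth increasing into the sample.  All axial
#' quantities in the package (intensities, attenuation and backscattering
#' profiles) live on such a grid.
#'
#' @param dz axial pixel pitch in mm (must be positive).
#' @param n number of axial samples (at least 2).
#' @param z0 depth of the first sample relative to the detector reference, mm.
#' @return An object of class `depth_grid`.
#' @examples
#' g <- depth_grid(dz = 0.001, n = 1000)
#' head(depths(g))
#' @export
depth_grid <- function(dz, n, z0 = 0) {
  stopifnot(is.numeric(dz), length(dz) == 1L, is.finite(dz), dz > 0)
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 2L)
  stopifnot(is.numeric(z0), length(z0) == 1L, is.finite(z0))
  structure(list(z0 = as.numeric(z0), dz = as.numeric(dz), n = n),
            class = "depth_grid")
}

#' Depth coordinates of a grid
#'
#' @param grid a [depth_grid()].
#' @return Numeric vector of depths in mm, length `grid$n`.
#' @export
depths <- function(grid) {
  stopifnot(inherits(grid, "depth_grid"))
  grid$z0 + (seq_len(grid$n) - 1L) * grid$dz
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("<depth_grid> n = %d, dz = %g mm, z in [%g, %g] mm\n",
              x$n, x$dz, x$z0, x$z0 + (x$n - 1L) * x$dz))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-12) {
  abs(a$z0 - b$z0) < tol && abs(a$dz - b$dz) < tol && a$n == b$n
}

# ---------------------------------------------------------------------------
# A-scan profile
# ---------------------------------------------------------------------------

#' Single A-scan intensity profile
#'
#' Carries linear-scale intensity values `I(z)` on a [depth_grid()].  An
#' optional analytic tail describes the continuation of the profile beyond
#' the last sample as `I(z) = prefactor * exp(-2 * mu * z)`, so that
#' semi-infinite depth integrals can include the exact exponential
#' remainder.  Negative values are only allowed in raw (pre
#' background-subtraction) data and must be clipped before estimation; use
#' `clip = TRUE` for that.
#'
#' @param values numeric intensity values (A.U., linear scale), one per
#'   grid sample.  All values must be finite.
#' @param grid a [depth_grid()].
#' @param tail optional list with elements `prefactor` and `mu` describing
#'   the analytic exponential continuation beyond the deepest sample.
#' @param clip clip negative values to zero instead of rejecting them.
#' @return An object of class `ascan`.
#' @seealso [extrapolate_tail()] which attaches a fitted tail,
#'   [tail_integral()] for the analytic remainder.
#' @export
ascan <- function(values, grid, tail = NULL, clip = FALSE) {
  stopifnot(inherits(grid, "depth_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop("length(values) must equal grid$n (", grid$n, ")")
  if (any(!is.finite(values)))
    stop("A-scan values must be finite")
  if (any(values < 0)) {
    if (clip) values[values < 0] <- 0
    else stop("negative intensities: raw data must be clipped (clip = TRUE) ",
              "before estimation")
  }
  if (!is.null(tail)) tail <- validate_tail(tail)
  structure(list(grid = grid, values = values, tail = tail), class = "ascan")
}

validate_tail <- function(tail) {
  stopifnot(is.list(tail), all(c("prefactor", "mu") %in% names(tail)))
  stopifnot(is.finite(tail$prefactor), tail$prefactor >= 0,
            is.finite(tail$mu), tail$mu > 0)
  tail[c("prefactor", "mu")]
}

#' @export
print.ascan <- function(x, ...) {
  cat(sprintf("<ascan> %d samples, dz = %g mm, I in [%.3g, %.3g]%s\n",
              x$grid$n, x$grid$dz, min(x$values), max(x$values),
              if (is.null(x$tail)) "" else ", analytic tail attached"))
  invisible(x)
}

#' Analytic remainder of a semi-infinite intensity integral
#'
#' For an [ascan()] carrying an exponential tail `I(z) = A exp(-2 mu z)`,
#' the integral from the deepest sample to infinity is `A exp(-2 mu
#' z_end) / (2 mu)` in closed form.  Returns 0 when no tail is attached.
#'
#' @param a an [ascan()].
#' @return Scalar integral remainder (A.U. * mm).
#' @export
tail_integral <- function(a) {
  stopifnot(inherits(a, "ascan"))
  if (is.null(a$tail)) return(0)
  z_end <- a$grid$z0 + (a$grid$n - 1L) * a$grid$dz
  a$tail$prefactor * exp(-2 * a$tail$mu * z_end) / (2 * a$tail$mu)
}

# Integral of I from each grid sample to infinity (trapezoid + analytic tail).
# Returns a vector aligned with the grid.
integral_to_inf <- function(a) {
  z <- depths(a$grid)
  ct <- pracma::cumtrapz(z, a$values)
  as.numeric(ct[length(ct)] - ct) + tail_integral(a)
}

# ---------------------------------------------------------------------------
# B-scan
# ---------------------------------------------------------------------------

#' Cross-sectional B-scan raster
#'
#' A collection of A-scans sharing one depth grid, stored as a matrix with
#' depth along rows and lateral position along columns.
#'
#' @param values numeric matrix, `grid$n` rows, one column per A-scan.
#' @param grid shared [depth_grid()].
#' @param lateral_pitch lateral step between A-scans in mm.
#' @return An object of class `bscan`.
#' @export
bscan <- function(values, grid, lateral_pitch = NA_real_) {
  stopifnot(inherits(grid, "depth_grid"), is.matrix(values))
  if (nrow(values) != grid$n)
    stop("nrow(values) must equal grid$n")
  if (any(!is.finite(values)))
    stop("B-scan values must be finite")
  structure(list(grid = grid, values = values,
                 lateral_pitch = as.numeric(lateral_pitch)),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d x %d (depth x lateral), dz = %g mm\n",
              nrow(x$values), ncol(x$values), x$grid$dz))
  invisible(x)
}

#' Extract one column of a B-scan as an A-scan
#'
#' @param b a [bscan()].
#' @param j column index.
#' @param clip clip negative values (passed to [ascan()]).
#' @export
bscan_column <- function(b, j, clip = FALSE) {
  stopifnot(inherits(b, "bscan"), j >= 1, j <= ncol(b$values))
  ascan(b$values[, j], b$grid, clip = clip)
}

# ---------------------------------------------------------------------------
# Optical profile, system parameters, layers
# ---------------------------------------------------------------------------

#' Depth-resolved optical properties
#'
#' Pairs a per-depth attenuation coefficient `mu(z)` (1/mm) with a
#' per-depth backscattering fraction `R(z)` (unitless) on a common grid.
#' `mu` must be non-negative; `R` must lie strictly inside (0, 1) wherever
#' it is defined (`NA` marks depths where no estimate exists, e.g. above
#' the sample surface).
#'
#' @param grid a [depth_grid()].
#' @param mu numeric vector of attenuation coefficients, 1/mm.
#' @param R numeric vector of backscattering fractions.
#' @return An object of class `optical_profile`.
#' @export
optical_profile <- function(grid, mu, R) {
  stopifnot(inherits(grid, "depth_grid"))
  mu <- as.numeric(mu); R <- as.numeric(R)
  stopifnot(length(mu) == grid$n, length(R) == grid$n)
  if (any(mu < 0, na.rm = TRUE)) stop("mu must be non-negative")
  bad <- !is.na(R) & (R <= 0 | R >= 1)
  if (any(bad)) stop("R must lie strictly in (0, 1) where defined")
  structure(list(grid = grid, mu = mu, R = R), class = "optical_profile")
}

#' @export
print.optical_profile <- function(x, ...) {
  cat(sprintf("<optical_profile> %d samples, mu in [%.3g, %.3g] 1/mm, R in [%.3g, %.3g]\n",
              x$grid$n, min(x$mu, na.rm = TRUE), max(x$mu, na.rm = TRUE),
              min(x$R, na.rm = TRUE), max(x$R, na.rm = TRUE)))
  invisible(x)
}

#' OCT system constants
#'
#' @param beta_L0 digitized initial irradiance `beta * L(0)` in A.U. * mm;
#'   must be positive.  The value is obtained experimentally by globally
#'   integrating the signal of a strong reflector.
#' @param na numerical aperture of the detection optics, in (0, 1).
#' @param l_coh coherence length of the source, mm.
#' @param db_ref reference intensity for decibel conversion (A.U.).  The
#'   noise-floor thresholds are quoted in dB without a printed reference,
#'   so the reference defaults to 1 A.U. and is user-overridable.
#' @param psf optional [psf_model()] describing the axial focus profile.
#' @return An object of class `system_params`.
#' @export
system_params <- function(beta_L0, na = 0.05, l_coh = 12, db_ref = 1,
                          psf = NULL) {
  stopifnot(is.numeric(beta_L0), beta_L0 > 0)
  stopifnot(is.numeric(na), na > 0, na < 1)
  stopifnot(is.numeric(db_ref), db_ref > 0)
  if (!is.null(psf)) stopifnot(inherits(psf, "psf_model"))
  structure(list(beta_L0 = beta_L0, na = na, l_coh = l_coh,
                 db_ref = db_ref, psf = psf),
            class = "system_params")
}

#' Homogeneous layer specification
#'
#' One locally homogeneous layer of a digital phantom: thickness in mm
#' (the final layer of a phantom may be unbounded, `Inf`), attenuation
#' coefficient in 1/mm and backscattering fraction in (0, 1).
#'
#' @param thickness layer thickness, mm (positive, possibly `Inf`).
#' @param mu attenuation coefficient, 1/mm (non-negative).
#' @param R backscattering fraction, in (0, 1).
#' @return A one-row data frame with columns `thickness`, `mu`, `R`.
#' @export
layer_spec <- function(thickness, mu, R) {
  stopifnot(thickness > 0, mu >= 0, R > 0, R < 1)
  data.frame(thickness = thickness, mu = mu, R = R)
}

# ---------------------------------------------------------------------------
# Decibel conversion
# ---------------------------------------------------------------------------

#' Linear intensity to decibels
#'
#' `10 * log10(value / db_ref)` elementwise; zeros map to `-Inf`.  The
#' convention follows the squared-magnitude definition of OCT intensity,
#' so 10 (not 20) multiplies the log.
#'
#' @param values non-negative linear intensities.
#' @param db_ref positive reference intensity (default 1 A.U.).
#' @return Numeric vector of dB values.
#' @examples
#' to_db(c(1, 100, 1e5))        # 0, 20, 50 dB
#' @export
to_db <- function(values, db_ref = 1) {
  stopifnot(is.numeric(db_ref), length(db_ref) == 1L, db_ref > 0)
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE))
    stop("to_db: negative intensities are outside the dB domain")
  out <- rep(-Inf, length(values))
  pos <- !is.na(values) & values > 0
  out[pos] <- 10 * log10(values[pos] / db_ref)
  out[is.na(values)] <- NA_real_
  out
}

#' Decibels to linear intensity
#'
#' Inverse of [to_db()]: `db_ref * 10^(db / 10)`.
#'
#' @param db dB values.
#' @param db_ref positive reference intensity.
#' @export
from_db <- function(db, db_ref = 1) {
  stopifnot(db_ref > 0)
  db_ref * 10^(as.numeric(db) / 10)
}
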