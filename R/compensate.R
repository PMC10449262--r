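# Attenuation-compensated intensity reconstruction and 8-bit display
# rendering.

#' Display configuration
#'
#' @param gamma display gamma exponent applied after dB normalization
#'   (default 0.75, which lifts mid-tones and enhances contrast).
#' @param db_range two-element dB window `(low, high)` to which values
#'   are clipped before normalization.
#' @export
display_config <- function(gamma = 0.75, db_range = c(0, 80)) {
  stopifnot(gamma > 0, length(db_range) == 2L, db_range[1L] < db_range[2L])
  structure(list(gamma = gamma, db_range = db_range),
            class = "display_config")
}

#' Attenuation-compensated intensity
#'
#' `I_D(z) = 2 R(z) mu(z) beta_L0`: the intensity the sample would
#' return if the full incident irradiance reached every depth.  Removes
#' the accumulated `exp(-2 int mu)` loss, so a homogeneous sample maps to
#' a depth-independent value and a layered one to one plateau per layer.
#'
#' @param profile an [optical_profile()]; `NA` backscatter (outside the
#'   sample) yields 0 intensity.
#' @param beta_L0 digitized initial irradiance, A.U. * mm.
#' @return An [ascan()] of compensated intensities.
#' @export
compensate <- function(profile, beta_L0) {
  stopifnot(inherits(profile, "optical_profile"), beta_L0 > 0)
  vals <- 2 * ifelse(is.na(profile$R), 0, profile$R) * profile$mu * beta_L0
  ascan(vals, profile$grid)
}

#' Compensate a solved B-scan
#'
#' Builds the compensated raster `2 R mu beta_L0` from the `mu` and `R`
#' maps of [solve_bscan()].
#'
#' @param mu_map,R_map matrices from [solve_bscan()].
#' @param beta_L0 digitized initial irradiance.
#' @param grid the shared [depth_grid()].
#' @param lateral_pitch lateral step, mm.
#' @return A [bscan()].
#' @export
compensate_bscan <- function(mu_map, R_map, beta_L0, grid,
                             lateral_pitch = NA_real_) {
  vals <- 2 * ifelse(is.na(R_map), 0, R_map) * mu_map * beta_L0
  bscan(vals, grid, lateral_pitch)
}

#' Render intensities to an 8-bit raster
#'
#' dB-converts, clips to the display range, normalizes to [0, 1], applies
#' gamma correction, and scales to integers 0..255.  Monotone in the
#' input.
#'
#' @param x an [ascan()], [bscan()] or numeric matrix/vector of linear
#'   intensities.
#' @param display a [display_config()].
#' @param db_ref dB reference intensity.
#' @return Integer array of the same shape with values in 0..255.
#' @export
render <- function(x, display = display_config(), db_ref = 1) {
  stopifnot(inherits(display, "display_config"))
  vals <- if (inherits(x, c("ascan", "bscan"))) x$values else x
  if (any(!is.finite(vals))) stop("render needs finite intensities")
  db <- 10 * log10(pmax(vals, .Machine$double.xmin) / db_ref)
  lo <- display$db_range[1L]; hi <- display$db_range[2L]
  u <- (pmin(pmax(db, lo), hi) - lo) / (hi - lo)
  out <- as.integer(round(255 * u^display$gamma))
  if (is.matrix(vals)) out <- matrix(out, nrow(vals), ncol(vals))
  out
}
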