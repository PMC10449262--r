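# Instrument-effect removal: axial focus (PSF) correction with two-position
# calibration, temporal B-scan averaging, and noise-floor fitting with
# exponential tail extrapolation.

#' Axial point-spread-function model
#'
#' Lorentzian depth sensitivity of a focused Gaussian beam,
#' `H(z - z_f, z_R) = 1 / (((z - z_f) / z_R)^2 + 1)`, with Rayleigh length
#' `z_R` and focal depth `z_f`.  Sensitivity roll-off is treated as an
#' identity factor by default (negligible for a source whose coherence
#' length far exceeds the imaging depth) but an arbitrary per-depth
#' roll-off vector can be supplied to [psf_correct()].
#'
#' @param z_R Rayleigh length, mm (positive).
#' @param z_f focal depth relative to the depth origin, mm.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(z_R, z_f) {
  stopifnot(is.numeric(z_R), z_R > 0, is.numeric(z_f), is.finite(z_f))
  structure(list(z_R = z_R, z_f = z_f), class = "psf_model")
}

#' Evaluate the axial PSF factor
#'
#' @param psf a [psf_model()].
#' @param z depths, mm.
#' @return `H(z - z_f, z_R)` values in (0, 1].
#' @export
psf_factor <- function(psf, z) {
  stopifnot(inherits(psf, "psf_model"))
  1 / (((z - psf$z_f) / psf$z_R)^2 + 1)
}

apply_depth_factor <- function(x, fac) {
  if (inherits(x, "bscan")) {
    bscan(x$values * fac, x$grid, x$lateral_pitch)
  } else if (inherits(x, "ascan")) {
    ascan(x$values * fac, x$grid, tail = x$tail)
  } else stop("expected an ascan or bscan")
}

#' Apply the axial PSF to a clean scan (forward direction)
#'
#' Multiplies every A-scan by `H(z - z_f, z_R)`; the inverse of
#' [psf_correct()].  Used when constructing degraded fixtures.
#'
#' @param x an [ascan()] or [bscan()].
#' @param psf a [psf_model()].
#' @export
psf_apply <- function(x, psf) {
  apply_depth_factor(x, psf_factor(psf, depths(x$grid)))
}

#' Remove the axial PSF from acquired data
#'
#' Divides every A-scan by `H(z - z_f, z_R)` so that the in-focus depth
#' (`z = z_f`, where `H = 1`) is unchanged and out-of-focus depths are
#' boosted.  An optional per-depth sensitivity roll-off vector is divided
#' out as well.
#'
#' @param x an [ascan()] or [bscan()].
#' @param psf a [psf_model()].
#' @param rolloff optional numeric vector `T(z)` of per-depth sensitivity
#'   factors (same length as the grid); identity when omitted.
#' @export
psf_correct <- function(x, psf, rolloff = NULL) {
  fac <- psf_factor(psf, depths(x$grid))
  if (!is.null(rolloff)) {
    stopifnot(length(rolloff) == x$grid$n, all(rolloff > 0))
    fac <- fac * rolloff
  }
  apply_depth_factor(x, 1 / fac)
}

#' Average a stack of B-scans
#'
#' Elementwise temporal mean over `n_average` frames of identical
#' geometry; for independent fully developed speckle this reduces the
#' intensity variance by about `1 / n_average`.
#'
#' @param stack list of [bscan()] objects sharing one geometry.
#' @param n_average number of frames to average (defaults to all).
#' @return A [bscan()].
#' @export
average_bscans <- function(stack, n_average = length(stack)) {
  stopifnot(is.list(stack), length(stack) >= 1L, n_average >= 1L,
            length(stack) >= n_average)
  g <- stack[[1L]]$grid
  for (b in stack) {
    stopifnot(inherits(b, "bscan"))
    if (!same_grid(b$grid, g) ||
        !identical(dim(b$values), dim(stack[[1L]]$values)))
      stop("all B-scans in the stack must share the same geometry")
  }
  acc <- Reduce(`+`, lapply(stack[seq_len(n_average)], `[[`, "values"))
  bscan(acc / n_average, g, stack[[1L]]$lateral_pitch)
}

#' Two-position calibration pair
#'
#' Two images of the same strong reflector acquired with the sample
#' shifted axially by a measured `delta_z`; the input of
#' [calibrate_psf()].
#'
#' @param image1,image2 [bscan()] objects sharing the axial pitch.
#' @param delta_z measured surface-depth shift between the images, mm
#'   (positive).
#' @export
calibration_pair <- function(image1, image2, delta_z) {
  stopifnot(inherits(image1, "bscan"), inherits(image2, "bscan"))
  if (abs(image1$grid$dz - image2$grid$dz) > 1e-12)
    stop("calibration images must share the axial pitch")
  if (!(is.numeric(delta_z) && delta_z > 0))
    stop("delta_z must be positive (a zero shift is degenerate)")
  structure(list(image1 = image1, image2 = image2, delta_z = delta_z),
            class = "calibration_pair")
}

#' Calibrate the axial PSF by exhaustive search
#'
#' For each candidate `(z_R, z_f)` the two images are PSF-normalized and
#' the L1 norm of their difference over the depth overlap (image2 shifted
#' by `delta_z`), summed over all A-scans, is evaluated; the minimizing
#' pair is returned.  This is a plain exhaustive search over the supplied
#' grids; ties break towards the smallest `z_R`, then the smallest `z_f`.
#'
#' @param pair a [calibration_pair()].
#' @param grid_zR candidate Rayleigh lengths, mm.
#' @param grid_zf candidate focal depths, mm.
#' @return A list with the fitted [psf_model()], the attained `l1` value
#'   and the full `loss` matrix (`length(grid_zR)` x `length(grid_zf)`).
#' @export
calibrate_psf <- function(pair,
                          grid_zR = seq(0.01, 2, by = 0.01),
                          grid_zf = seq(-1, 3, by = 0.01)) {
  stopifnot(inherits(pair, "calibration_pair"))
  dz <- pair$image1$grid$dz
  shift <- as.integer(round(pair$delta_z / dz))
  n1 <- pair$image1$grid$n
  n2 <- pair$image2$grid$n
  m <- min(n1, n2 - shift)
  if (m < 2L) stop("no depth overlap after shifting by delta_z")
  z1 <- depths(pair$image1$grid)[seq_len(m)]
  I1 <- pair$image1$values[seq_len(m), , drop = FALSE]
  I2 <- pair$image2$values[seq_len(m) + shift, , drop = FALSE]
  z2 <- depths(pair$image2$grid)[seq_len(m) + shift]
  loss <- matrix(NA_real_, length(grid_zR), length(grid_zf))
  for (i in seq_along(grid_zR)) {
    for (j in seq_along(grid_zf)) {
      h1 <- 1 / (((z1 - grid_zf[j]) / grid_zR[i])^2 + 1)
      h2 <- 1 / (((z2 - grid_zf[j]) / grid_zR[i])^2 + 1)
      loss[i, j] <- sum(abs(I1 / h1 - I2 / h2))
    }
  }
  best <- which(loss == min(loss), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  list(psf = psf_model(grid_zR[best[1L]], grid_zf[best[2L]]),
       l1 = min(loss), loss = loss)
}

#' Preprocessing configuration
#'
#' @param n_average temporal averaging window in B-scans.
#' @param floor_db dB level defining the deep end `z_nf1` of the
#'   noise-floor fit window (default 50 dB).
#' @param start_db dB level defining the shallow end `z_nf0` (default
#'   58 dB); must exceed `floor_db`.
#' @param db_ref dB reference intensity, A.U.
#' @param crossing_tol_db slack added to `floor_db` when locating the
#'   floor crossing: with a background sitting exactly at the threshold
#'   the trace approaches it asymptotically, so the crossing is declared
#'   once the smoothed trace is within this many dB of `floor_db`.
#' @param subtract_background subtract the estimated background level
#'   (median intensity beyond the floor crossing) before the exponential
#'   fit.
#' @param median_window width of the running-median filter (samples)
#'   applied to the dB trace before threshold crossings are located.
#' @export
preprocess_config <- function(n_average = 5L, floor_db = 50, start_db = 58,
                              db_ref = 1, crossing_tol_db = 0.5,
                              subtract_background = TRUE,
                              median_window = 5L) {
  stopifnot(n_average >= 1L, start_db > floor_db, db_ref > 0,
            crossing_tol_db >= 0, median_window >= 1L)
  structure(list(n_average = as.integer(n_average), floor_db = floor_db,
                 start_db = start_db, db_ref = db_ref,
                 crossing_tol_db = crossing_tol_db,
                 subtract_background = subtract_background,
                 median_window = as.integer(median_window)),
            class = "preprocess_config")
}

#' Fit the noise floor of an A-scan
#'
#' Locates, beyond the intensity maximum, the first depths where the
#' median-filtered dB trace falls to `start_db` (giving `z_nf0`) and to
#' `floor_db` (giving `z_nf1`), then fits `I(z) ~ exp(-2 mu z)` on the
#' window `(z_nf0, z_nf1)` by least squares on `log I` versus `z`, whose
#' slope is `-2 mu_tilde`.  When `subtract_background` is set, the
#' background level (median intensity beyond `z_nf1`) is removed before
#' taking logs, which keeps the fitted decay rate unbiased even when the
#' window runs into the floor.
#'
#' @param a an [ascan()].
#' @param config a [preprocess_config()].
#' @return An object of class `noise_floor_fit` with fields `z_nf0`,
#'   `z_nf1`, `mu_tilde` (1/mm), `prefactor` (A.U.) and `floor_level`.
#' @export
fit_noise_floor <- function(a, config = preprocess_config()) {
  stopifnot(inherits(a, "ascan"), inherits(config, "preprocess_config"))
  z <- depths(a$grid)
  db <- to_db(pmax(a$values, 0), config$db_ref)
  k <- config$median_window
  if (k > 1L && a$grid$n > k + 1L) {
    if (k %% 2L == 0L) k <- k + 1L               # runmed needs odd width
    sm <- as.numeric(runmed(pmax(db, -400), k))  # -Inf capped, far below any threshold
  } else sm <- db
  imax <- which.max(a$values)
  below0 <- which(seq_along(z) > imax & sm <= config$start_db)
  below1 <- which(seq_along(z) > imax &
                    sm <= config$floor_db + config$crossing_tol_db)
  if (!length(below0))
    stop("profile never falls to start_db: treat the full profile as signal")
  if (!length(below1))
    stop("profile never falls to floor_db: treat the full profile as signal")
  i0 <- below0[1L]; i1 <- below1[1L]
  if (i1 <= i0 + 3L)
    stop("noise-floor fit window is too short")
  # background level from the deepest quarter beyond the crossing -- but
  # only when that region is actually flat (a decaying profile without a
  # floor must not have part of its own signal subtracted)
  floor_level <- 0
  if (i1 < a$grid$n - 4L) {
    deep <- a$values[i1:a$grid$n]
    qs <- stats::quantile(deep, c(0.1, 0.9), names = FALSE)
    if (qs[1L] > 0 && qs[2L] / qs[1L] < 3)
      floor_level <- median(tail(deep, max(5L, length(deep) %/% 4L)))
  }
  win <- i0:i1
  y <- a$values[win]
  if (config$subtract_background) y <- y - floor_level
  keep <- y > 0
  if (sum(keep) < 5L) stop("too few positive samples in the fit window")
  fit <- lm.fit(cbind(1, z[win][keep]), log(y[keep]))
  mu_tilde <- -coef(fit)[[2L]] / 2
  if (!is.finite(mu_tilde) || mu_tilde <= 0)
    stop("noise-floor fit produced a non-decaying exponential")
  structure(list(z_nf0 = z[i0], z_nf1 = z[i1], i_nf0 = i0, i_nf1 = i1,
                 mu_tilde = mu_tilde, prefactor = exp(coef(fit)[[1L]]),
                 floor_level = floor_level),
            class = "noise_floor_fit")
}

#' @export
print.noise_floor_fit <- function(x, ...) {
  cat(sprintf(
    "<noise_floor_fit> z_nf0 = %g mm, z_nf1 = %g mm, mu_tilde = %.4g 1/mm\n",
    x$z_nf0, x$z_nf1, x$mu_tilde))
  invisible(x)
}

#' Remove the noise floor and extrapolate the fitted exponential tail
#'
#' The estimated background level is subtracted from the retained signal
#' (a no-op when no flat floor was detected), values deeper than `z_nf1`
#' are replaced by `prefactor * exp(-2 mu_tilde z)`, and the same
#' exponential is attached as the analytic tail, so every semi-infinite
#' integral downstream includes the exact remainder beyond the grid.
#' This removes the attenuation underestimate that a depth-limited
#' integral over a flat background would otherwise cause.
#'
#' @param a an [ascan()].
#' @param fit a `noise_floor_fit` from [fit_noise_floor()].
#' @return An [ascan()] with floor-subtracted values, replaced deep
#'   values and an analytic tail.
#' @export
extrapolate_tail <- function(a, fit) {
  stopifnot(inherits(a, "ascan"), inherits(fit, "noise_floor_fit"))
  z <- depths(a$grid)
  vals <- pmax(a$values - fit$floor_level, 0)
  deep <- z > fit$z_nf1
  vals[deep] <- fit$prefactor * exp(-2 * fit$mu_tilde * z[deep])
  ascan(vals, a$grid, tail = list(prefactor = fit$prefactor,
                                  mu = fit$mu_tilde))
}
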