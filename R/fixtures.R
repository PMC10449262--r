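# Synthetic-data generation and the end-to-end pipeline.
#
# Fixtures compose the clean single-scattering signal with the
# instrument degradations in acquisition order: axial focus (PSF), then
# multiplicative speckle (unit-mean exponential, i.e. fully developed),
# then an additive background floor.  Every fixture returns the exact
# ground truth it was built from, so recovery errors are measurable
# without external data.

#' Fixture configuration
#'
#' @param phantom a [phantom_spec()] defining signal and truth.
#' @param speckle logical; multiply each pixel by an independent
#'   unit-mean exponential deviate (fully developed speckle).
#' @param floor_level additive background level, A.U. (0 disables).
#' @param psf optional [psf_model()] applied to the clean signal.
#' @param n_alines number of statistically independent A-scans.
#' @param seed RNG seed used for the speckle draws.
#' @export
fixture_config <- function(phantom, speckle = FALSE, floor_level = 0,
                           psf = NULL, n_alines = 1L, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"), floor_level >= 0,
            n_alines >= 1L)
  if (!is.null(psf)) stopifnot(inherits(psf, "psf_model"))
  structure(list(phantom = phantom, speckle = isTRUE(speckle),
                 floor_level = floor_level, psf = psf,
                 n_alines = as.integer(n_alines), seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a degraded B-scan fixture with its ground truth
#'
#' Builds the noise-free A-line, replicates it across columns, and
#' applies the configured degradations in order signal -> PSF -> speckle
#' -> additive floor.  Bit-reproducible for a fixed seed.
#'
#' @param config a [fixture_config()].
#' @param grid optional [depth_grid()]; defaults to [phantom_grid()] of
#'   the phantom.
#' @return A list: `bscan` (degraded), `truth` (an [optical_profile()]),
#'   `clean` (the noise-free [ascan()]).
#' @export
make_fixture <- function(config, grid = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  if (is.null(grid)) grid <- phantom_grid(config$phantom)
  clean <- simulate_aline(config$phantom, grid)
  vals <- matrix(clean$values, grid$n, config$n_alines)
  if (!is.null(config$psf))
    vals <- vals * psf_factor(config$psf, depths(grid))
  set.seed(config$seed)
  if (config$speckle)
    vals <- vals * matrix(stats::rexp(length(vals)), nrow(vals))
  if (config$floor_level > 0)
    vals <- vals + config$floor_level
  list(bscan = bscan(vals, grid),
       truth = phantom_profile(config$phantom, grid),
       clean = clean)
}

#' Attach an analytic exponential tail to a preprocessed A-scan
#'
#' When the dB thresholds are crossed this is the noise-floor fit and
#' extrapolation of [fit_noise_floor()] / [extrapolate_tail()].
#' Otherwise the same treatment is applied at the profile's own
#' usable-signal limit: the deepest depth where the median-filtered
#' intensity still exceeds `rel_floor` of its peak plays the role of
#' the floor crossing, the decay rate is fitted on the window just
#' above it, and everything deeper -- noise-dominated or absent -- is
#' replaced by the fitted exponential continuation, with the matching
#' analytic tail attached for the semi-infinite integrals.
#'
#' @param a an [ascan()].
#' @param pre_cfg a [preprocess_config()].
#' @param rel_floor usable-signal cutoff relative to the profile peak.
#' @return A tail-extrapolated [ascan()] ready for [solve_aline()].
#' @export
attach_tail <- function(a, pre_cfg = preprocess_config(), rel_floor = 1e-4) {
  fit <- tryCatch(fit_noise_floor(a, pre_cfg), error = function(e) NULL)
  if (!is.null(fit)) return(extrapolate_tail(a, fit))
  vals <- pmax(a$values, 0)
  n <- a$grid$n
  sm <- if (n > 7L) as.numeric(runmed(vals, 5L)) else vals
  ipk <- which.max(sm)
  usable <- which(sm > rel_floor * max(sm))
  i2 <- max(usable)
  z <- depths(a$grid)
  mu_tail <- NA_real_
  for (frac in c(0.25, 0.5, 1)) {               # widen until the fit decays
    i1 <- max(ipk + 1L, i2 - max(10L, ceiling(frac * (i2 - ipk))))
    if (i2 - i1 < 5L) next
    m <- tryCatch(layer_mu_fit(a, layer_window(z[i1], z[i2])),
                  error = function(e) NA_real_)
    if (is.finite(m) && m > 0) { mu_tail <- m; break }
  }
  if (!is.finite(mu_tail)) {
    # last resort: decay rate implied by the drop from the profile peak
    if (i2 > ipk && vals[i2] < vals[ipk] && vals[i2] > 0) {
      mu_tail <- log(vals[ipk] / vals[i2]) / (2 * (z[i2] - z[ipk]))
    } else stop("cannot attach a decaying tail: profile does not decay")
  }
  pref <- vals[i2] * exp(2 * mu_tail * z[i2])
  deep <- seq_len(n) > i2
  vals[deep] <- pref * exp(-2 * mu_tail * z[deep])
  ascan(vals, a$grid, tail = list(prefactor = pref, mu = mu_tail))
}

#' Run the full characterization pipeline on a B-scan
#'
#' Executes the processing chain end to end: temporal averaging (when a
#' stack is supplied), PSF correction (when the system carries a PSF
#' model), background subtraction and noise-floor extrapolation per
#' column, the constrained joint iteration per column, and attenuation
#' compensation.  Errors in a column are attributed to their stage and
#' the column falls back to the baseline estimate.
#'
#' @param x a [bscan()] or a list of B-scans (a temporal stack).
#' @param system a [system_params()].
#' @param pre_cfg a [preprocess_config()].
#' @param iter_cfg an [iteration_config()].
#' @param mode update rule for [solve_aline()].
#' @return A list: `mu` and `R` matrices, `compensated` [bscan()],
#'   `states` per column, `failed` column indices, `stop_reasons` table,
#'   and the preprocessed `bscan`.
#' @export
run_pipeline <- function(x, system, pre_cfg = preprocess_config(),
                         iter_cfg = iteration_config(), mode = "ratio") {
  stopifnot(inherits(system, "system_params"))
  b <- if (inherits(x, "bscan")) x
       else average_bscans(x, min(pre_cfg$n_average, length(x)))
  if (!is.null(system$psf)) b <- psf_correct(b, system$psf)
  cols <- lapply(seq_len(ncol(b$values)), function(j) {
    a <- bscan_column(b, j, clip = TRUE)
    attach_tail(a, pre_cfg)
  })
  sol <- solve_bscan(cols, system$beta_L0, iter_cfg, mode)
  comp <- compensate_bscan(sol$mu, sol$R, system$beta_L0, b$grid,
                           b$lateral_pitch)
  reasons <- table(vapply(sol$states, function(s)
    if (inherits(s, "error")) "error" else s$stop_reason, character(1)))
  list(mu = sol$mu, R = sol$R, compensated = comp, states = sol$states,
       failed = sol$failed, stop_reasons = reasons, bscan = b)
}

#' Per-layer means of an estimated profile
#'
#' Average of a per-depth estimate over the interior of each layer of a
#' phantom (a margin is excluded at both ends of every layer to avoid
#' interface pixels).
#'
#' @param values per-depth estimates on `grid`.
#' @param phantom the generating [phantom_spec()].
#' @param grid the [depth_grid()].
#' @param margin_mm interface exclusion margin, mm.
#' @param max_depth deepest depth used for the unbounded bottom layer,
#'   mm (defaults to the grid end).
#' @return Numeric vector of per-layer means.
#' @export
layer_means <- function(values, phantom, grid, margin_mm = 0.02,
                        max_depth = NULL) {
  z <- depths(grid)
  if (is.null(max_depth)) max_depth <- z[grid$n]
  bounds <- layer_bounds(phantom)
  upper <- c(bounds[-1], max_depth)
  vapply(seq_len(nrow(phantom$layers)), function(j) {
    sel <- z > bounds[j] + margin_mm & z < upper[j] - margin_mm
    mean(values[sel], na.rm = TRUE)
  }, numeric(1))
}
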