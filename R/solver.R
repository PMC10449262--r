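# Constrained stationary iteration for joint mu(z), R(z) estimation.
#
# The measured intensity I = 2 R mu betaL confounds three depth profiles,
# and the pair (baseline mu0, constant mean backscatter R_tilde)
# reproduces any I exactly, so the inverse problem is non-unique until a
# structural prior is imposed.  The prior used here is the one implied by
# the locally homogeneous portions of the model: R is piecewise constant
# on segments within which the log-intensity decays linearly.  Each loop
# (i) re-segments the backscattering profile by thresholding its
# derivative (fuzzy processing: small variations are averaged away, large
# ones retained as breakpoints), (ii) re-estimates each segment's
# attenuation from its log-slope and its backscattering fraction by
# amplitude matching against the remaining irradiance, and (iii) updates
# the depth-resolved attenuation by the ratio rule, i.e. the baseline
# estimator applied to I/R, which is exact when R is exact.  Constraint
# conditions on R's range, its spread around the mean backscatter, the
# mu compensation ratio, the loop count and the relative change guard the
# loop, which has no global convergence guarantee.

#' Iteration configuration
#'
#' Scaling factors and stopping controls for [solve_aline()].
#'
#' @param A,B lower/upper allowed ratio of any segment's backscattering
#'   to the mean backscatter `R_tilde` (defaults 0.1 and 10).
#' @param C,D lower/upper clamp on `mu_k / mu0` (defaults 0.2 and 5),
#'   preventing runaway attenuation compensation.
#' @param E maximum number of loops (default 10).
#' @param deriv_factor threshold multiplier on the mean absolute
#'   derivative of the backscattering profile; contiguous runs below the
#'   threshold become segments (default 4.5, the midpoint of the
#'   empirically useful four-to-five-times range).
#' @param rel_tol relative-change stopping tolerance on mu at the depth
#'   of maximal change (default 0.01).
#' @param deriv_halfwin half-width, in pixels, of the central difference
#'   used for the derivative (1 = adjacent neighbours; larger values
#'   average pixel noise at the cost of boundary localization).
#' @param flat_tol relative spread below which a profile is treated as a
#'   single segment; variation this small is indistinguishable from
#'   numerical noise (default 1e-3, far below any physically meaningful
#'   inter-layer contrast).
#' @param support_eps intensities below `support_eps * max(I)` are
#'   treated as below the usable signal level (outside the sample or
#'   noise-dominated); no estimate is made there and mu is reported
#'   as 0, mirroring the zeroing of the attenuation below the sample
#'   bottom.
#' @param surface_margin pixels excluded from backscatter estimation just
#'   below the detected surface (edge effects; default 2).
#' @export
iteration_config <- function(A = 0.1, B = 10, C = 0.2, D = 5, E = 10L,
                             deriv_factor = 4.5, rel_tol = 0.01,
                             deriv_halfwin = 1L, flat_tol = 1e-3,
                             support_eps = 1e-4, surface_margin = 2L) {
  stopifnot(A < 1, B > 1, C < 1, D > 1, E >= 1L, deriv_factor > 0,
            rel_tol > 0, deriv_halfwin >= 1L, flat_tol >= 0,
            support_eps >= 0, surface_margin >= 0L)
  structure(list(A = A, B = B, C = C, D = D, E = as.integer(E),
                 deriv_factor = deriv_factor, rel_tol = rel_tol,
                 deriv_halfwin = as.integer(deriv_halfwin),
                 flat_tol = flat_tol, support_eps = support_eps,
                 surface_margin = as.integer(surface_margin)),
            class = "iteration_config")
}

#' Fuzzy processing of a backscattering profile
#'
#' Replaces runs of small variation by their average while retaining
#' large changes.  The absolute central-difference derivative is
#' thresholded at `deriv_factor` times its own mean; contiguous runs at
#' or below the threshold become segments, each substituted by its mean,
#' and above-threshold runs (breakpoint zones) are attached to the
#' adjacent deeper segment -- the attenuation bias at a depth depends
#' only on backscattering variation below it, so boundary pixels must not
#' contaminate the shallower mean.  A profile whose total relative spread
#' is below `flat_tol` is returned unchanged as a single segment.
#'
#' @param R numeric backscattering profile on contiguous samples.
#' @param dz sample spacing, mm.
#' @param deriv_factor threshold multiplier (default 4.5).
#' @param halfwin central-difference half-width in pixels.
#' @param flat_tol single-segment relative-spread guard.
#' @param recursive re-apply the rule inside each segment with a
#'   threshold from that segment's own derivatives, until no segment
#'   splits further.  A single dominant change otherwise inflates the
#'   global mean derivative and masks smaller genuine steps elsewhere;
#'   recursion realizes the automatic per-iteration threshold adjustment
#'   with no extra parameter.  A step-free segment is a fixed point, so
#'   clean profiles are unaffected.
#' @param min_seg segments shorter than this are not re-examined.
#' @return A list: `values` (piecewise-constant profile), `seg_id`
#'   (segment label per sample, 1 = shallowest), `segments` (data frame
#'   with `start`, `end` sample indices and `mean`), `breakpoint`
#'   (logical, derivative above threshold), `threshold`.
#' @export
fuzzy_process_R <- function(R, dz, deriv_factor = 4.5, halfwin = 1L,
                            flat_tol = 1e-3, recursive = TRUE,
                            min_seg = 10L) {
  m <- length(R)
  stopifnot(m >= 3L, dz > 0, all(is.finite(R)))
  base <- fuzzy_once(R, dz, deriv_factor, halfwin, flat_tol)
  if (recursive && nrow(base$segments) > 1L) {
    for (pass in 1:6) {
      changed <- FALSE
      seg <- base$seg_id
      bp <- base$breakpoint
      next_id <- max(seg)
      for (s in sort(unique(seg))) {
        in_s <- which(seg == s)
        if (length(in_s) < max(min_seg, 3L)) next
        sub <- fuzzy_once(R[in_s], dz, deriv_factor, halfwin, flat_tol)
        if (nrow(sub$segments) > 1L) {
          changed <- TRUE
          seg[in_s] <- next_id + sub$seg_id
          bp[in_s] <- bp[in_s] | sub$breakpoint
          next_id <- next_id + max(sub$seg_id)
        }
      }
      if (!changed) break
      base$seg_id <- seg
      base$breakpoint <- bp
    }
    # relabel shallow -> deep and rebuild the summary
    starts <- vapply(unique(base$seg_id),
                     function(s) which(base$seg_id == s)[1L], integer(1))
    relab <- match(base$seg_id,
                   unique(base$seg_id)[order(starts)])
    base$seg_id <- relab
    labs <- sort(unique(relab))
    start <- integer(length(labs)); end <- integer(length(labs))
    means <- numeric(length(labs))
    vals <- R
    for (s in labs) {
      in_s <- relab == s
      core <- in_s & !base$breakpoint
      means[s] <- if (any(core)) mean(R[core]) else mean(R[in_s])
      vals[in_s] <- means[s]
      start[s] <- which(in_s)[1L]; end[s] <- max(which(in_s))
    }
    base$values <- vals
    base$segments <- data.frame(start = start, end = end, mean = means)
  }
  base
}

fuzzy_once <- function(R, dz, deriv_factor, halfwin, flat_tol) {
  m <- length(R)
  spread <- (max(R) - min(R)) / max(mean(abs(R)), .Machine$double.xmin)
  w <- max(1L, min(as.integer(halfwin), (m - 1L) %/% 2L))
  d <- numeric(m)
  ii <- (1L + w):(m - w)
  d[ii] <- (R[ii + w] - R[ii - w]) / (2 * w * dz)
  d[seq_len(w)] <- d[w + 1L]
  d[(m - w + 1L):m] <- d[m - w]
  thr <- deriv_factor * mean(abs(d))
  below <- abs(d) <= thr
  if (spread <= flat_tol || all(below)) {
    return(list(values = rep(mean(R), m), seg_id = rep(1L, m),
                segments = data.frame(start = 1L, end = m, mean = mean(R)),
                breakpoint = rep(FALSE, m), threshold = thr))
  }
  # walk deep -> shallow so breakpoint zones join the deeper segment
  seg <- integer(m); cur <- 0L; inseg <- FALSE
  for (i in m:1) {
    if (below[i]) {
      if (!inseg) { cur <- cur + 1L; inseg <- TRUE }
      seg[i] <- cur
    } else {
      if (cur == 0L) cur <- 1L
      seg[i] <- cur
      inseg <- FALSE
    }
  }
  seg <- max(seg) + 1L - seg                     # relabel 1 = shallowest
  vals <- R
  labs <- sort(unique(seg))
  means <- numeric(length(labs))
  start <- integer(length(labs)); end <- integer(length(labs))
  for (s in labs) {
    in_s <- seg == s
    core <- in_s & below
    means[s] <- if (any(core)) mean(R[core]) else mean(R[in_s])
    vals[in_s] <- means[s]
    start[s] <- which(in_s)[1L]; end[s] <- max(which(in_s))
  }
  list(values = vals, seg_id = seg,
       segments = data.frame(start = start, end = end, mean = means),
       breakpoint = !below, threshold = thr)
}

# Per-segment optics: attenuation from the log-slope of I inside each
# segment, backscattering by amplitude matching of the segment's
# integrated intensity against the irradiance remaining at its top.
# Exact for homogeneous segments; this is where the within-segment slope
# information enters the loop (the pointwise inversion alone carries
# none -- see the vignette).
segment_optics <- function(a, idx_sup, seg_id, mu_now, beta_L0,
                           clamp_lo = 0.2, clamp_hi = 5, core = NULL) {
  z <- depths(a$grid); n <- a$grid$n
  if (is.null(core)) core <- rep(TRUE, length(seg_id))
  labs <- sort(unique(seg_id))
  mu_seg <- numeric(length(labs))
  for (s in labs) {
    ii <- idx_sup[seg_id == s]
    # slope fitted on core (below-threshold) pixels only: breakpoint
    # zones carry the smeared interface transition, not the layer decay
    ok <- idx_sup[seg_id == s & core]
    ok <- ok[a$values[ok] > 0]
    if (length(ok) < 5L) { ok <- ii[a$values[ii] > 0] }
    ref <- max(mean(mu_now[ii]), 1e-9)
    mu_seg[s] <- if (length(ok) >= 5L)
      -coef(lm.fit(cbind(1, z[ok]), log(a$values[ok])))[[2L]] / 2
    else ref
    # noise-dominated segments can fit non-decaying or runaway slopes;
    # bound them by the same compensation limits that guard mu itself
    mu_seg[s] <- min(max(mu_seg[s], clamp_lo * ref), clamp_hi * ref)
  }
  muP <- numeric(n)
  for (s in labs) muP[idx_sup[seg_id == s]] <- mu_seg[s]
  cmu <- as.numeric(pracma::cumtrapz(z, muP))
  ctI <- as.numeric(pracma::cumtrapz(z, a$values))
  R_seg <- numeric(length(labs))
  last <- labs[length(labs)]
  for (s in labs) {
    ii <- idx_sup[seg_id == s]
    i1 <- min(ii); i2 <- max(ii)
    bL1 <- beta_L0 * exp(-2 * cmu[i1])
    if (s == last) {
      # deepest segment absorbs everything below it, incl. the analytic tail
      intI <- ctI[n] - ctI[i1] + tail_integral(a)
      damp <- if (!is.null(a$tail)) 1
              else 1 - exp(-2 * mu_seg[s] * (z[n] - z[i1]))
    } else {
      intI <- ctI[i2] - ctI[i1]
      damp <- 1 - exp(-2 * mu_seg[s] * (z[i2] - z[i1]))
    }
    R_seg[s] <- intI / (bL1 * max(damp, 1e-12))
  }
  R_full <- rep(NA_real_, n)
  for (s in labs) R_full[idx_sup[seg_id == s]] <- R_seg[s]
  idx <- which(!is.na(R_full))
  R_full <- as.numeric(approx(z[idx], R_full[idx], z, method = "constant",
                              rule = 2)$y)
  list(R = R_full, R_seg = R_seg, mu_seg = mu_seg)
}

#' One attenuation update given a backscattering profile
#'
#' Mode `"ratio"` (default) applies the baseline estimator to `I/R`:
#' `mu(z) = (I/R) / (2 int_z^inf I/R du)`, with the analytic tail scaled
#' by the deepest R value.  Because `I/R = 2 mu betaL` is proportional to
#' the irradiance derivative, this is exact whenever `R` is exact, and it
#' requires no differentiation of R.  Mode `"correction"` evaluates the
#' explicit bias bracket instead: the baseline estimate is multiplied by
#' `1 + sum_b dR_b exp(-2 int_0^b mu_prev) / (R(z) exp(-2 int_0^z
#' mu_prev))` over the breakpoints `b` deeper than `z`, treating the
#' derivative of the piecewise-constant profile as impulses at its jumps.
#'
#' @param a a tail-extrapolated [ascan()].
#' @param R backscattering profile (positive on the support of I).
#' @param mode `"ratio"` or `"correction"`.
#' @param mu_prev previous attenuation iterate, required for
#'   `"correction"`.
#' @param support logical vector marking in-sample depths; estimates
#'   outside are 0.  Defaults to `I > 0`.
#' @param clamp optional list with vectors `lo`, `hi` bounding the
#'   result elementwise.
#' @return Numeric attenuation profile, 1/mm.
#' @export
update_mu <- function(a, R, mode = c("ratio", "correction"),
                      mu_prev = NULL, support = NULL, clamp = NULL) {
  stopifnot(inherits(a, "ascan"), length(R) == a$grid$n)
  mode <- match.arg(mode)
  n <- a$grid$n
  if (is.null(support)) support <- a$values > 0
  if (any(support & (is.na(R) | R <= 0)))
    stop("R must be positive on the support of I")
  z <- depths(a$grid)
  if (mode == "ratio") {
    # integrate I/R over the whole grid (R is filled off-support); only
    # the reported estimate is masked to the support
    g <- ifelse(R > 0, a$values / R, 0)
    ct <- as.numeric(pracma::cumtrapz(z, g))
    den <- ct[n] - ct + tail_integral(a) / R[n]
    mu <- ifelse(support & den > 0, g / (2 * den), 0)
  } else {
    if (is.null(mu_prev)) stop("correction mode needs mu_prev")
    base_den <- integral_to_inf(a)
    base <- ifelse(support & base_den > 0, a$values / (2 * base_den), 0)
    cmu <- as.numeric(pracma::cumtrapz(z, mu_prev))
    att <- exp(-2 * cmu)
    dR <- c(diff(R), 0)
    jumps <- which(abs(dR) > 0 & support)
    jump_w <- dR[jumps] * att[jumps]
    # suffix sums of jump weights deeper than each depth
    corr <- numeric(n)
    if (length(jumps)) {
      sfx <- rev(cumsum(rev(jump_w)))
      pos <- findInterval(seq_len(n), jumps) + 1L
      has <- pos <= length(jumps)
      corr[has] <- sfx[pos[has]]
    }
    bracket <- pmax(1 + ifelse(support, corr / (R * att), 0), 0)
    mu <- base * bracket
  }
  if (!is.null(clamp)) mu <- pmin(pmax(mu, clamp$lo), clamp$hi)
  mu[!support] <- 0
  mu
}

#' Jointly estimate depth-resolved attenuation and backscattering
#'
#' Runs the constrained stationary iteration on a preprocessed,
#' tail-extrapolated A-scan.  Initialization: `mu0` is the baseline
#' estimate, the segmentation comes from fuzzy processing of the
#' pointwise backscattering inversion (computed with a one-pixel
#' look-ahead so that layer interfaces leave detectable derivative
#' marks), and the segment optics (slope-fitted attenuation, amplitude-
#' matched backscattering) give `R0`.  Each loop then recomputes the
#' depth-resolved attenuation from the current R by the ratio rule,
#' re-segments, and re-fits the segment optics.  The loop stops when the
#' maximal relative change of mu falls to `rel_tol`, when the loop count
#' reaches `E`, when the mu clamp saturates everywhere, or when a
#' constraint on R (range, or spread around the mean backscatter) is
#' violated -- in which case the last valid state is returned with the
#' violation recorded.
#'
#' @param a a tail-extrapolated [ascan()] (see [extrapolate_tail()];
#'   noise-free simulations carry their analytic tail already).
#' @param beta_L0 digitized initial irradiance, A.U. * mm.
#' @param config an [iteration_config()].
#' @param mode attenuation update rule, `"ratio"` or `"correction"`.
#' @return An object of class `iteration_state`: fields `mu`, `R`
#'   (final profiles), `mu0`, `R_tilde`, `segments`, `k`, `stop_reason`
#'   (`"converged"`, `"max_loops"`, `"clamp_saturated"`,
#'   `"constraint_R_range"` or `"constraint_R_band"`), `history` (max
#'   relative change of mu per loop) and `support`.
#' @export
solve_aline <- function(a, beta_L0, config = iteration_config(),
                        mode = c("ratio", "correction")) {
  stopifnot(inherits(a, "ascan"), inherits(config, "iteration_config"),
            beta_L0 > 0)
  mode <- match.arg(mode)
  n <- a$grid$n
  mx <- max(a$values)
  if (mx <= 0) stop("all-zero A-scan: nothing to estimate")
  support <- a$values > config$support_eps * mx
  # contiguous support from the surface to the deepest usable sample
  i_top <- which(support)[1L]
  i_bot <- max(which(support))
  support <- seq_len(n) >= i_top & seq_len(n) <= i_bot
  idx_sup <- which(support)
  margin <- min(config$surface_margin, length(idx_sup) - 3L)
  idx_est <- idx_sup[idx_sup > i_top + margin - 1L]
  if (length(idx_est) < 5L) stop("support too small for estimation")

  mu0 <- vermeer_mu(a)
  mu0[!support] <- 0
  clamp <- list(lo = config$C * mu0, hi = config$D * mu0)
  R_tilde <- mean_R(a, beta_L0)

  segment_state <- function(mu_now) {
    Rraw <- init_R(a, mu_now, beta_L0, lag = 1L)
    fz <- fuzzy_process_R(Rraw[idx_est], a$grid$dz,
                          deriv_factor = config$deriv_factor,
                          halfwin = config$deriv_halfwin,
                          flat_tol = config$flat_tol)
    so <- segment_optics(a, idx_est, fz$seg_id, mu_now, beta_L0,
                         clamp_lo = config$C, clamp_hi = config$D,
                         core = !fz$breakpoint)
    # constraints on R are enforced per segment: a violating segment is
    # projected onto the nearest admissible value; a violation is fatal
    # only when it covers most of the depth
    lo <- max(config$A * R_tilde, .Machine$double.xmin)
    hi <- min(config$B * R_tilde, 1 - 1e-12)
    bad <- !is.finite(so$R_seg) | so$R_seg <= lo | so$R_seg >= hi
    frac_bad <- sum(fz$seg_id %in% which(bad)) / length(fz$seg_id)
    if (any(bad)) {
      range_bad <- any(!is.finite(so$R_seg[bad]) | so$R_seg[bad] <= 0 |
                         so$R_seg[bad] >= 1)
      so$R_seg[!is.finite(so$R_seg)] <- hi
      so$R_seg <- pmin(pmax(so$R_seg, lo), hi)
      R_new <- so$R
      for (s in which(bad)) R_new[idx_est[fz$seg_id == s]] <- so$R_seg[s]
      so$R <- R_new
    } else range_bad <- FALSE
    viol <- if (frac_bad <= 0.5) NULL
            else if (range_bad) "constraint_R_range" else "constraint_R_band"
    list(fz = fz, R = so$R, R_seg = so$R_seg, viol = viol)
  }

  st <- segment_state(mu0)
  if (!is.null(st$viol))
    stop("initialization violates constraint ", st$viol,
         ": check beta_L0 and preprocessing")
  mu_k <- mu0; R_k <- st$R; seg_k <- st$fz$segments
  history <- numeric(0)
  stop_reason <- "max_loops"
  k <- 0L
  while (k < config$E) {
    k <- k + 1L
    mu_next <- update_mu(a, R_k, mode = mode, mu_prev = mu_k,
                         support = support, clamp = clamp)
    clamped <- support & (mu_next <= clamp$lo | mu_next >= clamp$hi)
    if (all(clamped[idx_est])) {
      stop_reason <- "clamp_saturated"; k <- k - 1L; break
    }
    st_next <- segment_state(mu_next)
    if (!is.null(st_next$viol)) {
      stop_reason <- st_next$viol; k <- k - 1L; break   # roll back
    }
    chg <- max(abs(mu_next - mu_k)[idx_est] /
                 pmax(abs(mu_k)[idx_est], .Machine$double.xmin))
    history <- c(history, chg)
    mu_k <- mu_next; R_k <- st_next$R; seg_k <- st_next$fz$segments
    if (chg <= config$rel_tol) { stop_reason <- "converged"; break }
  }
  R_out <- R_k
  R_out[!support] <- NA_real_
  structure(list(mu = mu_k, R = R_out, mu0 = mu0, R_tilde = R_tilde,
                 segments = seg_k, k = k, stop_reason = stop_reason,
                 history = history, support = support, grid = a$grid),
            class = "iteration_state")
}

#' @export
print.iteration_state <- function(x, ...) {
  cat(sprintf("<iteration_state> k = %d (%s), %d segment(s), R_tilde = %.4g\n",
              x$k, x$stop_reason, nrow(x$segments), x$R_tilde))
  invisible(x)
}

#' Columnwise joint estimation over a B-scan
#'
#' Applies [solve_aline()] to every A-scan of a B-scan independently.
#' Columns that fail (e.g. all-zero) fall back to the baseline profile
#' (or zeros) and are recorded.
#'
#' @param b a [bscan()] whose columns are tail-extrapolated, or a list of
#'   tail-extrapolated [ascan()] objects sharing one grid.
#' @param beta_L0 digitized initial irradiance.
#' @param config an [iteration_config()].
#' @param mode update rule passed to [solve_aline()].
#' @return A list with matrices `mu` and `R` aligned with the input, the
#'   per-column `states`, and `failed` (column indices that fell back).
#' @export
solve_bscan <- function(b, beta_L0, config = iteration_config(),
                        mode = "ratio") {
  cols <- if (inherits(b, "bscan"))
    lapply(seq_len(ncol(b$values)), function(j) bscan_column(b, j, clip = TRUE))
  else b
  n <- cols[[1L]]$grid$n
  mu_map <- matrix(0, n, length(cols))
  R_map <- matrix(NA_real_, n, length(cols))
  states <- vector("list", length(cols))
  failed <- integer(0)
  for (j in seq_along(cols)) {
    res <- tryCatch(solve_aline(cols[[j]], beta_L0, config, mode),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, j)
      mu_fallback <- tryCatch(vermeer_mu(cols[[j]]),
                              error = function(e) rep(0, n))
      mu_map[, j] <- suppressWarnings(mu_fallback)
      states[[j]] <- res
    } else {
      mu_map[, j] <- res$mu
      R_map[, j] <- res$R
      states[[j]] <- res
    }
  }
  list(mu = mu_map, R = R_map, states = states, failed = failed)
}
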