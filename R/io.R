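# Raster and profile I/O.
#
# B-scans are stored either as single-precision TIFF (depth = rows,
# lateral = columns) with a JSON sidecar carrying the grid metadata, or as
# plain delimited text with a JSON header line.  The TIFF writer rescales
# by a power of two so that [0, 1]-range storage is exact in binary
# floating point; the scale is recorded in the sidecar.

sidecar_path <- function(path) paste0(path, ".json")

bscan_meta <- function(b, scale = 1) {
  meta <- list(z0 = b$grid$z0, dz = b$grid$dz, n = b$grid$n,
               n_alines = ncol(b$values), scale = scale)
  if (!is.na(b$lateral_pitch)) meta$lateral_pitch <- b$lateral_pitch
  meta
}

#' Write a B-scan raster
#'
#' @param b a [bscan()].
#' @param path output file path.
#' @param format `"tiff"` for 32-bit TIFF plus a `<path>.json` sidecar
#'   with the grid and scale (samples are quantized by the TIFF library,
#'   so round trips are accurate to about 1e-7 relative), or `"text"`
#'   for tab-delimited text whose first line is a JSON comment with the
#'   grid; the text path round-trips doubles losslessly.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(b, path, format = c("tiff", "text")) {
  stopifnot(inherits(b, "bscan"))
  format <- match.arg(format)
  if (format == "tiff") {
    mx <- max(abs(b$values))
    scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
    if (min(b$values) < 0)
      stop("TIFF storage requires non-negative values; clip raw data first")
    tiff::writeTIFF(b$values / scale, path, bits.per.sample = 32L)
    jsonlite::write_json(bscan_meta(b, scale), sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", jsonlite::toJSON(bscan_meta(b), auto_unbox = TRUE,
                                             digits = NA)), con)
    write.table(format(b$values, digits = 17, scientific = TRUE, trim = TRUE),
                con, sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}

#' Read a B-scan raster
#'
#' Reads rasters written by [write_bscan()].  The stored shape must match
#' the sidecar metadata and all values must be finite.
#'
#' @param path file path.
#' @param format `"tiff"` or `"text"`.
#' @return A [bscan()].
#' @export
read_bscan <- function(path, format = c("tiff", "text")) {
  format <- match.arg(format)
  if (format == "tiff") {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    vals <- tiff::readTIFF(path) * meta$scale
    if (!is.matrix(vals)) vals <- matrix(vals, nrow = meta$n)
  } else {
    first <- readLines(path, n = 1L)
    if (!startsWith(first, "# "))
      stop("text raster is missing its JSON header line")
    meta <- jsonlite::fromJSON(sub("^# ", "", first))
    vals <- as.matrix(read.table(path, sep = "\t", skip = 1L))
    dimnames(vals) <- NULL
  }
  if (nrow(vals) != meta$n || ncol(vals) != meta$n_alines)
    stop(sprintf("raster is %d x %d but metadata says %d x %d",
                 nrow(vals), ncol(vals), meta$n, meta$n_alines))
  if (any(!is.finite(vals)))
    stop("raster contains non-finite values")
  lp <- meta$lateral_pitch
  if (is.null(lp)) lp <- NA_real_
  bscan(vals, depth_grid(meta$dz, meta$n, meta$z0), lateral_pitch = lp)
}

#' Write an optical profile as CSV
#'
#' Columns `z_mm`, `mu_per_mm`, `R`.
#'
#' @param p an [optical_profile()].
#' @param path output path.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "optical_profile"))
  df <- data.frame(z_mm = depths(p$grid), mu_per_mm = p$mu, R = p$R)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an optical profile from CSV
#'
#' @param path CSV written by [write_profile()].
#' @return An [optical_profile()].
#' @export
read_profile <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  dz <- median(diff(df$z_mm))
  optical_profile(depth_grid(dz, nrow(df), df$z_mm[1]), df$mu_per_mm, df$R)
}

#' Read system parameters from JSON or YAML
#'
#' Recognized fields: `beta_L0`, `na`, `l_coh`, `db_ref` and an optional
#' `psf` block with `z_R` and `z_f`.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return A [system_params()].
#' @export
read_system_params <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  psf <- if (!is.null(lst$psf)) psf_model(lst$psf$z_R, lst$psf$z_f) else NULL
  args <- lst[intersect(names(lst), c("beta_L0", "na", "l_coh", "db_ref"))]
  do.call(system_params, c(args, list(psf = psf)))
}

#' Read a phantom specification from JSON or YAML
#'
#' Expects `surface_depth`, `beta_L0` and a `layers` list with
#' `thickness_mm`, `mu_per_mm`, `R` per layer.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return A [phantom_spec()].
#' @export
read_phantom <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  lay <- lst$layers
  if (is.data.frame(lay)) {
    layers <- data.frame(thickness = lay$thickness_mm, mu = lay$mu_per_mm,
                         R = lay$R)
  } else {
    layers <- do.call(rbind, lapply(lay, function(l)
      data.frame(thickness = l$thickness_mm, mu = l$mu_per_mm, R = l$R)))
  }
  phantom_spec(layers, surface_depth = lst$surface_depth,
               beta_L0 = lst$beta_L0)
}
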