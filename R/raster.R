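#' Multiband spectral raster
#'
#' A `spectral_raster` is a list of named 2-D reflectance grids sharing one
#' shape, with a ground sampling distance and the world coordinate of the
#' top-left corner. The coordinate convention throughout the package is:
#' pixels are `(row, col)` 0-based with the origin at the top-left corner and
#' y increasing downward; world coordinates are metres with north equal to
#' `-y` (north-up raster). Polygon vertices are pixel-corner positions in
#' `(x = col, y = row)` order.
#'
#' @param bands named list of numeric matrices (reflectance, unitless,
#'   non-negative), all of identical dimension. Typical names are
#'   `"green"`, `"red"`, `"nir"` and optionally `"blue"`.
#' @param pixel_size_m metres per (square) pixel, positive.
#' @param origin numeric length-2 world coordinate `(x, y)` of the top-left
#'   corner, metres.
#' @return an object of class `spectral_raster`.
#' @examples
#' r <- spectral_raster(list(red = matrix(0.1, 4, 4), nir = matrix(0.6, 4, 4)),
#'                      pixel_size_m = 0.03)
#' compute_ndvi(r)$values[1, 1]
#' @export
spectral_raster <- function(bands, pixel_size_m, origin = c(0, 0)) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  dims <- lapply(bands, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("all bands must share identical dimensions")
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1L || pixel_size_m <= 0)
    stop("pixel_size_m must be a single positive number")
  structure(list(bands = bands, pixel_size_m = pixel_size_m,
                 origin = as.numeric(origin)),
            class = "spectral_raster")
}

#' @export
print.spectral_raster <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<spectral_raster> %d x %d px, %.4g m/px, bands: %s\n",
              d[1], d[2], x$pixel_size_m, paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' @export
dim.spectral_raster <- function(x) dim(x$bands[[1]])

new_index_raster <- function(values, index_name, pixel_size_m, origin) {
  structure(list(values = values, index_name = index_name,
                 pixel_size_m = pixel_size_m, origin = as.numeric(origin)),
            class = "index_raster")
}

#' @export
print.index_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<index_raster:%s> %d x %d px, %.4g m/px, range [%.3f, %.3f]\n",
              x$index_name, d[1], d[2], x$pixel_size_m,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.index_raster <- function(x) dim(x$values)

get_band <- function(r, name) {
  b <- r$bands[[name]]
  if (is.null(b)) stop(sprintf("raster has no '%s' band (bands: %s)",
                               name, paste(names(r$bands), collapse = ", ")))
  b
}

normalized_difference <- function(a, b, index_name, pixel_size_m, origin) {
  den <- a + b
  zero <- den == 0
  v <- (a - b) / den
  if (any(zero)) {
    v[zero] <- 0
    message(sprintf("%s: %d zero-denominator pixel(s) set to 0",
                    index_name, sum(zero)))
  }
  new_index_raster(v, index_name, pixel_size_m, origin)
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red), per pixel. Pixels where both bands are
#' zero are defined as 0 and counted in a message. The index is invariant to
#' multiplying both bands by a positive constant.
#'
#' @param r a [spectral_raster] with `nir` and `red` bands.
#' @return an `index_raster` with values in `[-1, 1]` for non-negative bands.
#' @export
compute_ndvi <- function(r) {
  stopifnot(inherits(r, "spectral_raster"))
  normalized_difference(get_band(r, "nir"), get_band(r, "red"),
                        "NDVI", r$pixel_size_m, r$origin)
}

#' Green normalized difference vegetation index
#'
#' GNDVI = (NIR - Green) / (NIR + Green), per pixel.
#'
#' @inheritParams compute_ndvi
#' @return an `index_raster`.
#' @export
compute_gndvi <- function(r) {
  stopifnot(inherits(r, "spectral_raster"))
  normalized_difference(get_band(r, "nir"), get_band(r, "green"),
                        "GNDVI", r$pixel_size_m, r$origin)
}

# 1-D overlap-length matrix between n_in input pixels of size s and the
# output pixels of size t covering the same extent. W[j, i] = length of
# overlap between output cell j and input cell i.
overlap_weights <- function(n_in, s, t) {
  extent <- n_in * s
  n_out <- ceiling(extent / t - 1e-9)
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    lo <- (j - 1) * t
    hi <- min(j * t, extent)
    i0 <- floor(lo / s) + 1
    i1 <- min(ceiling(hi / s - 1e-12), n_in)
    for (i in i0:i1)
      W[j, i] <- max(0, min(hi, i * s) - max(lo, (i - 1) * s))
  }
  W
}

resample_matrix <- function(m, s, t) {
  Wr <- overlap_weights(nrow(m), s, t)
  Wc <- overlap_weights(ncol(m), s, t)
  num <- Wr %*% m %*% t(Wc)
  den <- rowSums(Wr) %o% rowSums(Wc)
  num / den
}

#' Degrade raster resolution by exact area-weighted averaging
#'
#' Each output pixel is the overlap-area-weighted mean of the input pixels it
#' covers; non-integer ratios (e.g. 3 cm to 13 cm) are handled by exact 1-D
#' overlap weights, not block means. Output dimensions are
#' `ceiling(extent / target_pixel_size)`; a partial boundary pixel averages
#' only the covered part of the source. When the target extent tiles the
#' source exactly, the global mean is conserved exactly.
#'
#' @param r a [spectral_raster] or `index_raster`.
#' @param target_pixel_size_m target ground sampling distance, at least the
#'   source pixel size (no upsampling).
#' @return an object of the same class as `r` at the coarser resolution.
#' @export
resample_average <- function(r, target_pixel_size_m) {
  if (target_pixel_size_m < r$pixel_size_m - 1e-12)
    stop(sprintf("target pixel size %g m is smaller than source %g m (no upsampling)",
                 target_pixel_size_m, r$pixel_size_m))
  if (inherits(r, "spectral_raster")) {
    bands <- lapply(r$bands, resample_matrix, s = r$pixel_size_m,
                    t = target_pixel_size_m)
    spectral_raster(bands, target_pixel_size_m, r$origin)
  } else if (inherits(r, "index_raster")) {
    v <- resample_matrix(r$values, r$pixel_size_m, target_pixel_size_m)
    new_index_raster(v, r$index_name, target_pixel_size_m, r$origin)
  } else stop("r must be a spectral_raster or index_raster")
}

#' Extract a rectangular patch
#'
#' Cuts a `size_px` window centred at `center_px` (0-based pixel coordinates,
#' `(x = col, y = row)`), with the origin shifted accordingly.
#'
#' @param r a [spectral_raster] or `index_raster`.
#' @param center_px numeric length-2 `(x, y)` pixel centre of the window.
#' @param size_px integer length-2 `(width, height)` in pixels.
#' @return same class as `r`.
#' @export
extract_patch <- function(r, center_px, size_px) {
  size_px <- rep_len(as.integer(size_px), 2)
  d <- dim(r)                                # (rows, cols)
  x0 <- as.integer(round(center_px[1] - size_px[1] / 2))
  y0 <- as.integer(round(center_px[2] - size_px[2] / 2))
  if (x0 < 0 || y0 < 0 || x0 + size_px[1] > d[2] || y0 + size_px[2] > d[1])
    stop(sprintf("patch window x:[%d,%d) y:[%d,%d) outside raster %d x %d",
                 x0, x0 + size_px[1], y0, y0 + size_px[2], d[2], d[1]))
  rows <- (y0 + 1):(y0 + size_px[2])
  cols <- (x0 + 1):(x0 + size_px[1])
  origin <- r$origin + c(x0, y0) * r$pixel_size_m
  if (inherits(r, "spectral_raster")) {
    spectral_raster(lapply(r$bands, function(b) b[rows, cols, drop = FALSE]),
                    r$pixel_size_m, origin)
  } else {
    new_index_raster(r$values[rows, cols, drop = FALSE], r$index_name,
                     r$pixel_size_m, origin)
  }
}

#' Write / read a scene as multiband TIFF plus JSON sidecar
#'
#' Bands are stored as a multi-plane 32-bit float TIFF; pixel size, origin and
#' band names go to a `.json` sidecar next to the image (`<path>.json`).
#'
#' @param r a [spectral_raster].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(r, path) {
  stopifnot(inherits(r, "spectral_raster"))
  d <- dim(r)
  arr <- array(0, c(d[1], d[2], length(r$bands)))
  for (i in seq_along(r$bands)) arr[, , i] <- r$bands[[i]]
  tiff::writeTIFF(arr, path, bits.per.sample = 32L)
  meta <- list(pixel_size_m = r$pixel_size_m, origin = r$origin,
               bands = names(r$bands))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scene_tiff
#' @export
read_scene_tiff <- function(path) {
  arr <- tiff::readTIFF(path, all = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  bands <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  names(bands) <- meta$bands
  spectral_raster(bands, meta$pixel_size_m, meta$origin)
}
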