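#' Synthetic orchard scene parameters
#'
#' Parameters of the synthetic olive-orchard scene generator. Defaults follow
#' the study conditions the package emulates: trees on a ~6 m grid, crowns of
#' ~1-1.6 m radius (perimeters ~6.3-10 m), total heights 2-3.5 m, shadows
#' cast along the anti-solar azimuth with length `H / tan(altitude)`, imaged
#' at 3 cm/pixel with green/red/NIR bands whose reflectances give NDVI ~0.67
#' over canopy and ~0.09 over soil.
#'
#' @param extent_m scene width/height in metres, or `NULL` (default) to size
#'   the scene automatically around the generated geometry.
#' @param spacing_m mean tree spacing (m); must exceed twice the maximum
#'   crown radius so crowns never overlap by construction.
#' @param jitter_m positional jitter standard deviation (m), truncated at
#'   2 sd so the no-overlap guarantee holds in practice.
#' @param crown_radius_range_m `(low, high)` uniform crown radius range (m).
#' @param tree_height_range_m `(low, high)` uniform total tree height (m).
#' @param pixel_size_m ground sampling distance (m/pixel).
#' @param sun_altitude_deg solar altitude in (0, 90).
#' @param sun_azimuth_deg solar azimuth, degrees clockwise from north;
#'   shadows extend along the anti-solar azimuth. The default 135 (sun in the
#'   south-east, shadows to the north-west) keeps neighbouring shadows
#'   parallel and clear of the next grid row at the default geometry.
#' @param reflectance named list with numeric vectors `canopy` and `soil`
#'   (named band means), scalar `shadow_factor` applied to soil under
#'   shadow, and `noise_sd` additive Gaussian noise (0 = noise-free).
#' @param n_trees fixed tree count, or `NULL` to draw from
#'   `trees_per_patch_range`.
#' @param trees_per_patch_range integer `(low, high)` range of trees per
#'   patch (default 1-8).
#' @param trunk_offset_m unbranched trunk height excluded from biovolume (m).
#' @param crown_wobble list `(amplitude, harmonics)`: optional low-amplitude
#'   radial perturbation `r(phi) = r (1 + a cos(k phi + phase))` keeping the
#'   true perimeter computable by quadrature; default amplitude 0 (discs).
#' @param include_blue add a blue band (visible-brightness work uses it too).
#' @param seed integer seed; the same seed reproduces a scene bit-identically.
#' @return an object of class `orchard_params`.
#' @export
orchard_params <- function(extent_m = NULL,
                           spacing_m = 6.0,
                           jitter_m = 0.25,
                           crown_radius_range_m = c(1.0, 1.6),
                           tree_height_range_m = c(2.0, 3.5),
                           pixel_size_m = 0.03,
                           sun_altitude_deg = 29.61,
                           sun_azimuth_deg = 135,
                           reflectance = list(
                             canopy = c(green = 0.20, red = 0.12,
                                        nir = 0.60, blue = 0.08),
                             soil = c(green = 0.22, red = 0.25,
                                      nir = 0.30, blue = 0.20),
                             shadow_factor = 0.35,
                             noise_sd = 0.02),
                           n_trees = NULL,
                           trees_per_patch_range = c(1L, 8L),
                           trunk_offset_m = 0.5,
                           crown_wobble = list(amplitude = 0, harmonics = 3L),
                           include_blue = FALSE,
                           seed = 1L) {
  stopifnot(pixel_size_m > 0,
            sun_altitude_deg > 0, sun_altitude_deg < 90,
            crown_radius_range_m[1] <= crown_radius_range_m[2],
            tree_height_range_m[1] <= tree_height_range_m[2],
            trees_per_patch_range[1] <= trees_per_patch_range[2],
            trees_per_patch_range[1] >= 0,
            jitter_m >= 0, trunk_offset_m >= 0)
  if (spacing_m <= 2 * crown_radius_range_m[2])
    stop("spacing_m must exceed twice the maximum crown radius (no crown overlap)")
  structure(as.list(environment()), class = "orchard_params")
}

# shadow direction unit vector in the image frame (x east, y south):
# anti-solar azimuth = sun azimuth + 180, east = sin(az), north = cos(az),
# image y = -north.
shadow_direction <- function(sun_azimuth_deg) {
  az <- (sun_azimuth_deg + 180) * pi / 180
  c(sin(az), -cos(az))
}

crown_ring <- function(center, r, wobble, phase = 0, n = 96L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  amp <- wobble$amplitude
  k <- wobble$harmonics
  rad <- r * (1 + amp * cos(k * phi + phase))
  cbind(center[1] + rad * cos(phi), center[2] + rad * sin(phi))
}

# true perimeter of the (possibly perturbed) crown by fine quadrature
crown_true_perimeter <- function(r, wobble, phase = 0) {
  amp <- wobble$amplitude
  if (amp == 0) return(2 * pi * r)
  k <- wobble$harmonics
  phi <- seq(0, 2 * pi, length.out = 4097L)
  rad <- r * (1 + amp * cos(k * phi + phase))
  drad <- -r * amp * k * sin(k * phi + phase)
  f <- sqrt(rad^2 + drad^2)
  sum((f[-1] + f[-length(f)]) / 2) * diff(phi[1:2])
}

# visible shadow ring: stadium (dilation of the segment [c, c+(L-r)u] by r)
# minus the crown disc, whose boundary is the near crown arc + the two sides
# + the far end cap. Coordinates in the (t = along u, s = lateral) frame.
shadow_ring <- function(center, r, L, u, step_deg = 6) {
  w <- c(-u[2], u[1])
  a1 <- seq(90, -90, by = -step_deg) * pi / 180        # near arc on the crown
  near <- cbind(r * cos(a1), r * sin(a1))
  a2 <- seq(-90, 90, by = step_deg) * pi / 180         # far end cap
  far <- cbind(L - r + r * cos(a2), r * sin(a2))
  ts <- rbind(near, far)
  cbind(center[1] + ts[, 1] * u[1] + ts[, 2] * w[1],
        center[2] + ts[, 1] * u[2] + ts[, 2] * w[2])
}

geometry_bbox <- function(trees) {
  pts <- do.call(rbind, lapply(trees, function(t) rbind(t$crown_xy, t$shadow_xy)))
  c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
}

#' Generate a synthetic orchard scene with known per-tree geometry
#'
#' Places trees on a jittered grid, draws crown radius and total height per
#' tree, casts a stadium-shaped shadow of length `L = H / tan(altitude)` from
#' each trunk base along the anti-solar azimuth (width equal to the crown
#' diameter), and rasterizes: soil everywhere, shadows painted as darkened
#' soil, crowns painted last (nadir imagery shows canopy, not the shadow
#' beneath it). Gaussian band noise is added when `noise_sd > 0`. The same
#' seed yields bit-identical output.
#'
#' @param params an [orchard_params].
#' @return list with elements `raster` (a [spectral_raster]) and `truth`
#'   (class `scene_truth`: per-tree id, trunk base (m), crown and shadow
#'   polygons (m, image frame), `P_true`, `H_true`, `L_true`, `V_true`,
#'   plus the sun geometry and pixel size).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "orchard_params"))
  with_seed(params$seed, generate_scene_impl(params))
}

generate_scene_impl <- function(params) {
  p <- params
  n <- p$n_trees
  if (is.null(n))
    n <- sample(seq(p$trees_per_patch_range[1], p$trees_per_patch_range[2]), 1L)
  u <- shadow_direction(p$sun_azimuth_deg)
  tan_alt <- tan(p$sun_altitude_deg * pi / 180)

  trees <- list()
  if (n > 0) {
    ncol_g <- ceiling(sqrt(n))
    nrow_g <- ceiling(n / ncol_g)
    gx <- ((seq_len(n) - 1L) %% ncol_g) * p$spacing_m
    gy <- ((seq_len(n) - 1L) %/% ncol_g) * p$spacing_m
    jx <- pmin(pmax(stats::rnorm(n, 0, p$jitter_m), -2 * p$jitter_m), 2 * p$jitter_m)
    jy <- pmin(pmax(stats::rnorm(n, 0, p$jitter_m), -2 * p$jitter_m), 2 * p$jitter_m)
    r <- stats::runif(n, p$crown_radius_range_m[1], p$crown_radius_range_m[2])
    H <- stats::runif(n, p$tree_height_range_m[1], p$tree_height_range_m[2])
    phase <- stats::runif(n, 0, 2 * pi)
    L <- H / tan_alt
    if (any(L <= r))
      stop("shadow length <= crown radius; raise tree heights or sun altitude")
    for (i in seq_len(n)) {
      ctr <- c(gx[i] + jx[i], gy[i] + jy[i])
      P_true <- crown_true_perimeter(r[i], p$crown_wobble, phase[i])
      trees[[i]] <- list(
        id = i, trunk_base = ctr, radius = r[i], crown_phase = phase[i],
        crown_xy = crown_ring(ctr, r[i], p$crown_wobble, phase[i]),
        shadow_xy = shadow_ring(ctr, r[i], L[i], u),
        P_true = P_true, H_true = H[i], L_true = L[i],
        V_true = P_true^2 / (4 * pi) * max(H[i] - p$trunk_offset_m, 0))
    }
  }

  pad <- 0.5
  if (is.null(p$extent_m)) {
    if (n == 0) {
      extent <- c(p$spacing_m, p$spacing_m)
      shift <- c(0, 0)
    } else {
      bb <- geometry_bbox(trees)
      shift <- -c(bb[1], bb[2]) + pad
      extent <- c(bb[3] - bb[1], bb[4] - bb[2]) + 2 * pad
    }
  } else {
    extent <- rep_len(p$extent_m, 2)
    if (n > 0) {
      bb <- geometry_bbox(trees)
      need <- c(bb[3] - bb[1], bb[4] - bb[2]) + 2 * pad
      if (any(need > extent + 1e-9))
        stop(sprintf(paste0("extent_m = %.2f m is too small to host the scene ",
                            "geometry (needs >= %.2f x %.2f m incl. shadows)"),
                     p$extent_m[1], need[1], need[2]))
      shift <- c((extent[1] - (bb[3] - bb[1])) / 2 - bb[1],
                 (extent[2] - (bb[4] - bb[2])) / 2 - bb[2])
    } else shift <- c(0, 0)
  }
  if (n > 0) for (i in seq_len(n)) {
    trees[[i]]$trunk_base <- trees[[i]]$trunk_base + shift
    trees[[i]]$crown_xy <- sweep(trees[[i]]$crown_xy, 2, shift, "+")
    trees[[i]]$shadow_xy <- sweep(trees[[i]]$shadow_xy, 2, shift, "+")
  }

  ps <- p$pixel_size_m
  nc <- max(1L, as.integer(ceiling(extent[1] / ps - 1e-9)))
  nr <- max(1L, as.integer(ceiling(extent[2] / ps - 1e-9)))
  xc <- (seq_len(nc) - 0.5) * ps
  yc <- (seq_len(nr) - 0.5) * ps

  band_names <- c("green", "red", "nir", if (p$include_blue) "blue")
  soil <- p$reflectance$soil[band_names]
  canopy <- p$reflectance$canopy[band_names]
  bands <- lapply(soil, function(v) matrix(v, nr, nc))

  paint <- function(mask_fn, values, window) {
    cols <- which(xc >= window[1] & xc <= window[3])
    rows <- which(yc >= window[2] & yc <= window[4])
    if (!length(cols) || !length(rows)) return(invisible())
    X <- matrix(xc[cols], length(rows), length(cols), byrow = TRUE)
    Y <- matrix(yc[rows], length(rows), length(cols))
    m <- mask_fn(X, Y)
    for (b in seq_along(bands)) {
      sub <- bands[[b]][rows, cols]
      sub[m] <- if (is.matrix(values)) values[rows, cols][m] else values[b]
      bands[[b]][rows, cols] <<- sub
    }
    invisible()
  }

  sf <- p$reflectance$shadow_factor
  for (t in trees) {                         # shadows first ...
    seg0 <- t$trunk_base
    seg1 <- t$trunk_base + (t$L_true - t$radius) * u
    r <- t$radius
    win <- c(min(t$shadow_xy[, 1]) - ps, min(t$shadow_xy[, 2]) - ps,
             max(t$shadow_xy[, 1]) + ps, max(t$shadow_xy[, 2]) + ps)
    paint(function(X, Y) {
      dx <- seg1 - seg0
      len2 <- sum(dx^2)
      tt <- pmin(pmax(((X - seg0[1]) * dx[1] + (Y - seg0[2]) * dx[2]) / len2, 0), 1)
      (X - (seg0[1] + tt * dx[1]))^2 + (Y - (seg0[2] + tt * dx[2]))^2 <= r^2
    }, soil * sf, win)
  }
  wob <- p$crown_wobble
  for (t in trees) {                         # ... crowns painted last
    ctr <- t$trunk_base; r <- t$radius
    rmax <- r * (1 + abs(wob$amplitude))
    win <- c(ctr[1] - rmax - ps, ctr[2] - rmax - ps,
             ctr[1] + rmax + ps, ctr[2] + rmax + ps)
    paint(function(X, Y) {
      if (wob$amplitude == 0) {
        (X - ctr[1])^2 + (Y - ctr[2])^2 <= r^2
      } else {
        phi <- atan2(Y - ctr[2], X - ctr[1])
        rad <- r * (1 + wob$amplitude * cos(wob$harmonics * phi +
                                              t$crown_phase %||% 0))
        (X - ctr[1])^2 + (Y - ctr[2])^2 <= rad^2
      }
    }, canopy, win)
  }

  if (p$reflectance$noise_sd > 0)
    bands <- lapply(bands, function(b)
      pmin(pmax(b + stats::rnorm(length(b), 0, p$reflectance$noise_sd), 0), 1))

  truth <- structure(list(trees = trees, pixel_size_m = ps,
                          extent_m = c(nc, nr) * ps,
                          sun_altitude_deg = p$sun_altitude_deg,
                          sun_azimuth_deg = p$sun_azimuth_deg,
                          trunk_offset_m = p$trunk_offset_m),
                     class = "scene_truth")
  list(raster = spectral_raster(bands, ps), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d tree(s), %.1f x %.1f m, sun alt %.2f az %.1f\n",
              length(x$trees), x$extent_m[1], x$extent_m[2],
              x$sun_altitude_deg, x$sun_azimuth_deg))
  invisible(x)
}

#' Per-tree truth table
#'
#' @param truth a `scene_truth` (or list of them).
#' @return data.frame with columns `tree_id`, `P_true`, `H_true`, `L_true`,
#'   `V_true` (and `patch` when given a list).
#' @export
truth_table <- function(truth) {
  one <- function(tr, patch = NA_integer_) {
    if (!length(tr$trees))
      return(data.frame(patch = integer(), tree_id = integer(),
                        P_true = numeric(), H_true = numeric(),
                        L_true = numeric(), V_true = numeric()))
    do.call(rbind, lapply(tr$trees, function(t)
      data.frame(patch = patch, tree_id = t$id, P_true = t$P_true,
                 H_true = t$H_true, L_true = t$L_true, V_true = t$V_true)))
  }
  if (inherits(truth, "scene_truth")) return(one(truth)[-1])
  do.call(rbind, lapply(seq_along(truth), function(i) one(truth[[i]], i)))
}

#' Convert scene truth to pixel-coordinate annotations
#'
#' One `"crown"` and one `"shadow"` [instance_polygon] per tree, vertices
#' divided by the pixel size.
#'
#' @param truth a `scene_truth`.
#' @param pixel_size_m metres per pixel (defaults to the truth's own).
#' @param image_id id used for the single image entry.
#' @return an [annotation_set].
#' @export
truth_to_annotations <- function(truth, pixel_size_m = truth$pixel_size_m,
                                 image_id = "scene") {
  polys <- list()
  for (t in truth$trees) {
    polys[[length(polys) + 1L]] <-
      instance_polygon(t$crown_xy / pixel_size_m, "crown")
    polys[[length(polys) + 1L]] <-
      instance_polygon(t$shadow_xy / pixel_size_m, "shadow")
  }
  a <- annotation_set(stats::setNames(list(polys), image_id))
  a$pixel_size_m <- stats::setNames(pixel_size_m, image_id)
  a
}

#' Generate a reproducible set of orchard patches
#'
#' Draws a tree count per patch from `trees_per_patch_range` and generates
#' each scene under a derived seed (`seed + patch index`), so patch sets are
#' reproducible while scenes stay independent. When `total_trees` is given,
#' the drawn counts are repaired by +/-1 steps (still within the range) until
#' they sum to it — the standard 150-patch set uses `total_trees = 600`
#' (4 trees per patch on average) to match the study's segment counts.
#'
#' @param params an [orchard_params] (its `n_trees` is ignored).
#' @param n_patches number of patches, >= 1.
#' @param seed integer master seed.
#' @param total_trees optional exact total tree count across patches.
#' @return list of `n_patches` elements, each `list(raster, truth)`.
#' @export
generate_patch_set <- function(params, n_patches, seed = params$seed,
                               total_trees = NULL) {
  stopifnot(n_patches >= 1)
  lo <- params$trees_per_patch_range[1]
  hi <- params$trees_per_patch_range[2]
  counts <- with_seed(seed, {
    k <- sample(seq(lo, hi), n_patches, replace = TRUE)
    if (!is.null(total_trees)) {
      if (total_trees < lo * n_patches || total_trees > hi * n_patches)
        stop("total_trees unreachable within trees_per_patch_range")
      while (sum(k) != total_trees) {
        if (sum(k) > total_trees) {
          i <- sample(which(k > lo), 1L); k[i] <- k[i] - 1L
        } else {
          i <- sample(which(k < hi), 1L); k[i] <- k[i] + 1L
        }
      }
    }
    k
  })
  lapply(seq_len(n_patches), function(i) {
    pi_ <- params
    pi_$n_trees <- counts[i]
    pi_$seed <- as.integer(seed) + i
    generate_scene(pi_)
  })
}

#' The standard 150-patch synthetic set
#'
#' 150 patches with 1-8 trees each and exactly 600 trees in total (hence 600
#' crown and 600 shadow segments), mirroring the study's dataset shape.
#'
#' @param seed integer master seed.
#' @param params an [orchard_params].
#' @param truth_only if `TRUE`, skip rasterization and return truths only
#'   (fast path for counting/splitting checks).
#' @return list of patches as in [generate_patch_set], or of `scene_truth`
#'   when `truth_only`.
#' @export
default_patch_set <- function(seed = 1L, params = orchard_params(),
                              truth_only = FALSE) {
  if (!truth_only) return(generate_patch_set(params, 150L, seed,
                                             total_trees = 600L))
  ps <- generate_patch_set_counts(params, 150L, seed, 600L)
  ps
}

# truth-only fast path: same seeds and draws as generate_patch_set, but stop
# after the geometry (no painting). Used where only counts/ids matter.
generate_patch_set_counts <- function(params, n_patches, seed, total_trees) {
  big <- params
  big$pixel_size_m <- 1    # coarse grid: geometry identical, painting cheap
  set <- generate_patch_set(big, n_patches, seed, total_trees)
  lapply(set, function(s) s$truth)
}
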