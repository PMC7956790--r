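#' Biovolume configuration
#'
#' @param trunk_offset_m unbranched trunk height excluded from the cylinder
#'   (m); default 0.5.
#' @param theta_deg solar altitude used for the height conversion, in
#'   (0, 90).
#' @param rounding decimals used when formatting reported tables: 1 for
#'   P/L/h and 2 for V (volumes are always computed from unrounded
#'   intermediates).
#' @return object of class `biovolume_config`.
#' @export
biovolume_config <- function(trunk_offset_m = 0.5, theta_deg = 29.61,
                             rounding = c(PLh = 1, V = 2)) {
  stopifnot(trunk_offset_m >= 0, theta_deg > 0, theta_deg < 90)
  structure(list(trunk_offset_m = trunk_offset_m, theta_deg = theta_deg,
                 rounding = rounding),
            class = "biovolume_config")
}

#' Crown perimeter in metres
#'
#' Sum of edge lengths of the (optionally simplified) closed crown ring,
#' scaled by the pixel size. Simplification (default tolerance 1 px)
#' counters the staircase inflation of rasterized boundaries.
#'
#' @param polygon a crown [instance_polygon] (pixel coordinates).
#' @param pixel_size_m metres per pixel.
#' @param simplify_tol_px Douglas-Peucker tolerance; 0 disables.
#' @return perimeter in metres.
#' @export
crown_perimeter <- function(polygon, pixel_size_m, simplify_tol_px = 1.0) {
  stopifnot(inherits(polygon, "instance_polygon"))
  v <- simplify_ring(polygon$vertices, simplify_tol_px)
  if (nrow(v) < 3 || abs(shoelace_area(v)) < 1e-9)
    stop("degenerate crown ring after simplification")
  ring_length(v) * pixel_size_m
}

#' Crown surface as the circle of equal perimeter
#'
#' `S = P^2 / (4 pi)`: the area of the circle whose circumference equals the
#' crown-polygon perimeter (the cylinder base of the biovolume model).
#'
#' @param P_m crown perimeter in metres, positive.
#' @return surface in square metres.
#' @export
crown_surface <- function(P_m) {
  if (!is.numeric(P_m) || any(P_m <= 0)) stop("perimeter must be positive")
  P_m^2 / (4 * pi)
}

#' Shadow length along the anti-solar azimuth
#'
#' Projects all shadow vertices onto the anti-solar unit vector; the length
#' is the far-end projection minus the projection of the crown-boundary
#' vertex nearest the shadow's near end, in metres. A shadow lying behind
#' the crown along the axis (negative length) is an error; a shadow whose
#' along-axis extent is smaller than its lateral extent triggers a sanity
#' warning (azimuth likely wrong).
#'
#' @param crown,shadow paired [instance_polygon]s on one image (pixel
#'   coordinates).
#' @param azimuth_deg solar azimuth, degrees clockwise from north.
#' @param pixel_size_m metres per pixel.
#' @return shadow length in metres.
#' @export
shadow_length <- function(crown, shadow, azimuth_deg, pixel_size_m) {
  u <- shadow_direction(azimuth_deg)
  ps <- shadow$vertices %*% u
  near <- shadow$vertices[which.min(ps), ]
  d2 <- (crown$vertices[, 1] - near[1])^2 + (crown$vertices[, 2] - near[2])^2
  p0 <- sum(crown$vertices[which.min(d2), ] * u)
  L_px <- max(ps) - p0
  if (L_px <= 0)
    stop(sprintf("shadow lies behind the crown along azimuth %.1f (L = %.2f px)",
                 azimuth_deg, L_px))
  w <- c(-u[2], u[1])
  lateral <- diff(range(shadow$vertices %*% w))
  if (max(ps) - min(ps) < lateral)
    warning("shadow extent along the anti-solar axis is smaller than its width; check the azimuth")
  L_px * pixel_size_m
}

#' Tree height from shadow length
#'
#' `h = L tan(theta)` with theta the solar altitude: the flagpole model on
#' flat terrain.
#'
#' @param L_m shadow length in metres, non-negative.
#' @param theta_deg solar altitude in (0, 90) degrees.
#' @return height in metres.
#' @export
tree_height <- function(L_m, theta_deg) {
  if (any(theta_deg <= 0) || any(theta_deg >= 90))
    stop("solar altitude must lie strictly between 0 and 90 degrees")
  if (any(L_m < 0)) stop("shadow length must be non-negative")
  L_m * tan(theta_deg * pi / 180)
}

#' Cylinder biovolume
#'
#' `V = S * max(h - trunk_offset, 0)`: the crown-perimeter circle as the
#' cylinder base times the branched height. Heights at or below the trunk
#' offset clamp the volume to zero with a warning (segmentation noise can
#' shorten shadows), rather than erroring.
#'
#' @param S_m2 crown surface in square metres, positive.
#' @param h_m tree height in metres, non-negative.
#' @param cfg a [biovolume_config] (its `trunk_offset_m` is used).
#' @return volume in cubic metres.
#' @export
biovolume <- function(S_m2, h_m, cfg = biovolume_config()) {
  stopifnot(all(S_m2 > 0), all(h_m >= 0))
  eff <- h_m - cfg$trunk_offset_m
  if (any(eff <= 0)) {
    warning(sprintf("%d height(s) at or below the %.2f m trunk offset; volume clamped to 0",
                    sum(eff <= 0), cfg$trunk_offset_m))
    eff <- pmax(eff, 0)
  }
  S_m2 * eff
}

#' Overall biovolume accuracy
#'
#' `accuracy = (1 - mean(|V_G - V_M| / V_G)) * 100`: one hundred minus the
#' mean absolute relative volume error in percent. Equals 100 iff the two
#' vectors agree elementwise; may be negative for gross errors.
#'
#' @param V_G ground-truth volumes, all positive.
#' @param V_M estimated volumes, same length.
#' @return accuracy in percent.
#' @export
overall_accuracy <- function(V_G, V_M) {
  if (length(V_G) != length(V_M) || length(V_G) < 1)
    stop("V_G and V_M must have equal, non-zero length")
  if (any(V_G <= 0)) stop("all ground-truth volumes must be positive")
  (1 - mean(abs(V_G - V_M) / V_G)) * 100
}

#' Pair crown instances with their shadows
#'
#' Each crown is paired with the nearest shadow whose centroid lies within
#' +/- 60 degrees of the anti-solar azimuth from the crown centroid;
#' pairing is one-to-one (closest pairs first). Unpaired instances are
#' returned, never an error.
#'
#' @param crowns,shadows lists of [instance_polygon]s from one image.
#' @param azimuth_deg solar azimuth, degrees clockwise from north.
#' @return list with `pairs` (data.frame `crown`, `shadow`, `distance_px`),
#'   `unpaired_crowns`, `unpaired_shadows` (integer indices).
#' @export
pair_crowns_shadows <- function(crowns, shadows, azimuth_deg) {
  u <- shadow_direction(azimuth_deg)
  nc <- length(crowns); ns <- length(shadows)
  cand <- list()
  for (i in seq_len(nc)) {
    cc <- polygon_centroid(crowns[[i]]$vertices)
    for (j in seq_len(ns)) {
      sc <- polygon_centroid(shadows[[j]]$vertices)
      d <- sc - cc
      dist <- sqrt(sum(d^2))
      if (dist < 1e-9) next
      ang <- acos(min(max(sum(d * u) / dist, -1), 1)) * 180 / pi
      if (ang <= 60)
        cand[[length(cand) + 1L]] <- c(i, j, dist)
    }
  }
  pairs <- data.frame(crown = integer(), shadow = integer(),
                      distance_px = numeric())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, 3]), , drop = FALSE]
    cfree <- rep(TRUE, nc); sfree <- rep(TRUE, ns)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (cfree[i] && sfree[j]) {
        cfree[i] <- FALSE; sfree[j] <- FALSE
        pairs <- rbind(pairs, data.frame(crown = i, shadow = j,
                                         distance_px = cand[k, 3]))
      }
    }
  } else { cfree <- rep(TRUE, nc); sfree <- rep(TRUE, ns) }
  list(pairs = pairs,
       unpaired_crowns = which(cfree),
       unpaired_shadows = which(sfree))
}

#' Per-tree measurements from segmented crowns and shadows
#'
#' Pairs instances, then derives per pair the crown perimeter `P`, surface
#' `S = P^2/(4 pi)`, shadow length `L`, height `h = L tan(theta)` and
#' cylinder volume `V = S (h - trunk offset)`.
#'
#' @param crowns,shadows lists of [instance_polygon]s from one image.
#' @param theta_deg solar altitude in degrees.
#' @param azimuth_deg solar azimuth in degrees.
#' @param pixel_size_m metres per pixel.
#' @param cfg a [biovolume_config].
#' @param simplify_tol_px perimeter simplification tolerance.
#' @return data.frame of class `tree_measurements` with columns `tree_id`,
#'   `P`, `S`, `L`, `h`, `V` plus attribute `unpaired`.
#' @export
measure_trees <- function(crowns, shadows, theta_deg, azimuth_deg,
                          pixel_size_m, cfg = biovolume_config(theta_deg = theta_deg),
                          simplify_tol_px = 0) {
  pr <- pair_crowns_shadows(crowns, shadows, azimuth_deg)
  rows <- lapply(seq_len(nrow(pr$pairs)), function(k) {
    i <- pr$pairs$crown[k]; j <- pr$pairs$shadow[k]
    P <- crown_perimeter(crowns[[i]], pixel_size_m, simplify_tol_px)
    S <- crown_surface(P)
    L <- shadow_length(crowns[[i]], shadows[[j]], azimuth_deg, pixel_size_m)
    h <- tree_height(L, theta_deg)
    V <- suppressWarnings(biovolume(S, h, cfg))
    data.frame(tree_id = k, crown = i, shadow = j, P = P, S = S, L = L,
               h = h, V = V)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(tree_id = integer(), crown = integer(), shadow = integer(),
                  P = numeric(), S = numeric(), L = numeric(), h = numeric(),
                  V = numeric())
  attr(out, "unpaired") <- pr[c("unpaired_crowns", "unpaired_shadows")]
  class(out) <- c("tree_measurements", "data.frame")
  out
}
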