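#' Reference segmenter configuration
#'
#' Configuration of the deterministic threshold-based segmenter that stands
#' in for a learned instance-segmentation model and defines the ingestion
#' contract for external masks. Crowns are found by thresholding a
#' vegetation index; shadows by thresholding inverted visible brightness
#' (mean of the visible bands) after excluding crown pixels.
#'
#' @param crown_index `"ndvi"` or `"gndvi"`.
#' @param crown_threshold numeric fixed threshold on the index, or `"otsu"`.
#' @param shadow_threshold numeric fixed threshold on visible brightness, or
#'   `"otsu"` (computed on non-crown pixels; pixels below it are shadow).
#' @param min_area_px connected components smaller than this are dropped.
#' @param simplify_tol_px polygon simplification tolerance in pixels
#'   (Douglas-Peucker, default 1.0).
#' @param max_crown_area_px optional sanity bound: a warning is emitted when
#'   a component exceeds twice this area (touching crowns).
#' @param min_contrast minimum separation of the two Otsu class means for a
#'   foreground to be declared at all; guards against splitting unimodal
#'   noise on scenes without trees (or without shadows). In index units for
#'   crowns, reflectance units for shadows. Ignored for fixed thresholds.
#' @return object of class `segmenter_config`.
#' @export
segmenter_config <- function(crown_index = c("ndvi", "gndvi"),
                             crown_threshold = "otsu",
                             shadow_threshold = "otsu",
                             min_area_px = 10L,
                             simplify_tol_px = 1.0,
                             max_crown_area_px = NULL,
                             min_contrast = 0.1) {
  crown_index <- match.arg(crown_index)
  stopifnot(min_area_px >= 1)
  structure(list(crown_index = crown_index, crown_threshold = crown_threshold,
                 shadow_threshold = shadow_threshold,
                 min_area_px = as.integer(min_area_px),
                 simplify_tol_px = simplify_tol_px,
                 max_crown_area_px = max_crown_area_px,
                 min_contrast = min_contrast),
            class = "segmenter_config")
}

# Otsu threshold that refuses unimodal data: returns NA when the two class
# means are closer than min_contrast
guarded_otsu <- function(values, range, min_contrast) {
  if (diff(range) < 1e-9 || diff(range(values)) < min_contrast / 4)
    return(NA_real_)
  thr <- otsu_threshold(values, range)
  lo <- values[values <= thr]; hi <- values[values > thr]
  if (!length(lo) || !length(hi)) return(NA_real_)
  if (mean(hi) - mean(lo) < min_contrast) return(NA_real_)
  thr
}

# 8-connected component labeling. The pixel adjacency graph (4 shift
# directions, undirected) is handed to igraph::components; returns an
# integer matrix of labels (0 = background).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(fg)) return(lab)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  edges <- integer(0)
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    dr <- sh[1]; dc <- sh[2]
    r <- ((fg - 1L) %% nr) + 1L
    c <- ((fg - 1L) %/% nr) + 1L
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    nb <- fg[ok] + dr + dc * nr
    keep <- mask[nb]
    if (any(keep))
      edges <- c(edges, rbind(id[fg[ok][keep]], id[nb[keep]]))
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else comp <- seq_along(fg)
  lab[fg] <- as.integer(comp)
  lab
}

# Trace the outer boundary of the foreground of `mask` as a closed ring of
# 0-based pixel-corner coordinates (x = col, y = row), by crack following
# along pixel edges with the interior on the left (positive shoelace area in
# the y-down frame). 8-connected pinch corners are resolved by preferring
# the left turn, which keeps diagonally-touching pixels on one ring.
trace_boundary <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (!length(fg)) stop("cannot trace boundary of an empty mask")
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  bg_at <- function(rr, cc)
    rr < 1L | rr > nr | cc < 1L | cc > nc | !mask[cbind(pmin(pmax(rr, 1L), nr),
                                                        pmin(pmax(cc, 1L), nc))]
  key <- function(x, y) y * (nc + 1L) + x + 1L
  ef <- integer(0); et <- integer(0)
  add <- function(x1, y1, x2, y2) {
    ef <<- c(ef, key(x1, y1)); et <<- c(et, key(x2, y2))
  }
  up <- bg_at(r - 1L, c); rt <- bg_at(r, c + 1L)
  dn <- bg_at(r + 1L, c); lt <- bg_at(r, c - 1L)
  # per-side directed edges (corner coords are 0-based: pixel (r,c) spans
  # x in [c-1, c], y in [r-1, r])
  if (any(up)) add(c[up] - 1L, r[up] - 1L, c[up], r[up] - 1L)
  if (any(rt)) add(c[rt], r[rt] - 1L, c[rt], r[rt])
  if (any(dn)) add(c[dn], r[dn], c[dn] - 1L, r[dn])
  if (any(lt)) add(c[lt] - 1L, r[lt], c[lt] - 1L, r[lt] - 1L)
  from_x <- (ef - 1L) %% (nc + 1L); from_y <- (ef - 1L) %/% (nc + 1L)
  to_x <- (et - 1L) %% (nc + 1L); to_y <- (et - 1L) %/% (nc + 1L)
  by_from <- split(seq_along(ef), ef)
  used <- logical(length(ef))
  # start at the top edge of the topmost(-then-leftmost) pixel
  rmin <- min(r); cmin <- min(c[r == rmin])
  start_key <- key(cmin - 1L, rmin - 1L)
  cand <- by_from[[as.character(start_key)]]
  cur <- cand[to_y[cand] == rmin - 1L][1]          # its top edge goes right
  ring <- matrix(0L, length(ef) + 1L, 2L)
  n_pts <- 0L
  first <- cur
  repeat {
    used[cur] <- TRUE
    n_pts <- n_pts + 1L
    ring[n_pts, ] <- c(from_x[cur], from_y[cur])
    nxt_key <- et[cur]
    cand <- by_from[[as.character(nxt_key)]]
    cand <- cand[!used[cand]]
    if (!length(cand)) break
    if (length(cand) == 1L) cur <- cand
    else {
      dx <- to_x[cur] - from_x[cur]; dy <- to_y[cur] - from_y[cur]
      prefs <- rbind(c(dy, -dx), c(dx, dy), c(-dy, dx))  # left, straight, right
      cur <- NA_integer_
      for (k in 1:3) {
        hit <- cand[(to_x[cand] - (from_x[cand])) == prefs[k, 1] &
                      (to_y[cand] - (from_y[cand])) == prefs[k, 2]]
        if (length(hit)) { cur <- hit[1]; break }
      }
      if (is.na(cur)) cur <- cand[1]
    }
  }
  ring[seq_len(n_pts), , drop = FALSE]
}

# drop collinear intermediate vertices of a closed integer/numeric ring
collapse_collinear <- function(v) {
  n <- nrow(v)
  if (n < 4) return(v)
  prev <- v[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- v[c(2:n, 1), , drop = FALSE]
  cross <- (v[, 1] - prev[, 1]) * (nxt[, 2] - v[, 2]) -
    (v[, 2] - prev[, 2]) * (nxt[, 1] - v[, 1])
  keep <- abs(cross) > 1e-12
  if (!any(keep)) return(v[1:3, , drop = FALSE])
  v[keep, , drop = FALSE]
}

dp_chain <- function(v, tol) {
  n <- nrow(v)
  if (n <= 2) return(v)
  a <- v[1, ]; b <- v[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < 1e-12) sqrt((v[, 1] - a[1])^2 + (v[, 2] - a[2])^2)
  else abs((v[, 1] - a[1]) * ab[2] - (v[, 2] - a[2]) * ab[1]) / len
  i <- which.max(d)
  if (d[i] <= tol) return(v[c(1, n), , drop = FALSE])
  left <- dp_chain(v[1:i, , drop = FALSE], tol)
  right <- dp_chain(v[i:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# Douglas-Peucker on a closed ring: split at the vertex farthest from the
# first vertex, simplify both chains, rejoin.
simplify_ring <- function(v, tol) {
  if (tol <= 0 || nrow(v) <= 4) return(v)
  d <- sqrt((v[, 1] - v[1, 1])^2 + (v[, 2] - v[1, 2])^2)
  k <- which.max(d)
  c1 <- dp_chain(v[1:k, , drop = FALSE], tol)
  c2 <- dp_chain(rbind(v[k:nrow(v), , drop = FALSE], v[1, , drop = FALSE]), tol)
  out <- rbind(c1[-nrow(c1), , drop = FALSE], c2[-nrow(c2), , drop = FALSE])
  if (nrow(out) < 3) v[round(seq(1, nrow(v), length.out = 4))[1:3], , drop = FALSE]
  else out
}

#' Convert a single-component binary mask to a boundary polygon
#'
#' Traces the outer boundary along pixel edges (vertices at 0-based pixel
#' corners), removes collinear vertices and applies Douglas-Peucker
#' simplification. The ring is closed implicitly and has positive shoelace
#' area in the y-down image frame.
#'
#' @param grid binary matrix with exactly one 8-connected foreground
#'   component.
#' @param simplify_tol_px simplification tolerance in pixels; 0 disables.
#' @return numeric matrix of `(x, y)` vertices.
#' @export
mask_to_polygon <- function(grid, simplify_tol_px = 1.0) {
  lab <- label_components(grid)
  k <- max(lab)
  if (k == 0L) stop("mask has no foreground component")
  if (k > 1L) stop(sprintf("mask has %d components; expected exactly one", k))
  ring <- collapse_collinear(trace_boundary(lab == 1L))
  simplify_ring(ring, simplify_tol_px)
}

#' Rasterize a polygon onto a pixel grid
#'
#' Marks pixels whose centre `(col - 0.5, row - 0.5)` (0-based corner
#' coordinates) falls inside the ring.
#'
#' @param vertices `(x, y)` ring matrix.
#' @param nrow,ncol grid dimensions.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(vertices, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  cols <- which(seq_len(ncol) - 0.5 >= min(vertices[, 1]) - 1 &
                  seq_len(ncol) - 0.5 <= max(vertices[, 1]) + 1)
  rows <- which(seq_len(nrow) - 0.5 >= min(vertices[, 2]) - 1 &
                  seq_len(nrow) - 0.5 <= max(vertices[, 2]) + 1)
  if (!length(cols) || !length(rows)) return(out)
  pts <- cbind(rep(cols - 0.5, each = length(rows)),
               rep(rows - 0.5, times = length(cols)))
  inside <- mgcv::in.out(rbind(vertices, vertices[1, ]), pts)
  out[cbind(rep(rows, times = length(cols))[inside],
            rep(cols, each = length(rows))[inside])] <- TRUE
  out
}

otsu_threshold <- function(values, range) {
  v01 <- (values - range[1]) / (range[2] - range[1])
  t01 <- EBImage::otsu(EBImage::Image(matrix(v01, nrow = 1)), range = c(0, 1))
  range[1] + t01 * (range[2] - range[1])
}

crown_index_raster <- function(raster, cfg) {
  if (inherits(raster, "index_raster")) return(raster)
  switch(cfg$crown_index,
         ndvi = compute_ndvi(raster),
         gndvi = compute_gndvi(raster))
}

components_to_polygons <- function(mask, values, thr, label, cfg,
                                   higher_is_stronger = TRUE) {
  lab <- label_components(mask)
  k <- max(lab)
  out <- list()
  if (k == 0L) return(out)
  gbest <- if (higher_is_stronger) max(values[mask]) else min(values[mask])
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  if (!is.null(cfg$max_crown_area_px) && label == "crown" &&
      any(sizes >= cfg$min_area_px & sizes > 2 * cfg$max_crown_area_px))
    warning("component larger than twice the expected maximum crown area; touching crowns?")
  for (i in seq_len(k)) {
    if (sizes[i] < cfg$min_area_px) next
    comp <- lab == i
    ring <- simplify_ring(collapse_collinear(trace_boundary(comp)),
                          cfg$simplify_tol_px)
    m <- mean(values[comp])
    conf <- if (higher_is_stronger) (m - thr) / max(gbest - thr, 1e-12)
    else (thr - m) / max(thr - gbest, 1e-12)
    out[[length(out) + 1L]] <-
      instance_polygon(ring, label, min(max(conf, 0), 1))
  }
  out
}

#' Segment tree crowns from a raster
#'
#' Thresholds the configured vegetation index (Otsu by default), labels
#' 8-connected components, drops those below `min_area_px`, traces each
#' component boundary and simplifies it. Confidence is the component's mean
#' foreground index, normalized between the threshold and the scene maximum
#' (a component at the index maximum has confidence 1).
#'
#' @param raster a [spectral_raster] (index computed on the fly) or an
#'   `index_raster` (used directly).
#' @param cfg a [segmenter_config].
#' @return list of [instance_polygon]s with label `"crown"`.
#' @export
segment_crowns <- function(raster, cfg = segmenter_config()) {
  idx <- crown_index_raster(raster, cfg)
  thr <- if (identical(cfg$crown_threshold, "otsu"))
    guarded_otsu(idx$values, c(-1, 1), cfg$min_contrast)
  else cfg$crown_threshold
  if (is.na(thr)) return(list())
  mask <- idx$values > thr
  if (!any(mask)) return(list())
  components_to_polygons(mask, idx$values, thr, "crown", cfg)
}

visible_brightness <- function(raster) {
  vis <- intersect(c("blue", "green", "red"), names(raster$bands))
  if (!length(vis)) stop("raster has no visible band for brightness")
  Reduce(`+`, raster$bands[vis]) / length(vis)
}

#' Segment tree shadows from a raster
#'
#' Shadows are dark regions of the visible-brightness proxy (mean of the
#' visible bands). Crown pixels (from the crown index threshold) are
#' excluded before the shadow threshold is computed and applied, so canopy
#' is never mistaken for shadow. Confidence is the normalized darkness of
#' the component.
#'
#' @inheritParams segment_crowns
#' @return list of [instance_polygon]s with label `"shadow"`.
#' @export
segment_shadows <- function(raster, cfg = segmenter_config()) {
  stopifnot(inherits(raster, "spectral_raster"))
  bright <- visible_brightness(raster)
  idx <- crown_index_raster(raster, cfg)
  thr_c <- if (identical(cfg$crown_threshold, "otsu"))
    guarded_otsu(idx$values, c(-1, 1), cfg$min_contrast)
  else cfg$crown_threshold
  crown_mask <- if (is.na(thr_c)) idx$values > Inf else idx$values > thr_c
  keep <- !crown_mask
  if (!any(keep)) return(list())
  thr <- if (identical(cfg$shadow_threshold, "otsu"))
    guarded_otsu(bright[keep], range(bright[keep]), cfg$min_contrast)
  else cfg$shadow_threshold
  if (is.na(thr)) return(list())
  mask <- keep & bright < thr
  if (!any(mask)) return(list())
  components_to_polygons(mask, bright, thr, "shadow", cfg,
                         higher_is_stronger = FALSE)
}

#' Ingest external per-instance masks
#'
#' Adapter for model outputs delivered as a labeled integer grid (0 =
#' background, k = instance k): each label becomes an [instance_polygon], so
#' any external segmentation model can be slotted in front of the
#' evaluation and biovolume stages. VIA JSON predictions go through
#' [read_via_json] instead.
#'
#' @param labels integer matrix of instance labels.
#' @param label class of all instances, `"crown"` or `"shadow"`.
#' @param confidence optional numeric vector of per-instance confidences.
#' @param simplify_tol_px simplification tolerance.
#' @return list of [instance_polygon]s.
#' @export
masks_to_instances <- function(labels, label = "crown", confidence = NULL,
                               simplify_tol_px = 1.0) {
  ks <- setdiff(sort(unique(as.vector(labels))), 0)
  lapply(seq_along(ks), function(j) {
    ring <- mask_to_polygon(labels == ks[j], simplify_tol_px)
    instance_polygon(ring, label,
                     if (is.null(confidence)) 1.0 else confidence[j])
  })
}
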