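# Polygon primitives shared by the annotation, segmentation and geometry
# modules. Vertices are (x, y) pixel (or metre) coordinates, implicitly
# closed. Canonical winding has positive shoelace area in the y-down frame.

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(v) {
  a <- shoelace_area(v)
  if (abs(a) < 1e-12) return(colMeans(v))
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v); j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

ring_length <- function(v) {
  n <- nrow(v); j <- c(2:n, 1)
  sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
}

# segment-intersection test for self-intersection screening (non-adjacent
# proper crossings only; shared endpoints of neighbouring edges are fine)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_self_intersecting <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 2)) {
    for (k in (i + 2):n) {
      if (i == 1 && k == n) next            # adjacent around the wrap
      if (segments_cross(v[idx[i, 1], ], v[idx[i, 2], ],
                         v[idx[k, 1], ], v[idx[k, 2], ])) return(TRUE)
    }
  }
  FALSE
}

#' Labeled instance polygon
#'
#' An annotated crown or shadow instance: an ordered, implicitly closed ring
#' of at least three `(x, y)` pixel-corner vertices with a class label and a
#' confidence. The ring is canonicalized to positive shoelace area (in the
#' y-down image frame) on construction.
#'
#' @param vertices numeric matrix with two columns `(x, y)`, at least 3 rows.
#' @param label `"crown"` or `"shadow"`.
#' @param confidence in `[0, 1]`; 1 for manual annotations.
#' @return an object of class `instance_polygon` with fields `vertices`,
#'   `label`, `confidence` and derived `bbox` `(xmin, ymin, xmax, ymax)`.
#' @export
instance_polygon <- function(vertices, label = c("crown", "shadow"),
                             confidence = 1.0) {
  label <- match.arg(label)
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, is.numeric(vertices))
  if (nrow(vertices) < 3) stop("instance polygon needs at least 3 vertices")
  a <- shoelace_area(vertices)
  if (abs(a) < 1e-9) stop("instance polygon has zero shoelace area")
  if (a < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  stopifnot(confidence >= 0, confidence <= 1)
  structure(list(vertices = vertices, label = label,
                 confidence = as.numeric(confidence),
                 bbox = c(xmin = min(vertices[, 1]), ymin = min(vertices[, 2]),
                          xmax = max(vertices[, 1]), ymax = max(vertices[, 2]))),
            class = "instance_polygon")
}

#' @export
print.instance_polygon <- function(x, ...) {
  cat(sprintf("<instance_polygon:%s> %d vertices, area %.2f, conf %.3f\n",
              x$label, nrow(x$vertices), shoelace_area(x$vertices),
              x$confidence))
  invisible(x)
}

#' Polygon area and perimeter in pixel units
#' @param p an [instance_polygon].
#' @return numeric scalar.
#' @export
polygon_area <- function(p) abs(shoelace_area(p$vertices))

#' @rdname polygon_area
#' @export
polygon_perimeter <- function(p) ring_length(p$vertices)
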