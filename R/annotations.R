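#' Annotation set
#'
#' A named collection mapping image id to a list of [instance_polygon]s, with
#' optional per-image pixel size metadata (metres per pixel).
#'
#' @param images named list: image id -> list of [instance_polygon].
#' @param pixel_size_m optional named numeric vector of per-image pixel sizes.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(images = list(), pixel_size_m = NULL) {
  if (length(images) && anyDuplicated(names(images)))
    stop("image ids must be unique")
  structure(list(images = images, pixel_size_m = pixel_size_m),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n <- sum(vapply(x$images, length, 1L))
  cat(sprintf("<annotation_set> %d image(s), %d polygon(s)\n",
              length(x$images), n))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$images)

# case-insensitive class-name synonyms; VIA attribute keys are free-form
.label_synonyms <- list(
  crown  = c("crown", "tree", "olive", "olive tree", "tree crown", "canopy"),
  shadow = c("shadow", "tree shadow", "olive shadow")
)

normalize_label <- function(x, synonyms = .label_synonyms) {
  lx <- tolower(trimws(as.character(x)))
  for (lab in names(synonyms)) if (lx %in% synonyms[[lab]]) return(lab)
  NA_character_
}

#' Read VGG Image Annotator (VIA) 1.x polygon annotations
#'
#' Parses a VIA 1.x JSON document. Both `regions` dialects (mapping keyed
#' `"0"`, `"1"`, ... and plain sequence) are accepted. Polygon regions with
#' `all_points_x` / `all_points_y` shape attributes become
#' [instance_polygon]s; the class is read from the `region_attributes` key
#' `"class"` (falling back to the first attribute value), matched
#' case-insensitively against a synonym table (`"tree"`, `"olive"`,
#' `"crown"` -> crown; `"shadow"` -> shadow). Non-polygon regions, rings with
#' fewer than 3 points, and self-intersecting rings are skipped with a
#' warning, never fatally.
#'
#' @param text JSON string, or a file path to one.
#' @return an [annotation_set].
#' @export
read_via_json <- function(text) {
  if (length(text) == 1 && !grepl("\\{", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  images <- list()
  for (key in names(doc)) {
    entry <- doc[[key]]
    id <- if (!is.null(entry$filename)) entry$filename else key
    regions <- entry$regions
    if (is.null(regions)) regions <- list()
    if (!is.null(names(regions))) regions <- unname(regions[order(
      suppressWarnings(as.numeric(names(regions))))])
    polys <- list()
    for (reg in regions) {
      sa <- reg$shape_attributes
      if (is.null(sa) || !identical(sa$name, "polygon")) {
        warning(sprintf("image '%s': skipping non-polygon region", id))
        next
      }
      x <- unlist(sa$all_points_x); y <- unlist(sa$all_points_y)
      if (length(x) < 3 || length(x) != length(y)) {
        warning(sprintf("image '%s': rejecting polygon with <3 points", id))
        next
      }
      v <- cbind(x, y)
      if (abs(shoelace_area(v)) < 1e-9) {
        warning(sprintf("image '%s': rejecting zero-area polygon", id))
        next
      }
      if (is_self_intersecting(v)) {
        warning(sprintf("image '%s': rejecting self-intersecting polygon", id))
        next
      }
      ra <- reg$region_attributes
      raw <- if (!is.null(ra$class)) ra$class
             else if (length(ra)) ra[[1]] else ""
      lab <- normalize_label(raw)
      if (is.na(lab)) {
        warning(sprintf("image '%s': unknown class '%s', skipping", id, raw))
        next
      }
      conf <- if (!is.null(ra$confidence))
        as.numeric(ra$confidence) else 1.0
      polys[[length(polys) + 1L]] <- instance_polygon(v, lab, conf)
    }
    images[[id]] <- polys
  }
  annotation_set(images)
}

#' Write an annotation set as VIA 1.x JSON
#'
#' Emits the regions-as-mapping dialect with regions keyed `"0"`, `"1"`, ...
#' in deterministic order. `read_via_json(write_via_json(a))` is the identity
#' on polygon coordinates and labels.
#'
#' @param set an [annotation_set].
#' @param path optional file path; if `NULL` the JSON text is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
write_via_json <- function(set, path = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  doc <- list()
  for (id in names(set$images)) {
    regions <- list()
    polys <- set$images[[id]]
    for (i in seq_along(polys)) {
      p <- polys[[i]]
      regions[[as.character(i - 1L)]] <- list(
        shape_attributes = list(
          name = "polygon",
          all_points_x = as.numeric(p$vertices[, 1]),
          all_points_y = as.numeric(p$vertices[, 2])),
        region_attributes = list(class = p$label,
                                 confidence = p$confidence))
    }
    doc[[id]] <- list(filename = id, size = -1L, regions = regions,
                      file_attributes = structure(list(), names = character()))
  }
  if (!length(doc)) doc <- structure(list(), names = character())
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Flatten an annotation set to a CSV-friendly data frame
#'
#' One row per polygon with a WKT-style vertex string.
#'
#' @param set an [annotation_set].
#' @return data.frame with columns `image_id`, `label`, `confidence`, `wkt`.
#' @export
annotations_to_csv <- function(set) {
  rows <- list()
  for (id in names(set$images)) for (p in set$images[[id]]) {
    v <- rbind(p$vertices, p$vertices[1, ])
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = id, label = p$label, confidence = p$confidence,
      wkt = sprintf("POLYGON ((%s))",
                    paste(sprintf("%g %g", v[, 1], v[, 2]), collapse = ", ")),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(image_id = character(), label = character(),
                      confidence = numeric(), wkt = character()))
  do.call(rbind, rows)
}

#' Random train/test split of image ids
#'
#' Uniform random partition, deterministic under `seed`, with
#' `|train| = round(fraction * n)`.
#'
#' @param ids character or integer vector of image ids, length >= 2.
#' @param fraction train fraction in (0, 1); default 0.8.
#' @param seed integer RNG seed.
#' @return list with class `dataset_split`: `train_ids`, `test_ids`,
#'   `fraction`, `seed`.
#' @export
split_dataset <- function(ids, fraction = 0.8, seed = 1L) {
  if (length(ids) < 2) stop("need at least 2 ids to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- length(ids)
  n_train <- round(fraction * n)
  perm <- with_seed(seed, sample.int(n))
  structure(list(train_ids = ids[sort(perm[seq_len(n_train)])],
                 test_ids = ids[sort(perm[-seq_len(n_train)])],
                 fraction = fraction, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$fraction, x$seed))
  invisible(x)
}

# run expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
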