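#' Instance matching configuration
#'
#' @param iou_threshold IoU strictly above this makes a matched pair a true
#'   positive (a pair at exactly the threshold counts as a false positive).
#'   Default 0.5.
#' @param iou_mode `"bbox"` (axis-aligned bounding boxes, the default) or
#'   `"mask"` (rasterized polygon overlap on a shared grid).
#' @return object of class `match_config`.
#' @export
match_config <- function(iou_threshold = 0.5, iou_mode = c("bbox", "mask")) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  structure(list(iou_threshold = iou_threshold,
                 iou_mode = match.arg(iou_mode)),
            class = "match_config")
}

bbox_iou <- function(a, b) {
  ix <- max(0, min(a["xmax"], b["xmax"]) - max(a["xmin"], b["xmin"]))
  iy <- max(0, min(a["ymax"], b["ymax"]) - max(a["ymin"], b["ymin"]))
  inter <- ix * iy
  area_a <- (a["xmax"] - a["xmin"]) * (a["ymax"] - a["ymin"])
  area_b <- (b["xmax"] - b["xmin"]) * (b["ymax"] - b["ymin"])
  un <- area_a + area_b - inter
  if (un <= 0) return(0)                      # degenerate boxes
  unname(inter / un)
}

mask_iou <- function(a, b) {
  xmax <- ceiling(max(a$bbox["xmax"], b$bbox["xmax"])) + 1L
  ymax <- ceiling(max(a$bbox["ymax"], b$bbox["ymax"])) + 1L
  ma <- rasterize_polygon(a$vertices, ymax, xmax)
  mb <- rasterize_polygon(b$vertices, ymax, xmax)
  un <- sum(ma | mb)
  if (un == 0) return(0)
  sum(ma & mb) / un
}

#' Intersection over union of two instances
#'
#' Bounding-box mode uses rectangle intersection/union areas; mask mode
#' rasterizes both polygons on a shared pixel grid and counts pixels.
#' Degenerate (zero-area) geometry gives IoU 0. Symmetric; 1 only for
#' identical geometry.
#'
#' @param a,b [instance_polygon]s in the same pixel frame.
#' @param mode `"bbox"` or `"mask"`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b, mode = c("bbox", "mask")) {
  mode <- match.arg(mode)
  if (mode == "bbox") bbox_iou(a$bbox, b$bbox) else mask_iou(a, b)
}

#' Match predicted instances to ground truth by IoU
#'
#' One-to-one greedy matching, the standard detection-benchmark convention:
#' predictions are visited in order of descending confidence (ties broken by
#' larger best IoU, then input order); each is matched to its highest-IoU
#' not-yet-matched ground truth. A matched pair with IoU strictly above the
#' threshold is a true positive; any other prediction is a false positive
#' (and does not consume the ground truth); unmatched ground truths are
#' false negatives. By construction `TP + FN = #ground truths` and
#' `TP + FP = #predictions`.
#'
#' @param predictions,ground_truths lists of [instance_polygon]s of one
#'   class on one image.
#' @param cfg a [match_config].
#' @return object of class `match_tally` with fields `TP`, `FP`, `FN` and a
#'   data.frame `pairs` (`pred`, `gt`, `iou`) of matched pairs.
#' @export
match_instances <- function(predictions, ground_truths,
                            cfg = match_config()) {
  labs <- unique(c(vapply(predictions, `[[`, "", "label"),
                   vapply(ground_truths, `[[`, "", "label")))
  if (length(labs) > 1)
    stop(sprintf("mixed class labels in matching: %s",
                 paste(labs, collapse = ", ")))
  np <- length(predictions); ng <- length(ground_truths)
  M <- matrix(0, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng))
    M[i, j] <- iou(predictions[[i]], ground_truths[[j]], cfg$iou_mode)
  conf <- vapply(predictions, `[[`, 0, "confidence")
  best <- if (ng) apply(M, 1, max) else rep(0, np)
  ord <- order(-conf, -best, seq_len(np))
  gt_free <- rep(TRUE, ng)
  pairs <- list()
  FP <- 0L
  for (i in ord) {
    j <- if (any(gt_free)) which(gt_free)[which.max(M[i, gt_free])] else 0L
    if (j > 0L && M[i, j] > cfg$iou_threshold) {
      gt_free[j] <- FALSE
      pairs[[length(pairs) + 1L]] <- data.frame(pred = i, gt = j,
                                                iou = M[i, j])
    } else FP <- FP + 1L
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(pred = integer(), gt = integer(), iou = numeric())
  structure(list(TP = nrow(pairs), FP = FP, FN = ng - nrow(pairs),
                 pairs = pairs),
            class = "match_tally")
}

#' @export
print.match_tally <- function(x, ...) {
  cat(sprintf("<match_tally> TP %d, FP %d, FN %d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Combine tallies from several images
#' @param ... `match_tally` objects (or one list of them).
#' @return a pooled `match_tally` (pairs dropped).
#' @export
combine_tallies <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "match_tally")) xs <- xs[[1]]
  structure(list(TP = sum(vapply(xs, `[[`, 0L, "TP")),
                 FP = sum(vapply(xs, `[[`, 0L, "FP")),
                 FN = sum(vapply(xs, `[[`, 0L, "FN")),
                 pairs = NULL),
            class = "match_tally")
}

#' Precision, recall and F1 from a tally
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1` their harmonic
#' mean; 0/0 cases are defined as 0.
#'
#' @param t a `match_tally`, or anything with fields `TP`, `FP`, `FN`.
#' @return object of class `metrics_report` with fields `precision`,
#'   `recall`, `f1`.
#' @export
precision_recall_f1 <- function(t) {
  stopifnot(t$TP >= 0, t$FP >= 0, t$FN >= 0)
  precision <- if (t$TP + t$FP == 0) 0 else t$TP / (t$TP + t$FP)
  recall <- if (t$TP + t$FN == 0) 0 else t$TP / (t$TP + t$FN)
  f1 <- if (precision + recall == 0) 0
  else 2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> precision %.4f, recall %.4f, F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Per-subset metrics table
#'
#' Builds the report table (one row per testing subset with TP, FP, FN,
#' precision, recall and F1), optionally written as CSV/TSV.
#'
#' @param tallies named list of `match_tally` (names = subset labels).
#' @param path optional output path (`.tsv` gets tabs, else commas).
#' @return data.frame with columns `TestingSubset`, `TP`, `FP`, `FN`,
#'   `Precision`, `Recall`, `F1`.
#' @export
metrics_table <- function(tallies, path = NULL) {
  rows <- lapply(names(tallies), function(nm) {
    t <- tallies[[nm]]
    m <- precision_recall_f1(t)
    data.frame(TestingSubset = nm, TP = t$TP, FP = t$FP, FN = t$FN,
               Precision = m$precision, Recall = m$recall, F1 = m$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  out
}
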