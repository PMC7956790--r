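#' Pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic orchard, the four data
#' subsets (resolution in m/pixel), the segmenter, the matcher, the
#' biovolume geometry, the train/test split and the master seed. All
#' randomness flows from the single seed; per-stage seeds are derived from
#' it. In the synthetic pipeline every subset shares the scene's own sun
#' geometry (one simulated flight), so the per-subset theta equals the
#' generator's sun altitude unless overridden.
#'
#' @param orchard an [orchard_params].
#' @param n_patches number of patches (150 in the standard set).
#' @param total_trees exact total tree count, or `NULL`.
#' @param subsets named list: subset label -> list(`pixel_size_m`,
#'   optional `theta_deg`).
#' @param split_fraction train fraction (default 0.8).
#' @param segmenter a [segmenter_config].
#' @param matcher a [match_config].
#' @param biovolume a [biovolume_config] (theta filled per subset).
#' @param out_dir output directory for report files, or `NULL` for none.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(orchard = orchard_params(),
                            n_patches = 150L,
                            total_trees = if (n_patches == 150L) 600L else NULL,
                            subsets = list(
                              `RGB-3` = list(pixel_size_m = 0.03),
                              `RGB-13` = list(pixel_size_m = 0.13),
                              `NDVI-13` = list(pixel_size_m = 0.13),
                              `GNDVI-13` = list(pixel_size_m = 0.13)),
                            split_fraction = 0.8,
                            segmenter = segmenter_config(),
                            matcher = match_config(),
                            biovolume = biovolume_config(),
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(n_patches >= 1, split_fraction > 0, split_fraction < 1)
  for (nm in names(subsets))
    if (is.null(subsets[[nm]]$pixel_size_m))
      stop(sprintf("subset '%s' lacks pixel_size_m", nm))
  structure(list(orchard = orchard, n_patches = as.integer(n_patches),
                 total_trees = total_trees, subsets = subsets,
                 split_fraction = split_fraction, segmenter = segmenter,
                 matcher = matcher, biovolume = biovolume,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config] arguments; `orchard`, `segmenter`,
#' `matcher` and `biovolume` sub-blocks are passed to their constructors.
#'
#' @param path YAML file path.
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$orchard)) args$orchard <- do.call(orchard_params, y$orchard)
  if (!is.null(y$segmenter)) args$segmenter <- do.call(segmenter_config, y$segmenter)
  if (!is.null(y$matcher)) args$matcher <- do.call(match_config, y$matcher)
  if (!is.null(y$biovolume)) args$biovolume <- do.call(biovolume_config, y$biovolume)
  for (nm in c("n_patches", "total_trees", "subsets", "split_fraction",
               "out_dir", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(pipeline_config, args)
}

segment_scene <- function(raster, cfg) {
  list(crowns = segment_crowns(raster, cfg$segmenter),
       shadows = segment_shadows(raster, cfg$segmenter))
}

# match estimated trees to truth trees by trunk-base distance (pixel frame)
match_to_truth <- function(meas, crowns, truth, pixel_size_m) {
  if (!nrow(meas) || !length(truth$trees)) return(cbind(meas[0, ], V_true = numeric()))
  tx <- vapply(truth$trees, function(t) t$trunk_base[1], 0) / pixel_size_m
  ty <- vapply(truth$trees, function(t) t$trunk_base[2], 0) / pixel_size_m
  used <- rep(FALSE, length(truth$trees))
  out <- list()
  for (k in seq_len(nrow(meas))) {
    cc <- polygon_centroid(crowns[[meas$crown[k]]]$vertices)
    d <- sqrt((tx - cc[1])^2 + (ty - cc[2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] * pixel_size_m < truth_spacing_guard(truth)) {
      used[j] <- TRUE
      row <- meas[k, ]
      row$truth_id <- truth$trees[[j]]$id
      row$P_true <- truth$trees[[j]]$P_true
      row$V_true <- truth$trees[[j]]$V_true
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

truth_spacing_guard <- function(truth) 3.0   # half the default 6 m spacing

#' Run the synthetic evaluation pipeline
#'
#' Generates the patch set, splits it train/test, and on the test patches,
#' for every configured subset: degrades resolution, segments crowns and
#' shadows with the reference segmenter, matches against the ground-truth
#' annotations (IoU), derives per-tree measurements and the biovolume
#' accuracy against the generator's truth. Writes, when `out_dir` is set,
#' `metrics_crown.csv`, `metrics_shadow.csv`, `tree_measurements.csv`,
#' `accuracy_summary.csv` and a JSON run `manifest.json`; identical
#' config and seed produce byte-identical outputs.
#'
#' @param cfg a [pipeline_config].
#' @return list of class `pipeline_run`: `metrics` (data.frame per class
#'   and subset), `measurements`, `accuracy` (per subset), `split`,
#'   `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  message(sprintf("generating %d patches (seed %d)", cfg$n_patches, cfg$seed))
  patches <- generate_patch_set(cfg$orchard, cfg$n_patches, cfg$seed,
                                cfg$total_trees)
  ids <- seq_len(cfg$n_patches)
  split <- if (cfg$n_patches >= 2)
    split_dataset(ids, cfg$split_fraction, cfg$seed) else
      list(train_ids = integer(), test_ids = ids)
  test_ids <- split$test_ids
  message(sprintf("evaluating %d test patches on %d subset(s)",
                  length(test_ids), length(cfg$subsets)))

  metrics <- list(); meas_all <- list(); acc <- list()
  for (nm in names(cfg$subsets)) {
    sub <- cfg$subsets[[nm]]
    theta <- sub$theta_deg %||% cfg$orchard$sun_altitude_deg
    tallies <- list(crown = list(), shadow = list())
    rows <- list()
    VG <- numeric(); VM <- numeric()
    for (pid in test_ids) {
      sc <- patches[[pid]]
      r <- if (sub$pixel_size_m > sc$raster$pixel_size_m + 1e-12)
        resample_average(sc$raster, sub$pixel_size_m) else sc$raster
      seg <- segment_scene(r, cfg)
      gt <- truth_to_annotations(sc$truth, r$pixel_size_m,
                                 image_id = sprintf("patch_%03d", pid))
      gt_polys <- gt$images[[1]]
      gt_crowns <- Filter(function(p) p$label == "crown", gt_polys)
      gt_shadows <- Filter(function(p) p$label == "shadow", gt_polys)
      tallies$crown[[length(tallies$crown) + 1L]] <-
        match_instances(seg$crowns, gt_crowns, cfg$matcher)
      tallies$shadow[[length(tallies$shadow) + 1L]] <-
        match_instances(seg$shadows, gt_shadows, cfg$matcher)
      m <- measure_trees(seg$crowns, seg$shadows, theta,
                         cfg$orchard$sun_azimuth_deg, r$pixel_size_m,
                         biovolume_config(cfg$biovolume$trunk_offset_m, theta))
      mt <- match_to_truth(m, seg$crowns, sc$truth, r$pixel_size_m)
      if (!is.null(mt) && nrow(mt)) {
        mt$patch <- pid; mt$subset <- nm
        rows[[length(rows) + 1L]] <- mt
        VG <- c(VG, mt$V_true); VM <- c(VM, mt$V)
      }
    }
    metrics[[nm]] <- list(crown = combine_tallies(tallies$crown),
                          shadow = combine_tallies(tallies$shadow))
    meas_all[[nm]] <- if (length(rows)) do.call(rbind, rows)
    acc[[nm]] <- if (length(VG)) overall_accuracy(VG, VM) else NA_real_
    message(sprintf("  %s: crown TP/FP/FN %d/%d/%d, %d measured trees, accuracy %.2f%%",
                    nm, metrics[[nm]]$crown$TP, metrics[[nm]]$crown$FP,
                    metrics[[nm]]$crown$FN, length(VG), acc[[nm]]))
  }

  crown_tab <- metrics_table(lapply(metrics, `[[`, "crown"))
  shadow_tab <- metrics_table(lapply(metrics, `[[`, "shadow"))
  meas_tab <- do.call(rbind, Filter(Negate(is.null), meas_all))
  acc_tab <- data.frame(subset = names(acc),
                        n_trees = vapply(names(acc), function(nm)
                          if (is.null(meas_all[[nm]])) 0L else nrow(meas_all[[nm]]), 0L),
                        accuracy_pct = unlist(acc), row.names = NULL)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(crown_tab, file.path(cfg$out_dir, "metrics_crown.csv"),
                     row.names = FALSE)
    utils::write.csv(shadow_tab, file.path(cfg$out_dir, "metrics_shadow.csv"),
                     row.names = FALSE)
    if (!is.null(meas_tab))
      utils::write.csv(meas_tab, file.path(cfg$out_dir, "tree_measurements.csv"),
                       row.names = FALSE)
    utils::write.csv(acc_tab, file.path(cfg$out_dir, "accuracy_summary.csv"),
                     row.names = FALSE)
    manifest <- list(seed = cfg$seed, n_patches = cfg$n_patches,
                     subsets = names(cfg$subsets),
                     n_test = length(test_ids),
                     package_version = as.character(utils::packageVersion("olivecanopy")))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(metrics_crown = crown_tab, metrics_shadow = shadow_tab,
                 measurements = meas_tab, accuracy = acc_tab,
                 split = split, config = cfg),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\ncrown metrics:\n")
  print(x$metrics_crown)
  cat("shadow metrics:\n")
  print(x$metrics_shadow)
  cat("biovolume accuracy:\n")
  print(x$accuracy)
  invisible(x)
}

#' Recompute the study's reported tables from their printed inputs
#'
#' From the embedded reference constants: recomputes precision/recall/F1
#' for every reported TP/FP/FN row, every cylinder volume from the printed
#' perimeter and height (ground truth) or perimeter, shadow length and
#' subset solar altitude (model estimates), and the per-subset overall
#' accuracies, each compared with the printed value at its tolerance
#' (one unit in the 4th decimal for metrics, 0.1 m^3 for volumes, 0.05
#' percentage points for accuracies; the RGB-3 accuracy is reported but
#' flagged approximate and excluded from the pass flag).
#'
#' @return list of class `reference_report` with data.frames `metrics`,
#'   `volumes`, `accuracy`, each carrying recomputed and printed values and
#'   a `pass` flag.
#' @export
reproduce_reference_tables <- function() {
  det <- reference_detection_counts()
  m <- lapply(seq_len(nrow(det)), function(i)
    precision_recall_f1(list(TP = det$TP[i], FP = det$FP[i], FN = det$FN[i])))
  det$precision_calc <- vapply(m, `[[`, 0, "precision")
  det$recall_calc <- vapply(m, `[[`, 0, "recall")
  det$f1_calc <- vapply(m, `[[`, 0, "f1")
  tol <- 1e-4 + 1e-9                     # printed values are truncated
  det$pass <- abs(round(det$precision_calc, 4) - det$precision) <= tol &
    abs(round(det$recall_calc, 4) - det$recall) <= tol &
    abs(round(det$f1_calc, 4) - det$f1) <= tol

  tr <- reference_tree_measurements()
  theta <- ifelse(grepl("^RGB", tr$subset), theta_for_subset("RGB"),
                  theta_for_subset("NDVI"))
  h_eff <- ifelse(is.na(tr$L), tr$h, tree_height(ifelse(is.na(tr$L), 0, tr$L), theta))
  S <- crown_surface(tr$P)
  tr$V_calc <- suppressWarnings(biovolume(S, h_eff))
  tr$pass <- abs(tr$V_calc - tr$V) <= 0.1

  gt <- tr[tr$subset == "ground_truth", ]
  accs <- reference_accuracies()
  accs$accuracy_calc <- vapply(accs$subset, function(s)
    overall_accuracy(gt$V, tr$V[tr$subset == s]), 0)
  accs$pass <- ifelse(accs$exact, abs(accs$accuracy_calc - accs$accuracy) <= 0.05, NA)

  structure(list(metrics = det, volumes = tr, accuracy = accs),
            class = "reference_report")
}

#' @export
print.reference_report <- function(x, ...) {
  cat(sprintf("<reference_report> metrics rows: %d/%d pass; volumes: %d/%d pass\n",
              sum(x$metrics$pass), nrow(x$metrics),
              sum(x$volumes$pass), nrow(x$volumes)))
  cat("accuracies:\n")
  print(x$accuracy)
  invisible(x)
}
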