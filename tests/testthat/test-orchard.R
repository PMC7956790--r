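test_that("scene truth obeys the shadow and volume identities", {
  p <- orchard_params(n_trees = 5, seed = 21)
  sc <- generate_scene(p)
  tan_alt <- tan(p$sun_altitude_deg * pi / 180)
  for (t in sc$truth$trees) {
    expect_equal(t$L_true, t$H_true / tan_alt, tolerance = 1e-12)
    expect_equal(t$V_true,
                 t$P_true^2 / (4 * pi) * (t$H_true - p$trunk_offset_m),
                 tolerance = 1e-12)
    expect_equal(t$P_true, 2 * pi * t$radius, tolerance = 1e-12)
  }
})

test_that("degenerate and boundary scenes behave as specified", {
  # no trees: pure soil statistics, empty truth
  p0 <- orchard_params(n_trees = 0, extent_m = 3, seed = 1)
  p0$reflectance$noise_sd <- 0
  sc0 <- generate_scene(p0)
  expect_length(sc0$truth$trees, 0L)
  expect_true(all(sc0$raster$bands$red == p0$reflectance$soil["red"]))
  # one tree with crown radius 1 m has P_true = 2 pi
  p1 <- orchard_params(n_trees = 1, crown_radius_range_m = c(1, 1), seed = 1)
  expect_equal(generate_scene(p1)$truth$trees[[1]]$P_true, 2 * pi)
  # L_true inverts the height relation: H = 2.5, theta = 29.61 -> L ~ 4.40
  p2 <- orchard_params(n_trees = 1, tree_height_range_m = c(2.5, 2.5),
                       sun_altitude_deg = 29.61, seed = 1)
  expect_equal(generate_scene(p2)$truth$trees[[1]]$L_true,
               2.5 / tan(29.61 * pi / 180), tolerance = 1e-12)
  expect_equal(round(generate_scene(p2)$truth$trees[[1]]$L_true, 2), 4.40)
  # too-small extent errors naming the constraint
  expect_error(generate_scene(orchard_params(n_trees = 4, extent_m = 2)),
               "too small")
  expect_error(orchard_params(spacing_m = 3, crown_radius_range_m = c(1, 1.6)),
               "spacing")
})

test_that("generation is bit-identical under a fixed seed", {
  p <- orchard_params(n_trees = 3, seed = 123)
  a <- generate_scene(p); b <- generate_scene(p)
  expect_identical(a$raster$bands, b$raster$bands)
  expect_identical(truth_table(a$truth), truth_table(b$truth))
  s1 <- generate_patch_set(orchard_params(), 3, seed = 9)
  s2 <- generate_patch_set(orchard_params(), 3, seed = 9)
  expect_identical(truth_table(lapply(s1, `[[`, "truth")),
                   truth_table(lapply(s2, `[[`, "truth")))
})

test_that("truth polygons rasterize to the analytic disc area and aligned shadows", {
  p <- orchard_params(n_trees = 3, seed = 6)
  p$reflectance$noise_sd <- 0
  sc <- generate_scene(p)
  d <- dim(sc$raster)
  u <- olivecanopy:::shadow_direction(p$sun_azimuth_deg)
  for (t in sc$truth$trees) {
    ip <- instance_polygon(t$crown_xy / p$pixel_size_m, "crown")
    area_px <- sum(rasterize_polygon(ip$vertices, d[1], d[2]))
    expect_equal(area_px, pi * (t$radius / p$pixel_size_m)^2,
                 tolerance = 5e-3)        # relative; rasterization granularity
    cen <- olivecanopy:::polygon_centroid(t$shadow_xy)
    dv <- cen - t$trunk_base
    offset_px <- abs(dv[1] * u[2] - dv[2] * u[1]) / p$pixel_size_m
    expect_lt(offset_px, 1)
    # centroid lies down-shadow, not up-sun
    expect_gt(sum(dv * u), 0)
  }
})

test_that("truth converts to pixel annotations with one polygon per class per tree", {
  sc <- generate_scene(orchard_params(n_trees = 3, seed = 8))
  a <- truth_to_annotations(sc$truth)
  labs <- vapply(a$images[[1]], `[[`, "", "label")
  expect_equal(sum(labs == "crown"), 3L)
  expect_equal(sum(labs == "shadow"), 3L)
  # vertices scale by 1 / pixel size
  sq <- structure(list(trees = list(list(id = 1,
    crown_xy = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)) ,
    shadow_xy = cbind(c(2, 3, 3, 2), c(0, 0, 1, 1)))),
    pixel_size_m = 0.1), class = "scene_truth")
  a2 <- truth_to_annotations(sq, 0.1)
  expect_equal(max(a2$images[[1]][[1]]$vertices), 10)
  expect_length(truth_to_annotations(
    structure(list(trees = list(), pixel_size_m = 1), class = "scene_truth")
  )$images[[1]], 0L)
})

test_that("patch sets draw counts in range and can hit an exact total", {
  set <- generate_patch_set(orchard_params(), 4, seed = 2)
  expect_length(set, 4L)
  counts <- vapply(set, function(s) length(s$truth$trees), 0L)
  expect_true(all(counts >= 1 & counts <= 8))
  truths <- default_patch_set(seed = 5, truth_only = TRUE)
  n <- vapply(truths, function(t) length(t$trees), 0L)
  expect_length(n, 150L)
  expect_equal(sum(n), 600L)
  expect_true(all(n >= 1 & n <= 8))
})
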