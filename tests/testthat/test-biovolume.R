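test_that("perimeter, surface, height and volume follow the cylinder model", {
  sq <- instance_polygon(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)), "crown")
  expect_equal(crown_perimeter(sq, 1), 16)
  ngon <- instance_polygon(cbind(cos(seq(0, 2 * pi, length.out = 361)[-361]),
                                 sin(seq(0, 2 * pi, length.out = 361)[-361])),
                           "crown")
  expect_equal(crown_perimeter(ngon, 1, simplify_tol_px = 0), 2 * pi,
               tolerance = 1e-4)
  expect_equal(crown_surface(2 * pi), pi)
  expect_equal(crown_surface(6.3), 6.3^2 / (4 * pi))
  expect_error(crown_surface(0), "positive")
  expect_equal(tree_height(3.6, 26.22), 3.6 * tan(26.22 * pi / 180))
  expect_equal(round(tree_height(3.6, 26.22), 1), 1.8)
  expect_equal(round(tree_height(4.3, 29.61), 2), 2.44)
  expect_equal(tree_height(0, 45), 0)
  expect_error(tree_height(1, 95), "between 0 and 90")
  expect_equal(biovolume(3, 0.5), 0) |> suppressWarnings()
  expect_warning(biovolume(3, 0.4), "clamped")
  cfg <- biovolume_config(theta_deg = 29.61)
  S <- crown_surface(10)
  h <- tree_height(5.8, 29.61)
  expect_equal(biovolume(S, h, cfg), 22.25, tolerance = 0.01)
})

test_that("volume scales as the square of perimeter and height round-trips", {
  P <- runif(20, 5, 12); h <- runif(20, 1, 4)
  expect_equal(suppressWarnings(biovolume(crown_surface(2 * P), h)),
               4 * suppressWarnings(biovolume(crown_surface(P), h)))
  # monotone in P and in h
  expect_true(all(diff(suppressWarnings(
    biovolume(crown_surface(sort(P)), 3))) > 0))
  expect_true(all(diff(suppressWarnings(
    biovolume(crown_surface(8), sort(h)))) > 0))
  # L -> h -> L round trip at machine precision
  theta <- 29.61
  L <- h / tan(theta * pi / 180)
  expect_equal(tree_height(L, theta), h, tolerance = 1e-14)
})

test_that("shadow length is the axis projection from the crown edge", {
  # crown disc (radius 10 px) and a stadium shadow of tip distance 45 px
  phi <- seq(0, 2 * pi, length.out = 73)[-73]
  crown <- instance_polygon(cbind(50 + 10 * cos(phi), 50 + 10 * sin(phi)),
                            "crown")
  az <- 135                                # shadow towards the north-west
  u <- olivecanopy:::shadow_direction(az)
  w <- c(-u[2], u[1])
  base <- c(50, 50)
  ts <- rbind(cbind(10 * cos(seq(pi / 2, -pi / 2, length.out = 19)),
                    10 * sin(seq(pi / 2, -pi / 2, length.out = 19))),
              cbind(35 + 10 * cos(seq(-pi / 2, pi / 2, length.out = 19)),
                    10 * sin(seq(-pi / 2, pi / 2, length.out = 19))))
  shadow <- instance_polygon(
    cbind(base[1] + ts[, 1] * u[1] + ts[, 2] * w[1],
          base[2] + ts[, 1] * u[2] + ts[, 2] * w[2]), "shadow")
  expect_equal(shadow_length(crown, shadow, az, 0.1), 4.5, tolerance = 0.01)
  # shadow placed up-sun errors
  bad <- instance_polygon(
    cbind(base[1] - (12 + ts[, 1]) * u[1] + ts[, 2] * w[1],
          base[2] - (12 + ts[, 1]) * u[2] + ts[, 2] * w[2]), "shadow")
  expect_error(shadow_length(crown, bad, az, 0.1), "behind")
  # azimuth rotated 90 degrees triggers the sanity warning
  expect_warning(shadow_length(crown, shadow, az + 90, 0.1), "azimuth")
})

test_that("crowns pair with down-shadow shadows and leave strays unpaired", {
  phi <- seq(0, 2 * pi, length.out = 25)[-25]
  disc <- function(cx, cy, r, lab) instance_polygon(
    cbind(cx + r * cos(phi), cy + r * sin(phi)), lab)
  az <- 135                                 # shadows towards (-x, -y)
  crown <- disc(50, 50, 10, "crown")
  good <- disc(30, 30, 8, "shadow")
  pr <- pair_crowns_shadows(list(crown), list(good), az)
  expect_equal(nrow(pr$pairs), 1L)
  up_sun <- disc(70, 70, 8, "shadow")
  pr2 <- pair_crowns_shadows(list(crown), list(up_sun), az)
  expect_equal(nrow(pr2$pairs), 0L)
  expect_equal(pr2$unpaired_crowns, 1L)
  expect_equal(pr2$unpaired_shadows, 1L)
  # generator scenes pair one-to-one
  p <- orchard_params(n_trees = 4, seed = 17)
  p$reflectance$noise_sd <- 0
  sc <- generate_scene(p)
  pr3 <- pair_crowns_shadows(segment_crowns(sc$raster),
                             segment_shadows(sc$raster), p$sun_azimuth_deg)
  expect_equal(nrow(pr3$pairs), 4L)
})

test_that("overall accuracy is the mean relative volume error statistic", {
  expect_equal(overall_accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(overall_accuracy(10, 5), 50)
  expect_equal(overall_accuracy(c(10, 10), c(5, 20)), 25)
  expect_error(overall_accuracy(c(1, 2), 1), "equal")
  expect_error(overall_accuracy(c(0, 1), c(1, 1)), "positive")
  tr <- reference_tree_measurements()
  VG <- tr$V[tr$subset == "ground_truth"]
  expect_equal(overall_accuracy(VG, tr$V[tr$subset == "NDVI-13"]), 82.58,
               tolerance = 0.01)
})
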