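via_doc <- function(regions_json) sprintf(
  '{"img.png12345":{"filename":"img.png","size":12345,"regions":%s,"file_attributes":{}}}',
  regions_json)

square_region <- function(cls = "crown") sprintf(
  '{"shape_attributes":{"name":"polygon","all_points_x":[0,10,10,0],"all_points_y":[0,0,10,10]},"region_attributes":{"class":"%s"}}',
  cls)

test_that("VIA 1.x documents parse in both regions dialects", {
  for (regions in c(sprintf('{"0":%s}', square_region()),
                    sprintf("[%s]", square_region()))) {
    a <- read_via_json(via_doc(regions))
    expect_length(a, 1L)
    p <- a$images[[1]][[1]]
    expect_s3_class(p, "instance_polygon")
    expect_equal(p$label, "crown")
    expect_equal(nrow(p$vertices), 4L)
    expect_equal(polygon_area(p), 100)
  }
  expect_length(read_via_json(via_doc("{}"))$images[[1]], 0L)
})

test_that("class synonyms, bad regions and self-intersections are handled", {
  a <- read_via_json(via_doc(sprintf('{"0":%s,"1":%s}',
                                     square_region("Olive Tree"),
                                     square_region("Shadow"))))
  labs <- vapply(a$images[[1]], `[[`, "", "label")
  expect_equal(labs, c("crown", "shadow"))
  # a two-point ring is rejected with a warning, not an error
  bad <- '{"0":{"shape_attributes":{"name":"polygon","all_points_x":[0,1],"all_points_y":[0,1]},"region_attributes":{"class":"crown"}}}'
  expect_warning(a2 <- read_via_json(via_doc(bad)), "<3 points")
  expect_length(a2$images[[1]], 0L)
  # non-polygon shapes are skipped
  rect <- '{"0":{"shape_attributes":{"name":"rect","x":0,"y":0,"width":5,"height":5},"region_attributes":{"class":"crown"}}}'
  expect_warning(a3 <- read_via_json(via_doc(rect)), "non-polygon")
  expect_length(a3$images[[1]], 0L)
  # self-crossing ring (non-zero area) is rejected
  bow <- '{"0":{"shape_attributes":{"name":"polygon","all_points_x":[0,4,3,1],"all_points_y":[0,0,3,-1]},"region_attributes":{"class":"crown"}}}'
  expect_warning(a4 <- read_via_json(via_doc(bow)), "self-intersecting")
  expect_length(a4$images[[1]], 0L)
})

test_that("write_via_json is the inverse of read_via_json", {
  sc <- generate_scene(orchard_params(n_trees = 3, seed = 2))
  a <- truth_to_annotations(sc$truth)
  b <- read_via_json(write_via_json(a))
  expect_equal(names(b$images), names(a$images))
  expect_length(b$images[[1]], 6L)
  for (i in seq_along(a$images[[1]])) {
    expect_equal(unname(b$images[[1]][[i]]$vertices),
                 unname(a$images[[1]][[i]]$vertices))
    expect_equal(b$images[[1]][[i]]$label, a$images[[1]][[i]]$label)
  }
  # empty set still produces a valid document
  expect_length(read_via_json(write_via_json(annotation_set()))$images, 0L)
})

test_that("stored polygons carry positive shoelace area after canonicalization", {
  cw <- instance_polygon(cbind(c(0, 0, 5, 5), c(0, 5, 5, 0)), "crown")
  expect_gt(olivecanopy:::shoelace_area(cw$vertices), 0)
  sc <- generate_scene(orchard_params(n_trees = 2, seed = 9))
  for (p in truth_to_annotations(sc$truth)$images[[1]])
    expect_gt(olivecanopy:::shoelace_area(p$vertices), 0)
})

test_that("dataset split is a deterministic partition with round(fraction*n) train ids", {
  s <- split_dataset(1:150, 0.8, 42)
  expect_length(s$train_ids, 120L)
  expect_length(s$test_ids, 30L)
  expect_setequal(c(s$train_ids, s$test_ids), 1:150)
  expect_length(intersect(s$train_ids, s$test_ids), 0L)
  expect_identical(s$train_ids, split_dataset(1:150, 0.8, 42)$train_ids)
  expect_equal(length(split_dataset(1:2, 0.5, 1)$train_ids), 1L)
  expect_error(split_dataset(1, 0.5), "at least 2")
  expect_error(split_dataset(1:10, 1.2), "fraction")
  # partition property over random sizes and fractions
  set.seed(77)
  for (k in 1:25) {
    n <- sample(2:400, 1)
    f <- runif(1, 0.05, 0.95)
    s <- split_dataset(seq_len(n), f, k)
    expect_length(s$train_ids, round(f * n))
    expect_setequal(c(s$train_ids, s$test_ids), seq_len(n))
  }
})

test_that("annotations flatten to one WKT row per polygon", {
  sc <- generate_scene(orchard_params(n_trees = 2, seed = 4))
  df <- annotations_to_csv(truth_to_annotations(sc$truth))
  expect_equal(nrow(df), 4L)
  expect_true(all(grepl("^POLYGON", df$wkt)))
  expect_equal(sum(df$label == "crown"), 2L)
})
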