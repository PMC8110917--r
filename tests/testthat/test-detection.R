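test_that("oracle_detect without noise reproduces the training regions", {
  set.seed(41)
  truth <- annotation_set("img", list(random_polyline(4, "vessel"),
                                      random_polyline(3, "vessel"),
                                      random_polyline(3, "debris")))
  dets <- oracle_detect(truth, box_size = 16, stride = 8, seed = 9)
  expected <- do.call(rbind, lapply(
    Filter(function(p) p$label == "vessel", truth$polylines),
    function(p) boxes_from_polyline(p, 16, 8, image_id = "img")$boxes))
  expect_equal(dets$boxes, expected)
})

test_that("oracle_detect is deterministic given the seed", {
  set.seed(42)
  truth <- annotation_set("img", list(random_polyline(6, "vessel")))
  a <- oracle_detect(truth, 16, 8, jitter_sd = 2, miss_rate = 0.3,
                     false_positive_count = 5, field_px = c(100, 100), seed = 7)
  b <- oracle_detect(truth, 16, 8, jitter_sd = 2, miss_rate = 0.3,
                     false_positive_count = 5, field_px = c(100, 100), seed = 7)
  expect_identical(a, b)
  c <- oracle_detect(truth, 16, 8, jitter_sd = 2, miss_rate = 0.3,
                     false_positive_count = 5, field_px = c(100, 100), seed = 8)
  expect_false(identical(a$boxes, c$boxes))
})

test_that("oracle_detect drop-out follows the binomial retention rate", {
  # one long vessel -> ~500 boxes; over 50 seeds mean retention ~ 0.8
  truth <- annotation_set("img", list(straight_polyline(4000, x0 = 0)))
  n0 <- nrow(oracle_detect(truth, 16, 8, seed = 1)$boxes)
  expect_gt(n0, 400)
  kept <- vapply(1:50, function(s)
    nrow(oracle_detect(truth, 16, 8, miss_rate = 0.2, seed = s)$boxes),
    numeric(1))
  p_hat <- mean(kept) / n0
  se <- sqrt(0.2 * 0.8 / (n0 * 50))
  expect_lt(abs(p_hat - 0.8), 3 * se + 1e-6)
})

test_that("classical_detect finds boxes on bars and respects size filters", {
  blank <- image2d(matrix(0, 50, 50), 1, id = "blank")
  expect_message(empty <- classical_detect(blank), "empty foreground")
  expect_equal(nrow(empty$boxes), 0)

  img <- bar_image()
  ds <- classical_detect(img, threshold_quantile = 0.8,
                         min_component_px = 20, max_component_px = 5000,
                         box_size = 16, stride = 8)
  expect_gt(nrow(ds$boxes), 5)
  # all centers inside the bar's bounding box
  expect_true(all(ds$boxes$cx >= 9 & ds$boxes$cx <= 110))
  expect_true(all(ds$boxes$cy >= 26 & ds$boxes$cy <= 32))
  expect_true(all(ds$boxes$confidence >= 0 & ds$boxes$confidence <= 1))

  # a 5-px speck below min_component_px contributes no boxes
  px <- img$pixels
  px[5, 5:9] <- 1
  img2 <- image2d(px, 1, id = "bar")
  ds2 <- classical_detect(img2, threshold_quantile = 0.8,
                          min_component_px = 20, max_component_px = 5000,
                          box_size = 16, stride = 8)
  expect_true(all(ds2$boxes$cy > 20))
})

test_that("pixel_based_length measures a bar and ignores filtered specks", {
  expect_equal(pixel_based_length(image2d(matrix(0, 40, 40), 1)), 0)

  img <- bar_image()  # hard-edged bar, axis length 100 px
  len <- pixel_based_length(img, 0.9, min_object_px = 10)
  expect_gt(len, 90)
  expect_lt(len, 105)

  # 4-px speck with min_object_px = 10: unchanged length
  px <- img$pixels
  px[5, 5:8] <- 1
  len2 <- pixel_based_length(image2d(px, 1, id = "bar"), 0.9,
                             min_object_px = 10)
  expect_equal(len2, len)
})

test_that("detect dispatches backends and enforces the box contract", {
  img <- bar_image()
  direct <- classical_detect(img, 0.8, 20, 5000, 16, 8)
  via <- detect(img, "classical", threshold_quantile = 0.8,
                min_component_px = 20, max_component_px = 5000,
                box_size = 16, stride = 8)
  expect_equal(via$boxes, direct$boxes)

  bad_backend <- function(image, ...) {
    out <- detection_set(image$id, data.frame(
      cx = 1, cy = 1, w = 1, h = 1, confidence = 1, label = "vessel"))
    out$boxes$w <- 0  # mutate behind the constructor's back
    out
  }
  expect_error(detect(img, bad_backend), "non-positive extent")

  overconfident <- function(image, ...) {
    out <- detection_set(image$id, data.frame(
      cx = 1, cy = 1, w = 2, h = 2, confidence = 1, label = "vessel"))
    out$boxes$confidence <- 1.5
    out
  }
  expect_error(detect(img, overconfident), "confidence outside")

  wrong_image <- function(image, ...) detection_set("other")
  expect_error(detect(img, wrong_image), "was given image")
})

test_that("detections round-trip through JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  ds <- detection_set("img", data.frame(
    cx = c(1.25, 30.5), cy = c(2.5, 40.125), w = 16, h = 16,
    confidence = c(0.9, 0.4), label = c("vessel", "debris"),
    stringsAsFactors = FALSE))
  write_detections(ds, tmp)
  back <- read_detections(tmp)
  expect_equal(back$image_id, "img")
  expect_equal(back$boxes, ds$boxes)

  write_detections(detection_set("none"), tmp)
  expect_equal(nrow(read_detections(tmp)$boxes), 0)
})
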