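test_that("descriptors are min-max normalized with the degenerate convention", {
  m <- matrix(100, 9, 9)
  expect_equal(extract_descriptor(m, c(5, 5), 3), rep(0, 9))
  m2 <- matrix(0, 9, 9); m2[5, 5] <- 10
  d <- extract_descriptor(m2, c(5, 5), 3)
  expect_equal(matrix(d, 3, 3)[2, 2], 1)
  expect_equal(sum(d), 1)
  # positive affine invariance
  set.seed(1)
  m3 <- matrix(runif(81, 10, 50), 9, 9)
  expect_equal(extract_descriptor(m3, c(5, 5), 5),
               extract_descriptor(2.7 * m3 + 13, c(5, 5), 5),
               tolerance = 1e-12)
  expect_error(extract_descriptor(m3, c(1, 5), 5), "border")
  expect_error(extract_descriptor(m3, c(5, 5), 4), "odd")
})

test_that("leave-one-out accuracy is perfect on a well-separated fixture", {
  tr <- cached_training_set()
  xs <- tr$spots[1:20, , drop = FALSE]
  xb <- tr$background[1:20, , drop = FALSE]
  x <- rbind(xs, xb)
  y <- rep(c(1, 0), each = 20)
  hits <- vapply(seq_len(40), function(i) {
    det <- train_detector(x[-i, , drop = FALSE][y[-i] == 1, , drop = FALSE],
                          x[-i, , drop = FALSE][y[-i] == 0, , drop = FALSE])
    p <- predict(det, x[i, ])$posterior_spot
    (p >= 0.5) == (y[i] == 1)
  }, logical(1))
  expect_identical(mean(hits), 1)
})

test_that("posteriors are symmetric under label swap and sum to one", {
  tr <- cached_training_set()
  xs <- tr$spots[1:20, ]; xb <- tr$background[1:20, ]
  d1 <- train_detector(xs, xb)
  d2 <- train_detector(xb, xs)
  probe <- rbind(xs[1:5, ], xb[1:5, ])
  p1 <- predict(d1, probe)
  p2 <- predict(d2, probe)
  expect_equal(p1$posterior_spot + p1$posterior_background, rep(1, 10))
  expect_equal(p1$posterior_spot, p2$posterior_background, tolerance = 1e-9)
})

test_that("singular covariance without ridge raises an actionable error", {
  xs <- matrix(rep(c(0, 1), each = 3), 3, 4)
  xb <- matrix(rep(c(1, 0), each = 3), 3, 4) + 0.1
  expect_error(train_detector(xs, xb, regularization = 0), "regularization")
})

test_that("scanning a blank noise image yields no detections", {
  det <- cached_detector()
  f <- render_field(field_spec(c(128, 128), background_level = 45, seed = 7))
  map <- scan_image(f$image, det)
  expect_identical(nrow(detect_events(map, det$threshold)), 0L)
})

test_that("a bright spot is localized within one pixel", {
  det <- cached_detector()
  f <- spot_field(1, image_size = c(64, 64), snr = 100, seed = 33)
  map <- scan_image(f$image, det)
  ev <- detect_events(map, det$threshold)
  expect_identical(nrow(ev), 1L)
  expect_lt(sqrt((ev$row - f$truth$row)^2 + (ev$col - f$truth$col)^2), 1)
})

test_that("a constant image scores identically at every defined position", {
  det <- cached_detector()
  map <- scan_image(matrix(50, 40, 40), det)
  v <- map$values[!is.na(map$values)]
  expect_equal(diff(range(v)), 0)
})

test_that("thresholding and connectivity produce the expected events", {
  vals <- matrix(NA_real_, 20, 20)
  vals[3:18, 3:18] <- 0
  map <- structure(list(values = vals, valid_margin = 2L),
                   class = "probability_map")
  expect_identical(nrow(detect_events(map, 0.5, pad = 0)), 0L)
  # two blobs separated by > 1 background pixel, one diagonal-connected
  vals[4:5, 4:5] <- 0.9
  vals[6, 6] <- 0.9          # touches (5,5) diagonally -> same event
  vals[12:13, 12] <- 0.95
  map$values <- vals
  ev <- detect_events(map, 0.5, pad = 0)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$n_pixels, c(5L, 2L))
})

test_that("ten well-separated spots are each recovered within one pixel", {
  det <- cached_detector()
  f <- spot_field(10, image_size = c(128, 128), snr = 20,
                  min_separation_px = 18, seed = 11)
  ev <- detect_events(scan_image(f$image, det), det$threshold)
  expect_identical(nrow(ev), 10L)
  d <- sqrt(outer(ev$row, f$truth$row, `-`)^2 +
              outer(ev$col, f$truth$col, `-`)^2)
  expect_true(all(apply(d, 2, min) < 1))
})

test_that("detection output is invariant to positive affine intensity maps", {
  det <- cached_detector()
  f <- spot_field(6, image_size = c(96, 96), snr = 25, seed = 13)
  ev1 <- detect_events(scan_image(f$image$pixels, det), det$threshold)
  ev2 <- detect_events(scan_image(2.5 * f$image$pixels + 7, det),
                       det$threshold)
  expect_equal(ev1, ev2, tolerance = 1e-9)
})

test_that("threshold calibration minimizes false positives at the TPR target", {
  # 1-d score-like descriptors with a clean gap
  pos <- matrix(seq(0.51, 0.99, length.out = 100), ncol = 1)
  neg <- matrix(seq(0.01, 0.49, length.out = 100), ncol = 1)
  cal <- calibrate_threshold(pos, neg, folds = 5)
  expect_true(cal$achieved)
  expect_identical(cal$cv_fpr, 0)
  expect_gte(cal$cv_tpr, 0.99)
  # relaxing the TPR constraint can only raise the returned cut
  cal95 <- calibrate_threshold(pos, neg, folds = 5, target_tpr = 0.95)
  expect_gte(cal95$threshold, cal$threshold)
})

test_that("detector models survive a JSON round trip", {
  det <- cached_detector()
  path <- withr::local_tempfile(fileext = ".json")
  write_detector_json(det, path)
  back <- read_detector_json(path)
  probe <- cached_training_set()$spots[1:4, ]
  expect_equal(predict(back, probe), predict(det, probe), tolerance = 1e-12)
  expect_identical(back$window_size, det$window_size)
  expect_equal(back$threshold, det$threshold)
})

test_that("posteriors agree with an independent LDA implementation", {
  # low-dimensional, well-conditioned problem where the ridge is negligible
  set.seed(9)
  xs <- matrix(rnorm(200, mean = 0.6, sd = 0.1), 50, 4)
  xb <- matrix(rnorm(200, mean = 0.4, sd = 0.1), 50, 4)
  det <- train_detector(xs, xb, regularization = 1e-12)
  ref <- MASS::lda(rbind(xs, xb), grouping = rep(c("spot", "bg"), each = 50))
  probe <- rbind(xs[1:10, ], xb[1:10, ])
  p_ref <- predict(ref, probe)$posterior[, "spot"]
  expect_equal(unname(predict(det, probe)$posterior_spot), unname(p_ref),
               tolerance = 1e-6)
})
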