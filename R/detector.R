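#' Extract a min-max normalized window descriptor
#'
#' The descriptor is the `w x w` window centred at `center`, min-max
#' normalized to `[0, 1]` and flattened column-major. Normalization makes the
#' descriptor invariant to positive affine rescaling of the intensities, so
#' bright and dim cells produce similar descriptors. Constant windows (zero
#' range) map to the all-zeros descriptor.
#'
#' @param image A [raster_image()] or numeric matrix.
#' @param center Integer `(row, col)` of the window centre.
#' @param w Odd window size in pixels (default 15, wide enough for a 7.5 um
#'   spot plus margin at 3 um/px).
#' @return Numeric vector of length `w^2` in `[0, 1]`.
#' @export
extract_descriptor <- function(image, center, w = 15L) {
  px <- if (inherits(image, "raster_image")) image$pixels else image
  if (w %% 2 != 1) abort("window size `w` must be odd")
  h <- (w - 1L) %/% 2L
  r <- center[1]; c <- center[2]
  if (r - h < 1 || r + h > nrow(px) || c - h < 1 || c + h > ncol(px)) {
    abort("window crosses the image border")
  }
  win <- px[(r - h):(r + h), (c - h):(c + h)]
  rng <- max(win) - min(win)
  if (rng == 0) return(rep(0, w * w))
  as.vector((win - min(win)) / rng)
}

#' Train the two-class linear discriminant spot detector
#'
#' Fits Gaussian class-conditionals with a shared (pooled within-class)
#' covariance to normalized window descriptors of the spot and background
#' classes. The pooled covariance is ridge-regularized
#' (`cov + regularization * I`); with the default `regularization = NULL` the
#' ridge is `0.1 * trace(cov) / dim`: strong shrinkage, chosen because the
#' 225-dimensional covariance estimated from a few hundred labeled patches is
#' otherwise so ill-conditioned that unseen noise patches receive divergent
#' scores (weaker ridges produce dozens of false events on blank fields).
#'
#' @param spot_patches,background_patches Matrices with one descriptor per
#'   row (see [extract_descriptor()]), or lists of descriptor vectors.
#' @param regularization Ridge added to the pooled covariance diagonal;
#'   `NULL` for the scaled default.
#' @param priors Optional class priors `(spot, background)`; defaults to the
#'   class frequencies.
#' @return An `lda_detector` object with fields `mean_spot`,
#'   `mean_background`, `pooled_covariance`, `class_priors`, `window_size`,
#'   and `threshold` (`NA` until [calibrate_threshold()] is run).
#' @export
train_detector <- function(spot_patches, background_patches,
                           regularization = NULL, priors = NULL) {
  as_mat <- function(x) if (is.list(x)) do.call(rbind, x) else x
  xs <- as_mat(spot_patches)
  xb <- as_mat(background_patches)
  if (nrow(xs) < 2 || nrow(xb) < 2) abort("need >= 2 patches per class")
  if (ncol(xs) != ncol(xb)) abort("classes have different descriptor sizes")
  d <- ncol(xs)
  w <- as.integer(round(sqrt(d)))
  if (w * w != d) abort("descriptor length is not a perfect square")
  mu_s <- colMeans(xs)
  mu_b <- colMeans(xb)
  cs <- crossprod(sweep(xs, 2, mu_s))
  cb <- crossprod(sweep(xb, 2, mu_b))
  pooled <- (cs + cb) / (nrow(xs) + nrow(xb) - 2)
  reg <- regularization %||% (0.1 * sum(diag(pooled)) / d)
  pooled_r <- pooled + diag(reg, d)
  ch <- tryCatch(chol(pooled_r), error = function(e) NULL)
  if (is.null(ch)) {
    abort("pooled covariance is singular; increase `regularization`")
  }
  if (is.null(priors)) {
    priors <- c(nrow(xs), nrow(xb)) / (nrow(xs) + nrow(xb))
  }
  delta <- mu_s - mu_b
  wvec <- backsolve(ch, backsolve(ch, delta, transpose = TRUE))
  bias <- -0.5 * sum((mu_s + mu_b) * wvec) + log(priors[1] / priors[2])
  structure(
    list(mean_spot = mu_s, mean_background = mu_b,
         pooled_covariance = pooled_r, class_priors = priors,
         window_size = w, threshold = NA_real_,
         regularization = reg, weights = wvec, bias = bias),
    class = "lda_detector"
  )
}

#' @export
print.lda_detector <- function(x, ...) {
  cat(sprintf(
    "<lda_detector> window %dx%d, priors (spot %.3f, bg %.3f), threshold %s\n",
    x$window_size, x$window_size, x$class_priors[1], x$class_priors[2],
    if (is.na(x$threshold)) "uncalibrated" else format(x$threshold)))
  invisible(x)
}

#' Spot-class posterior probabilities for descriptors
#'
#' With the shared covariance the log posterior odds are linear in the
#' descriptor, so the spot posterior is a logistic function of the linear
#' discriminant score; the two class posteriors sum to one by construction.
#'
#' @param object An [train_detector()] model.
#' @param descriptors Matrix with one descriptor per row (or a single vector).
#' @param ... Unused.
#' @return A tibble with columns `posterior_spot`, `posterior_background`.
#' @export
predict.lda_detector <- function(object, descriptors, ...) {
  if (is.null(dim(descriptors))) descriptors <- rbind(descriptors)
  p <- stats::plogis(drop(descriptors %*% object$weights) + object$bias)
  tibble::tibble(posterior_spot = p, posterior_background = 1 - p)
}

# local min / max over w x w windows, separable running passes
local_extrema <- function(px, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  vc <- nc - 2L * h
  rmin <- px[, 1:vc]; rmax <- rmin
  for (b in 2:w) {
    sl <- px[, b:(b + vc - 1L)]
    rmin <- pmin(rmin, sl); rmax <- pmax(rmax, sl)
  }
  vr <- nr - 2L * h
  mn <- rmin[1:vr, , drop = FALSE]; mx <- rmax[1:vr, , drop = FALSE]
  for (a in 2:w) {
    mn <- pmin(mn, rmin[a:(a + vr - 1L), , drop = FALSE])
    mx <- pmax(mx, rmax[a:(a + vr - 1L), , drop = FALSE])
  }
  list(min = mn, max = mx)
}

#' Scan an image with the detector at stride 1
#'
#' Scores every window whose centre keeps the window fully inside the image
#' (a margin of `(w - 1) / 2` pixels is left unscored; no padding is
#' fabricated) and returns the spot-class posterior per window centre. The
#' per-window min-max normalization folds into the linear score, so the scan
#' reduces to one correlation with the discriminant weights plus running
#' window minima / maxima.
#'
#' @param image A [raster_image()] or numeric matrix.
#' @param detector An [train_detector()] model.
#' @return A `probability_map`: list with `values` (matrix aligned to the
#'   image, `NA` in the margin) and `valid_margin`.
#' @export
scan_image <- function(image, detector) {
  px <- if (inherits(image, "raster_image")) image$pixels else image
  w <- detector$window_size
  h <- (w - 1L) %/% 2L
  if (nrow(px) < w || ncol(px) < w) abort("image smaller than the window")
  vr <- nrow(px) - 2L * h
  vc <- ncol(px) - 2L * h
  wk <- matrix(detector$weights, w, w)
  s <- matrix(0, vr, vc)
  for (a in 1:w) for (b in 1:w) {
    if (wk[a, b] == 0) next
    s <- s + wk[a, b] * px[a:(a + vr - 1L), b:(b + vc - 1L)]
  }
  ex <- local_extrema(px, w)
  rng <- ex$max - ex$min
  sum_w <- sum(wk)
  score <- matrix(detector$bias, vr, vc)
  pos <- rng > 0
  score[pos] <- score[pos] + (s[pos] - ex$min[pos] * sum_w) / rng[pos]
  vals <- matrix(NA_real_, nrow(px), ncol(px))
  vals[(h + 1):(h + vr), (h + 1):(h + vc)] <- stats::plogis(score)
  structure(list(values = vals, valid_margin = h), class = "probability_map")
}

#' Threshold a probability map into spot events
#'
#' Binarizes the map at `threshold`, labels 8-connected components, and
#' returns one event per component. Bounding boxes are expanded by `pad`
#' pixels (default the window half-width, so the Gaussian tail is inside the
#' fitted patch) and clipped at the borders; clipped events carry
#' `edge = TRUE`.
#'
#' @param map A [scan_image()] probability map.
#' @param threshold Posterior cut in `[0, 1]`.
#' @param pad Bounding-box pad in pixels.
#' @return A tibble with one row per event: `event_id`, posterior-weighted
#'   centroid `row`/`col`, bbox `rmin`/`rmax`/`cmin`/`cmax`, `peak_posterior`,
#'   `n_pixels`, `edge`.
#' @export
detect_events <- function(map, threshold, pad = map$valid_margin) {
  stopifnot(inherits(map, "probability_map"))
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1]")
  v <- map$values
  mask <- !is.na(v) & v >= threshold
  lab <- label_components_8(mask)
  k <- max(lab)
  empty <- tibble::tibble(
    event_id = integer(), row = numeric(), col = numeric(),
    rmin = integer(), rmax = integer(), cmin = integer(), cmax = integer(),
    peak_posterior = numeric(), n_pixels = integer(), edge = logical())
  if (k == 0L) return(empty)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  rr <- ((idx - 1L) %% nrow(v)) + 1L
  cc <- ((idx - 1L) %/% nrow(v)) + 1L
  wt <- v[idx]
  agg <- function(x, f) vapply(split(x, comp), f, numeric(1))
  wsum <- agg(wt, sum)
  out <- tibble::tibble(
    event_id = seq_len(k),
    row = agg(rr * wt, sum) / wsum,
    col = agg(cc * wt, sum) / wsum,
    rmin = as.integer(agg(rr, min)) - as.integer(pad),
    rmax = as.integer(agg(rr, max)) + as.integer(pad),
    cmin = as.integer(agg(cc, min)) - as.integer(pad),
    cmax = as.integer(agg(cc, max)) + as.integer(pad),
    peak_posterior = agg(wt, max),
    n_pixels = as.integer(agg(wt, length))
  )
  out$edge <- out$rmin < 1 | out$cmin < 1 |
    out$rmax > nrow(v) | out$cmax > ncol(v)
  out$rmin <- pmax(out$rmin, 1L)
  out$cmin <- pmax(out$cmin, 1L)
  out$rmax <- pmin(out$rmax, nrow(v))
  out$cmax <- pmin(out$cmax, ncol(v))
  out
}

#' Cross-validated detection threshold
#'
#' Chooses the largest posterior cut whose mean cross-validated true positive
#' rate stays at or above `target_tpr` (default 0.99), i.e. the cut that
#' minimizes false positives subject to the TPR constraint. Folds are
#' assigned deterministically by interleaving. If no cut achieves the target,
#' the TPR-maximizing cut is returned with a warning.
#'
#' @param spot_patches,background_patches Labeled descriptors as in
#'   [train_detector()].
#' @param folds Number of CV folds (>= 2, default 5).
#' @param target_tpr Required mean CV true positive rate.
#' @param regularization Passed to [train_detector()].
#' @return A list with `threshold`, `cv_tpr`, `cv_fpr`, and `achieved`
#'   (`FALSE` when the target TPR was unattainable).
#' @export
calibrate_threshold <- function(spot_patches, background_patches, folds = 5L,
                                target_tpr = 0.99, regularization = NULL) {
  as_mat <- function(x) if (is.list(x)) do.call(rbind, x) else x
  xs <- as_mat(spot_patches)
  xb <- as_mat(background_patches)
  if (folds < 2) abort("`folds` must be >= 2")
  if (nrow(xs) < folds || nrow(xb) < folds) {
    abort("need at least `folds` patches per class")
  }
  fs <- rep_len(seq_len(folds), nrow(xs))
  fb <- rep_len(seq_len(folds), nrow(xb))
  oof <- purrr::map(seq_len(folds), function(f) {
    det <- train_detector(xs[fs != f, , drop = FALSE],
                          xb[fb != f, , drop = FALSE],
                          regularization = regularization)
    list(pos = predict(det, xs[fs == f, , drop = FALSE])$posterior_spot,
         neg = predict(det, xb[fb == f, , drop = FALSE])$posterior_spot)
  })
  cuts <- sort(unique(c(unlist(purrr::map(oof, "pos")), 0, 1)))
  tpr_at <- function(t) mean(purrr::map_dbl(oof, ~ mean(.x$pos >= t)))
  fpr_at <- function(t) mean(purrr::map_dbl(oof, ~ mean(.x$neg >= t)))
  tprs <- vapply(cuts, tpr_at, numeric(1))
  ok <- tprs >= target_tpr
  if (any(ok)) {
    thr <- max(cuts[ok])
    achieved <- TRUE
  } else {
    warn(sprintf("no threshold reaches TPR >= %.3g; returning the %s",
                 target_tpr, "TPR-maximizing cut"))
    thr <- cuts[which.max(tprs)]
    achieved <- FALSE
  }
  list(threshold = thr, cv_tpr = tpr_at(thr), cv_fpr = fpr_at(thr),
       achieved = achieved)
}

#' Persist / restore a detector model as JSON
#'
#' @param detector An `lda_detector`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `lda_detector` (read).
#' @export
write_detector_json <- function(detector, path) {
  stopifnot(inherits(detector, "lda_detector"))
  out <- unclass(detector)
  out$pooled_covariance <- as.vector(out$pooled_covariance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detector_json
#' @export
read_detector_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(raw$mean_spot)
  raw$pooled_covariance <- matrix(raw$pooled_covariance, d, d)
  raw$window_size <- as.integer(raw$window_size)
  raw$threshold <- as.numeric(raw$threshold %||% NA_real_)
  structure(raw, class = "lda_detector")
}

#' Build a labeled descriptor set from simulated fields
#'
#' Renders seeded fields, takes one positive descriptor at each true spot
#' centre and `negatives_per_image` negatives at random positions far from
#' every spot. Used to train and calibrate the detector without manual
#' annotation.
#'
#' @param n_images Number of fields to render.
#' @param spots_per_image Spots per field.
#' @param snr_range Range of per-image SNR values (uniform).
#' @param w Window size.
#' @param negatives_per_image Background descriptors per field.
#' @param seed Integer seed.
#' @param ... Passed to [spot_field()].
#' @return List with matrices `spots` and `background` (one descriptor per
#'   row).
#' @export
simulated_training_set <- function(n_images = 8L, spots_per_image = 12L,
                                   snr_range = c(20, 100), w = 15L,
                                   negatives_per_image = 40L, seed = 1L,
                                   ...) {
  h <- (w - 1L) %/% 2L
  snrs <- withr::with_seed(seed + 3L,
                           stats::runif(n_images, snr_range[1], snr_range[2]))
  pos <- list(); neg <- list()
  for (i in seq_len(n_images)) {
    f <- spot_field(spots_per_image, snr = snrs[i], seed = seed + 100L * i,
                    margin_px = h + 2L, ...)
    px <- f$image$pixels
    for (j in seq_len(nrow(f$truth))) {
      pos[[length(pos) + 1L]] <- extract_descriptor(
        px, round(c(f$truth$row[j], f$truth$col[j])), w)
    }
    neg_pos <- withr::with_seed(seed + 100L * i + 1L, {
      acc <- matrix(numeric(0), 0, 2)
      while (nrow(acc) < negatives_per_image) {
        cand <- c(stats::runif(1, h + 1, nrow(px) - h),
                  stats::runif(1, h + 1, ncol(px) - h))
        d <- sqrt((f$truth$row - cand[1])^2 + (f$truth$col - cand[2])^2)
        if (min(d) > w) acc <- rbind(acc, round(cand))
      }
      acc
    })
    for (j in seq_len(nrow(neg_pos))) {
      neg[[length(neg) + 1L]] <- extract_descriptor(px, neg_pos[j, ], w)
    }
  }
  list(spots = do.call(rbind, pos), background = do.call(rbind, neg))
}
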