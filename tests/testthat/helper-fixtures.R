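# shared fixtures and independent oracles for the test suite

.cache <- new.env(parent = emptyenv())

# small simulated training set + calibrated detector, built once per run
cached_detector <- function() {
  if (is.null(.cache$det)) {
    tr <- simulated_training_set(n_images = 6L, spots_per_image = 10L,
                                 seed = 5L)
    cal <- calibrate_threshold(tr$spots, tr$background, folds = 5L)
    det <- train_detector(tr$spots, tr$background)
    det$threshold <- cal$threshold
    .cache$train <- tr
    .cache$cal <- cal
    .cache$det <- det
  }
  .cache$det
}

cached_training_set <- function() {
  cached_detector()
  .cache$train
}

cached_calibration <- function() {
  cached_detector()
  .cache$cal
}

bead_sigma <- function(pixel_size_um = 3) {
  7.5 / (pixel_size_um * 2 * sqrt(2 * log(2)))
}

# single noise-free discretized spot on a flat background
flat_spot_patch <- function(row, col, photons, sigma, size = 25L,
                            background = 5, noise = "none", seed = 1L) {
  tr <- spot_truth(row, col, photons, sigma)
  render_field(field_spec(c(size, size), background_level = background,
                          noise = noise, spots = tr, seed = seed))
}

# ---- independent oracle: exhaustive weighted-likelihood fit on 5x5 patches
# (isotropic Gaussian + uniform; written without any hemcyto EM code)

oracle_loglik <- function(patch, mu, sigma, wbg) {
  xs <- as.vector(row(patch))
  ys <- as.vector(col(patch))
  g <- exp(-((xs - mu[1])^2 + (ys - mu[2])^2) / (2 * sigma^2)) /
    (2 * pi * sigma^2)
  dens <- (1 - wbg) * g + wbg / length(patch)
  sum(as.vector(patch) * log(dens))
}

oracle_fit_5x5 <- function(patch) {
  obj <- function(p, mu) -oracle_loglik(patch, mu, exp(p[1]),
                                        stats::plogis(p[2]))
  eval_mu <- function(mu) {
    o <- stats::optim(c(0, stats::qlogis(0.3)), obj, mu = mu,
                      method = "Nelder-Mead")
    list(mu = mu, val = o$value, sigma = exp(o$par[1]),
         wbg = stats::plogis(o$par[2]))
  }
  best <- NULL
  for (r in seq(2.5, 3.5, by = 0.1)) for (c in seq(2.5, 3.5, by = 0.1)) {
    e <- eval_mu(c(r, c))
    if (is.null(best) || e$val < best$val) best <- e
  }
  coarse <- best$mu
  for (r in seq(coarse[1] - 0.1, coarse[1] + 0.1, by = 0.01)) {
    for (c in seq(coarse[2] - 0.1, coarse[2] + 0.1, by = 0.01)) {
      e <- eval_mu(c(r, c))
      if (e$val < best$val) best <- e
    }
  }
  best
}

# closed-form eigendecomposition of a symmetric 2x2 matrix (independent of
# the package's propose_split implementation)
eigen2x2 <- function(s) {
  a <- s[1, 1]; b <- s[1, 2]; d <- s[2, 2]
  disc <- sqrt(((a - d) / 2)^2 + b^2)
  l1 <- (a + d) / 2 + disc
  if (abs(b) < 1e-14) v <- if (a >= d) c(1, 0) else c(0, 1)
  else {
    v <- c(l1 - d, b)
    v <- v / sqrt(sum(v^2))
  }
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  list(lmax = l1, lmin = (a + d) / 2 - disc, v = v)
}
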