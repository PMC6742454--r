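test_that("the three covariance QC rules fire in their stated order", {
  lim <- qc_limits(pixel_size_um = 3)
  expect_identical(validate_component(diag(0.04, 2), lim),
                   "rejected(too_small)")
  expect_identical(validate_component(diag(4, 2), lim), "valid")
  expect_identical(validate_component(diag(c(100, 1e-9)), lim),
                   "rejected(degenerate)")
  # footprint bound: a Gaussian the size of the whole default budget
  big <- diag(100, 2)
  expect_identical(validate_component(big, lim), "rejected(too_large)")
  expect_error(qc_limits(min_three_sigma = -1), "> 0")
})

test_that("split geometry follows the leading eigenvector", {
  g <- list(mean = c(0, 0), cov = diag(c(9, 1)), weight = 0.4)
  sp <- propose_split(g)
  expect_equal(sp$magnitude, 3)
  expect_equal(sp$direction, c(1, 0))
  expect_equal(sp$child_means, rbind(c(3, 0), c(-3, 0)))
  expect_equal(sp$child_weight, 0.2)
  # rotated 45 degrees
  r <- matrix(c(1, 1, -1, 1), 2) / sqrt(2)
  g2 <- list(mean = c(0, 0), cov = r %*% diag(c(9, 1)) %*% t(r), weight = 1)
  sp2 <- propose_split(g2)
  expect_equal(sp2$magnitude, 3, tolerance = 1e-9)
  expect_equal(abs(sum(sp2$direction * c(1, 1) / sqrt(2))), 1,
               tolerance = 1e-9)
  # isotropic tie-break: first coordinate axis
  sp3 <- propose_split(list(mean = c(5, 5), cov = diag(4, 2), weight = 1))
  expect_equal(sp3$magnitude, 2)
  expect_equal(sp3$direction, c(1, 0))
})

test_that("proposed children are symmetric and separated by 2 sqrt(lmax)", {
  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, 0.5, 9); d <- runif(1, 0.5, 9)
    b <- runif(1, -1, 1) * sqrt(a * d) * 0.9
    g <- list(mean = runif(2, -5, 5), cov = matrix(c(a, b, b, d), 2),
              weight = 1)
    sp <- propose_split(g)
    o <- eigen2x2(g$cov)
    expect_equal(colMeans(sp$child_means), g$mean, tolerance = 1e-9)
    expect_equal(sqrt(sum(diff(sp$child_means)^2)), 2 * sqrt(o$lmax),
                 tolerance = 1e-9)
  }
})

test_that("BIC penalizes duplicated components by exactly 6 log n_eff", {
  f <- flat_spot_patch(13.4, 12.9, 3000, 1.1, background = 10,
                       noise = "poisson", seed = 17)
  patch <- f$image$pixels
  fit <- fit_hem(patch, hem_init(patch, c(13, 13)))
  dup <- fit
  half <- fit$components[[1]]
  half$weight <- half$weight / 2
  dup$components <- list(half, half)
  expect_equal(compute_bic(dup, patch) - compute_bic(fit, patch),
               6 * log(sum(patch)), tolerance = 1e-6)
  expect_error(compute_bic(fit, matrix(0, 5, 5)), "zero")
})

test_that("BIC prefers one Gaussian for a spot and two for a doublet", {
  f1 <- flat_spot_patch(13.4, 12.9, 1000, bead_sigma(), background = 11,
                        noise = "poisson", seed = 17)
  p1 <- f1$image$pixels
  one <- fit_hem(p1, hem_init(p1, c(13, 13)))
  two <- fit_hem(p1, hem_init(p1, rbind(c(12, 12), c(14, 14))))
  expect_lt(compute_bic(one, p1), compute_bic(two, p1))
  f2 <- cluster_field(2, 6, snr = 20, seed = 19)
  p2 <- f2$image$pixels
  ctrs <- as.matrix(f2$truth[, c("row", "col")])
  one2 <- fit_hem(p2, hem_init(p2, colMeans(ctrs)))
  two2 <- fit_hem(p2, hem_init(p2, ctrs))
  expect_lt(compute_bic(two2, p2), compute_bic(one2, p2))
})

test_that("refinement recovers isolated spots and equal doublets", {
  for (s in 1:10) {
    f <- flat_spot_patch(13 + 0.03 * s, 13 - 0.04 * s, 1000, bead_sigma(),
                         background = 7, noise = "poisson", seed = 100 + s)
    fit <- refine_event(f$image$pixels, hem_init(f$image$pixels, c(13, 13)))
    expect_identical(length(fit$components), 1L)
  }
  hits <- vapply(1:10, function(s) {
    f <- cluster_field(2, 6, snr = 20, seed = 200 + s)
    fit <- refine_event(f$image$pixels, hem_init(f$image$pixels, c(21, 21)))
    if (length(fit$components) != 2) return(FALSE)
    mu <- t(vapply(fit$components, `[[`, numeric(2), "mean"))
    d <- sqrt(outer(mu[, 1], f$truth$row, `-`)^2 +
                outer(mu[, 2], f$truth$col, `-`)^2)
    all(apply(d, 2, min) < 0.5)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("refinement is deterministic and never returns invalid components", {
  f <- cluster_field(3, 5, snr = 25, seed = 5)
  patch <- f$image$pixels
  a <- refine_event(patch, hem_init(patch, c(21, 21)))
  b <- refine_event(patch, hem_init(patch, c(21, 21)))
  expect_identical(a, b)
  lim <- qc_limits()
  fixtures <- c(list(patch), lapply(1:4, function(s) {
    cluster_field(2, 4 + s, snr = 12, seed = 300 + s)$image$pixels
  }))
  for (p in fixtures) {
    fit <- refine_event(p, hem_init(p, (dim(p) + 1) / 2))
    for (g in fit$components) {
      expect_identical(validate_component(g, lim), "valid")
    }
  }
})

test_that("accepted splits strictly decrease BIC below the initial fit", {
  f <- cluster_field(2, 6, snr = 25, seed = 41)
  patch <- f$image$pixels
  init <- hem_init(patch, c(21, 21))
  single <- fit_hem(patch, init)
  refined <- refine_event(patch, init, debug = TRUE)
  rl <- attr(refined, "refine_log")
  accepted <- Filter(function(r) r$accepted, rl)
  expect_gt(length(accepted), 0)
  for (r in accepted) expect_gt(r$bic_before - r$bic_after, 10)
  expect_lt(compute_bic(refined, patch), compute_bic(single, patch))
})
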