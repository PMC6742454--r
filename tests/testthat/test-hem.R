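test_that("gaussian density matches closed forms and integrates to one", {
  expect_equal(gaussian_density(c(0, 0), c(0, 0), diag(2)), 1 / (2 * pi))
  expect_equal(gaussian_density(c(1, 2), c(1, 2), diag(4, 2)), 1 / (8 * pi))
  # fine-grid quadrature over +/- 6 sigma in each direction
  s <- matrix(c(2, 0.7, 0.7, 1), 2)
  g <- seq(-12, 12, length.out = 601)
  step <- diff(g)[1]
  x <- as.matrix(expand.grid(g, g))
  expect_equal(sum(gaussian_density(x, c(0, 0), s)) * step^2, 1,
               tolerance = 1e-6)
  expect_error(gaussian_density(c(0, 0), c(0, 0),
                                matrix(c(1, 2, 2, 1), 2)), "definite")
})

test_that("uniform background density is the reciprocal domain area", {
  expect_equal(uniform_density(100, 100), 1e-4)
  expect_equal(uniform_density(15, 15), 1 / 225)
  for (wh in list(c(3, 7), c(21, 21), c(10, 400))) {
    expect_equal(uniform_density(wh[1], wh[2]) * wh[1] * wh[2], 1)
  }
})

test_that("responsibilities normalize per pixel in the expected ways", {
  patch <- matrix(5, 9, 9)
  # single Gaussian carrying all weight
  f1 <- hem_init(patch, c(5, 5))
  f1$components[[1]]$weight <- 1
  f1$background$weight <- 0
  expect_equal(as.vector(hem_e_step(patch, f1)[, 1]), rep(1, 81))
  # two identical Gaussians split everything evenly
  f2 <- hem_init(patch, rbind(c(5, 5), c(5, 5)))
  f2$components[[1]]$weight <- 0.5
  f2$components[[2]]$weight <- 0.5
  f2$background$weight <- 0
  z2 <- hem_e_step(patch, f2)
  expect_equal(z2[, 1], rep(0.5, 81))
  # rows always sum to one, background included
  f3 <- hem_init(patch, c(4, 6))
  expect_equal(rowSums(hem_e_step(patch, f3)), rep(1, 81))
})

test_that("the M-step is an intensity-weighted update", {
  patch <- matrix(0, 3, 3)
  patch[1, 1] <- 5; patch[1, 3] <- 5
  fit <- hem_init(patch, c(1, 2))
  z <- matrix(0, 9, 2); z[, 1] <- 1
  up <- hem_m_step(patch, z, fit)
  expect_equal(up$components[[1]]$mean, c(1, 2))
  expect_equal(sum(vapply(up$components, `[[`, numeric(1), "weight")) +
                 up$background$weight, 1, tolerance = 1e-12)
  # parameter recovery: noise-free sigma = 2 spot within 5 %
  f <- flat_spot_patch(13.2, 12.8, 20000, 2, background = 2, seed = 3)
  fit2 <- fit_hem(f$image$pixels, hem_init(f$image$pixels, c(13, 13)))
  s_eff <- det(fit2$components[[1]]$cov)^0.25
  expect_lt(abs(s_eff - 2) / 2, 0.05)
})

test_that("EM on a flat noisy patch assigns the mass to the background", {
  f <- render_field(field_spec(c(21, 21), background_level = 30, seed = 5))
  fit <- fit_hem(f$image$pixels, hem_init(f$image$pixels, c(11, 11)))
  expect_gte(fit$background$weight, 0.9)
})

test_that("the weighted log-likelihood trace never decreases", {
  fixtures <- list(
    flat_spot_patch(13.3, 12.6, 2000, bead_sigma(), background = 40,
                    noise = "poisson", seed = 21)$image$pixels,
    cluster_field(2, 5, snr = 15, seed = 22)$image$pixels,
    render_field(field_spec(c(15, 15), background_level = 8, seed = 23))$image$pixels)
  for (patch in fixtures) {
    fit <- fit_hem(patch, hem_init(patch, (dim(patch) + 1) / 2))
    expect_true(all(diff(fit$loglik_trace) > -1e-9))
  }
})

test_that("fluorescence attribution conserves the total patch intensity", {
  f <- cluster_field(2, 6, snr = 20, seed = 19)
  patch <- f$image$pixels
  fit <- fit_hem(patch, hem_init(patch, rbind(c(19, 22), c(23, 20))))
  fl_all <- measure_fluorescence(fit, patch)
  fl_bg <- measure_fluorescence(fit, patch, "background")
  expect_equal(sum(fl_all) + fl_bg, sum(patch), tolerance = 1e-9)
  # with no background weight a single Gaussian takes everything
  solo <- hem_init(patch, c(21, 21))
  solo$components[[1]]$weight <- 1
  solo$background$weight <- 0
  expect_equal(measure_fluorescence(solo, patch, 1), sum(patch))
})

test_that("fluorescence recovery is accurate and linear in amplitude", {
  errs <- vapply(1:20, function(s) {
    f <- flat_spot_patch(13.2, 12.7, 10000, bead_sigma(), background = 5,
                         noise = "poisson", seed = s)
    fit <- fit_hem(f$image$pixels, hem_init(f$image$pixels, c(13, 13)))
    measure_fluorescence(fit, f$image$pixels, 1) / 10000 - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
  # linearity: scaling amplitude by k scales recovery by k within 2 %
  rec <- vapply(c(1, 2, 4), function(k) {
    f <- flat_spot_patch(13.2, 12.7, k * 2000, bead_sigma(),
                         background = 20, noise = "poisson", seed = 77)
    fit <- fit_hem(f$image$pixels, hem_init(f$image$pixels, c(13, 13)))
    measure_fluorescence(fit, f$image$pixels, 1)
  }, numeric(1))
  expect_lt(abs(rec[2] / rec[1] - 2) / 2, 0.02)
  expect_lt(abs(rec[3] / rec[1] - 4) / 4, 0.02)
})

test_that("diameters follow the FWHM of the effective spread", {
  fit <- new_fit <- structure(
    list(components = list(list(mean = c(0, 0), cov = diag(4, 2),
                                weight = 0.5)),
         background = list(weight = 0.5, domain_height = 10,
                           domain_width = 10)),
    class = "hem_fit")
  expect_equal(estimate_diameter(fit, 1, 3), 3 * 2 * sqrt(2 * log(2)) * 2,
               tolerance = 1e-9)
  fit$components[[1]]$cov <- diag(c(4, 1))
  expect_equal(estimate_diameter(fit, 1, 3),
               3 * 2 * sqrt(2 * log(2)) * sqrt(2), tolerance = 1e-9)
})

test_that("tidy and glance summarize fits as tibbles", {
  f <- flat_spot_patch(13, 13, 3000, 1.1, background = 10,
                       noise = "poisson", seed = 2)
  fit <- fit_hem(f$image$pixels, hem_init(f$image$pixels, c(13, 13)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 2L)
  expect_identical(td$type, c("gaussian", "background"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_equal(gl$logLik, fit$loglik_trace[fit$n_iterations])
})
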