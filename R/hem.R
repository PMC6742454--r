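#' Bivariate Gaussian density
#'
#' Standard bivariate normal density with normalizer `2 * pi * sqrt(det(cov))`.
#'
#' @param x Positions: numeric length-2 vector or an `n x 2` matrix of
#'   `(row, col)` coordinates.
#' @param mean Length-2 centre.
#' @param cov 2 x 2 symmetric positive definite covariance (px^2).
#' @param log Return log density?
#' @return Numeric vector of densities.
#' @export
#' @examples
#' gaussian_density(c(0, 0), c(0, 0), diag(2))  # 1 / (2 * pi)
gaussian_density <- function(x, mean, cov, log = FALSE) {
  if (is.null(dim(x))) x <- rbind(x)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) abort("covariance must be positive definite")
  dx <- sweep(x, 2, mean)
  z <- backsolve(ch, t(dx), transpose = TRUE)
  ld <- -colSums(z^2) / 2 - log(2 * pi) - sum(base::log(diag(ch)))
  if (log) ld else exp(ld)
}

#' Uniform background density over the fitting domain
#'
#' @param domain_width,domain_height Domain dimensions in pixels (> 0).
#' @return The constant density `1 / (domain_width * domain_height)`.
#' @export
#' @examples
#' uniform_density(100, 100)  # 1e-4
uniform_density <- function(domain_width, domain_height) {
  if (domain_width <= 0 || domain_height <= 0) {
    abort("domain dimensions must be > 0")
  }
  1 / (domain_width * domain_height)
}

# (row, col) pixel-centre coordinates of a patch, column-major to match
# as.vector(patch)
pixel_coords <- function(patch) {
  cbind(as.vector(row(patch)), as.vector(col(patch)))
}

new_hem_fit <- function(components, background, loglik_trace = numeric(),
                        converged = FALSE, n_iterations = 0L) {
  structure(
    list(components = components, background = background,
         loglik_trace = loglik_trace, converged = converged,
         n_iterations = n_iterations),
    class = "hem_fit"
  )
}

#' @export
print.hem_fit <- function(x, ...) {
  cat(sprintf(
    "<hem_fit> %d Gaussian(s) + uniform background (weight %.3f), %s in %d iter\n",
    length(x$components), x$background$weight,
    if (x$converged) "converged" else "not converged", x$n_iterations))
  for (i in seq_along(x$components)) {
    g <- x$components[[i]]
    cat(sprintf("  [%d] mu = (%.2f, %.2f), weight %.3f, sigma_eff %.3f px\n",
                i, g$mean[1], g$mean[2], g$weight, det(g$cov)^0.25))
  }
  invisible(x)
}

#' Initial heterogeneous mixture for a patch
#'
#' One isotropic Gaussian per seed centre, scale-matched to the expected cell
#' diameter (`sigma0 = d0 / (2 * sqrt(2 * log(2)) * pixel_size)`), plus the
#' uniform background. The Gaussians share weight 0.5 equally and the
#' background starts at 0.5, which keeps the background from capturing the
#' spot during early iterations.
#'
#' @param patch Numeric intensity matrix.
#' @param centers `(row, col)` vector or matrix of seed centres
#'   (patch-local coordinates).
#' @param pixel_size_um Pixel size (um).
#' @param init_diameter_um Expected cell diameter used for the initial scale
#'   (default 10 um).
#' @param background_domain Optional `(height, width)` of the uniform
#'   component's domain; defaults to the patch dimensions (local background).
#' @return An unfitted `hem_fit`.
#' @export
hem_init <- function(patch, centers, pixel_size_um = 3,
                     init_diameter_um = 10, background_domain = NULL) {
  if (is.null(dim(centers))) centers <- rbind(centers)
  n <- nrow(centers)
  s0 <- init_diameter_um / (fwhm_factor() * pixel_size_um)
  comps <- purrr::map(seq_len(n), function(i) {
    list(mean = as.numeric(centers[i, ]), cov = diag(s0^2, 2),
         weight = 0.5 / n, empty = FALSE)
  })
  dom <- background_domain %||% dim(patch)
  bg <- list(weight = 0.5, domain_height = dom[1], domain_width = dom[2])
  new_hem_fit(comps, bg)
}

# per-pixel, per-component log densities (npix x (N + 1)); background last
hem_log_densities <- function(patch, fit) {
  x <- pixel_coords(patch)
  n <- length(fit$components)
  ld <- matrix(0, nrow(x), n + 1L)
  for (c in seq_len(n)) {
    g <- fit$components[[c]]
    ld[, c] <- gaussian_density(x, g$mean, g$cov, log = TRUE)
  }
  ld[, n + 1L] <- log(uniform_density(fit$background$domain_width,
                                      fit$background$domain_height))
  ld
}

hem_weights <- function(fit) {
  c(purrr::map_dbl(fit$components, "weight"), fit$background$weight)
}

#' E-step: per-pixel responsibilities
#'
#' Computes, once per pixel, the posterior membership
#' `z_c(x) = pi_c f_c(x) / sum_n pi_n f_n(x)` for every component including
#' the uniform background, in log space. Pixels where every component's
#' density underflows are assigned entirely to the background.
#'
#' @param patch Numeric intensity matrix.
#' @param fit A `hem_fit`.
#' @return An `npix x (N + 1)` matrix of responsibilities (background last,
#'   pixels in column-major order); rows sum to 1.
#' @export
hem_e_step <- function(patch, fit) {
  lw <- log(hem_weights(fit))
  lp <- sweep(hem_log_densities(patch, fit), 2, lw, `+`)
  lse <- logsumexp_rows(lp)
  z <- exp(lp - lse)
  bad <- !is.finite(lse)
  if (any(bad)) {
    z[bad, ] <- 0
    z[bad, ncol(z)] <- 1
  }
  z
}

#' M-step: intensity-weighted parameter updates
#'
#' Every pixel contributes with weight `z_c(x) * I(x)`: mixing weights are
#' the intensity-weighted responsibility shares, Gaussian means the weighted
#' centroids, and covariances the weighted scatter about the updated mean.
#' Covariance eigenvalues are floored at `cov_floor` to stop collapse onto
#' single bright pixels before the QC rules run. Components attracting
#' (numerically) no intensity are flagged `empty` for the refiner to cull.
#'
#' @param patch Numeric intensity matrix with `sum(patch) > 0`.
#' @param z Responsibilities from [hem_e_step()].
#' @param fit Current `hem_fit`.
#' @param cov_floor Eigenvalue floor in px^2 (default 0.04).
#' @param fix_background_weight When non-`NULL`, the background mixing weight
#'   is held at this value (global-background mode) and the Gaussian weights
#'   share the remainder proportionally.
#' @return The updated `hem_fit`.
#' @export
hem_m_step <- function(patch, z, fit, cov_floor = 0.04,
                       fix_background_weight = NULL) {
  intens <- as.vector(patch)
  tot <- sum(intens)
  if (tot <= 0) abort("patch has zero total intensity")
  x <- pixel_coords(patch)
  n <- length(fit$components)
  wz <- z * intens
  mass <- colSums(wz)
  pis <- mass / tot
  if (!is.null(fix_background_weight)) {
    gsum <- sum(pis[seq_len(n)])
    pis[seq_len(n)] <- if (gsum > 0) {
      pis[seq_len(n)] * (1 - fix_background_weight) / gsum
    } else rep((1 - fix_background_weight) / n, n)
    pis[n + 1L] <- fix_background_weight
  }
  for (c in seq_len(n)) {
    g <- fit$components[[c]]
    g$weight <- pis[c]
    if (mass[c] / tot < 1e-12) {
      g$empty <- TRUE
    } else {
      g$empty <- FALSE
      wc <- wz[, c]
      mu <- colSums(x * wc) / mass[c]
      dx <- sweep(x, 2, mu)
      sig <- crossprod(dx * sqrt(wc)) / mass[c]
      eg <- eigen(sig, symmetric = TRUE)
      vals <- pmax(eg$values, cov_floor)
      g$mean <- mu
      g$cov <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
    }
    fit$components[[c]] <- g
  }
  fit$background$weight <- pis[n + 1L]
  fit
}

#' Intensity-weighted log-likelihood of a fit
#'
#' `L = sum_x I(x) * log(sum_c pi_c f_c(x))`: each pixel counts as many times
#' as photons it received, computed once per pixel.
#'
#' @inheritParams hem_e_step
#' @return Scalar log-likelihood.
#' @export
hem_loglik <- function(patch, fit) {
  lw <- log(hem_weights(fit))
  lp <- sweep(hem_log_densities(patch, fit), 2, lw, `+`)
  sum(as.vector(patch) * logsumexp_rows(lp))
}

#' Fit the heterogeneous mixture by intensity-weighted EM
#'
#' Alternates [hem_e_step()] and [hem_m_step()] until the relative change of
#' the intensity-weighted log-likelihood drops below `tol` or `max_iter` is
#' reached. The per-iteration likelihood trace is recorded and is
#' non-decreasing (EM ascent).
#'
#' @param patch Numeric intensity matrix.
#' @param init Initial `hem_fit` (>= 1 Gaussian + the uniform background),
#'   e.g. from [hem_init()].
#' @param tol Relative log-likelihood tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @inheritParams hem_m_step
#' @return The converged `hem_fit` with `loglik_trace`, `converged`,
#'   `n_iterations` filled in.
#' @export
fit_hem <- function(patch, init, tol = 1e-8, max_iter = 200L,
                    cov_floor = 0.04, fix_background_weight = NULL) {
  stopifnot(inherits(init, "hem_fit"), length(init$components) >= 1)
  fit <- init
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    z <- hem_e_step(patch, fit)
    fit <- hem_m_step(patch, z, fit, cov_floor = cov_floor,
                      fix_background_weight = fix_background_weight)
    ll <- hem_loglik(patch, fit)
    if (!is.finite(ll)) abort("non-finite likelihood during EM")
    trace[iter] <- ll
    if (is.finite(prev) && abs(ll - prev) <= tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- ll
  }
  fit$loglik_trace <- trace
  fit$converged <- converged
  fit$n_iterations <- iter
  fit
}

#' Per-component fluorescence from final responsibilities
#'
#' `Fluorescence_c = sum_x z_c(x) * I(x)`: the spot's share of the patch
#' intensity under the fitted mixture. Summing over all components including
#' the background returns `sum(patch)` exactly.
#'
#' @param fit A fitted `hem_fit`.
#' @param patch The fitted intensity matrix.
#' @param component Component index, `"background"`, or `NULL` for all
#'   Gaussians.
#' @return Numeric fluorescence value(s).
#' @export
measure_fluorescence <- function(fit, patch, component = NULL) {
  z <- hem_e_step(patch, fit)
  fl <- colSums(z * as.vector(patch))
  n <- length(fit$components)
  if (is.null(component)) return(fl[seq_len(n)])
  if (identical(component, "background")) return(fl[n + 1L])
  fl[component]
}

#' Physical diameter of a fitted component
#'
#' The effective spread is the rotation-invariant geometric mean of the
#' principal standard deviations, `sigma_eff = det(cov)^(1/4)`; the diameter
#' is its full width at half maximum scaled to physical units:
#' `pixel_size * 2 * sqrt(2 * log(2)) * sigma_eff`.
#'
#' @param fit A fitted `hem_fit`.
#' @param component Gaussian component index.
#' @param pixel_size_um Pixel size (um).
#' @return Diameter in micrometres.
#' @export
estimate_diameter <- function(fit, component, pixel_size_um = 3) {
  g <- fit$components[[component]]
  d <- det(g$cov)
  if (d <= 0) abort("degenerate covariance")
  pixel_size_um * fwhm_factor() * d^0.25
}
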