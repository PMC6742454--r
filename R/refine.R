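#' Quality-control limits for fitted Gaussian components
#'
#' Encodes the three rejection rules for implausible fits: (1) too small ---
#' the Gaussian does not even cover one pixel (`3 * sigma_min <
#' min_three_sigma`); (2) too large --- the 3-sigma ellipse covers more area
#' than any plausible cell cluster, the default bound being three cells of
#' `max_cell_diameter_um` FWHM; (3) degenerate --- a near-singular covariance
#' from fitting a correlated set of background pixels.
#'
#' @param pixel_size_um Pixel size (um).
#' @param min_three_sigma Lower bound on `3 * sqrt(lambda_min)` in pixels
#'   (default 1: the Gaussian must cover at least one pixel).
#' @param max_cell_diameter_um Largest expected cell diameter (default 20 um)
#'   used for the footprint bound.
#' @param max_footprint_px2 Area bound on the 3-sigma ellipse
#'   (`pi * 3 sigma_1 * 3 sigma_2`); default three times the 3-sigma ellipse
#'   area of a `max_cell_diameter_um` cell.
#' @param max_condition_number Eigenvalue-ratio bound (default 1000).
#' @param min_eigenvalue Absolute lower bound on the smallest eigenvalue
#'   (px^2, default 0.01).
#' @return A `qc_limits` list.
#' @export
qc_limits <- function(pixel_size_um = 3, min_three_sigma = 1,
                      max_cell_diameter_um = 20,
                      max_footprint_px2 = NULL,
                      max_condition_number = 1000, min_eigenvalue = 0.01) {
  if (is.null(max_footprint_px2)) {
    s_cell <- max_cell_diameter_um / (fwhm_factor() * pixel_size_um)
    max_footprint_px2 <- 3 * pi * (3 * s_cell)^2
  }
  lim <- list(min_three_sigma = min_three_sigma,
              max_footprint_px2 = max_footprint_px2,
              max_condition_number = max_condition_number,
              min_eigenvalue = min_eigenvalue)
  if (any(unlist(lim) <= 0)) abort("all QC bounds must be > 0")
  structure(lim, class = "qc_limits")
}

#' Validate a fitted Gaussian component against the QC rules
#'
#' @param component A Gaussian component (list with `cov`), or a 2 x 2
#'   covariance matrix.
#' @param limits A [qc_limits()] object.
#' @return `"valid"`, or `"rejected(too_small)"`, `"rejected(too_large)"`,
#'   `"rejected(degenerate)"` naming the first failed rule.
#' @export
validate_component <- function(component, limits = qc_limits()) {
  sig <- if (is.matrix(component)) component else component$cov
  ev <- eigen2_closed_form(sig)$values
  s1 <- sqrt(max(ev[1], 0)); s2 <- sqrt(max(ev[2], 0))
  # degeneracy (near-singular scatter from correlated pixels) is checked
  # first: such fits are also tiny along one axis, but the failure is the
  # conditioning, not the size
  if (ev[2] <= 0 || ev[1] / ev[2] > limits$max_condition_number ||
      ev[2] < limits$min_eigenvalue) {
    return("rejected(degenerate)")
  }
  if (3 * s2 < limits$min_three_sigma) return("rejected(too_small)")
  if (pi * (3 * s1) * (3 * s2) > limits$max_footprint_px2) {
    return("rejected(too_large)")
  }
  "valid"
}

#' Propose splitting one Gaussian into two along its leading axis
#'
#' A single Gaussian fitted over two nearby similar spots centres between
#' them, points its leading eigenvector through both centres, and carries the
#' centre separation in its leading eigenvalue. The proposal therefore places
#' the children at `mu +/- sqrt(lambda_max) * v_max`. Each child is seeded
#' with the parent scatter minus the between-centres spread along the split
#' axis: for two similar round spots the within-spot variance along that axis
#' is the minor eigenvalue, so the child covariance is
#' `cov - (lambda_max - lambda_min) * v v'` (eigen-floored), with half the
#' parent weight; the refit then recovers differently sized cells.
#' For an exactly isotropic covariance the direction tie-breaks to the first
#' coordinate (row) axis; eigenvector signs are fixed (non-negative first
#' component) so the proposal is deterministic.
#'
#' @param component Gaussian component (list with `mean`, `cov`, `weight`).
#' @param cov_floor Eigenvalue floor for the child covariances (px^2).
#' @return A `split_decision` list: `direction` (unit vector), `magnitude`
#'   (`sqrt(lambda_max)`, pixels), `child_means` (2 x 2 matrix, one child per
#'   row), `child_cov`, `child_weight`.
#' @export
propose_split <- function(component, cov_floor = 0.04) {
  sig <- component$cov
  eg <- eigen(sig, symmetric = TRUE)
  lmax <- eg$values[1]
  if (lmax <= 0) abort("covariance must be positive definite")
  v <- eg$vectors[, 1]
  if (abs(eg$values[1] - eg$values[2]) <=
      1e-12 * max(abs(eg$values), 1)) {
    v <- c(1, 0)
  }
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  mag <- sqrt(lmax)
  child_cov <- sig - (lmax - max(eg$values[2], 0)) * tcrossprod(v)
  egc <- eigen(child_cov, symmetric = TRUE)
  child_cov <- egc$vectors %*% diag(pmax(egc$values, cov_floor)) %*%
    t(egc$vectors)
  mu <- component$mean
  structure(
    list(direction = v, magnitude = mag,
         child_means = rbind(mu + mag * v, mu - mag * v),
         child_cov = child_cov, child_weight = component$weight / 2),
    class = "split_decision"
  )
}

#' Bayesian information criterion of a heterogeneous fit
#'
#' `BIC = k * log(n_eff) - 2 * L` with `L` the intensity-weighted
#' log-likelihood. Intensities are photon counts, so the effective sample
#' size defaults to the total intensity `sum(patch)`; `n_eff = "pixels"`
#' uses the pixel count instead. Each Gaussian contributes 6 free parameters
#' (2 mean, 3 covariance, 1 mixing weight); the background density is
#' parameter-free and its weight is absorbed by the sum-to-one constraint,
#' so `k = 6 * N`.
#'
#' @param fit A fitted `hem_fit`.
#' @param patch The fitted intensity matrix.
#' @param n_eff `"intensity"` (default) or `"pixels"`.
#' @return Scalar BIC (lower is better).
#' @export
compute_bic <- function(fit, patch, n_eff = c("intensity", "pixels")) {
  n_eff <- match.arg(n_eff)
  n <- if (n_eff == "intensity") sum(patch) else length(patch)
  if (n <= 0) abort("effective sample size is zero")
  k <- 6 * length(fit$components)
  k * log(n) - 2 * hem_loglik(patch, fit)
}

# drop components listed in `drop`, renormalizing remaining weights
cull_components <- function(fit, drop) {
  if (length(drop) == 0) return(fit)
  fit$components <- fit$components[-drop]
  w <- sum(purrr::map_dbl(fit$components, "weight")) + fit$background$weight
  if (w <= 0) {
    fit$background$weight <- 1
    return(fit)
  }
  fit$components <- purrr::map(fit$components, function(g) {
    g$weight <- g$weight / w
    g
  })
  fit$background$weight <- fit$background$weight / w
  fit
}

#' Recursive BIC-controlled cluster refinement
#'
#' Starting from a converged single-spot fit, repeatedly: cull components
#' that fail [validate_component()] or came back empty (refitting after a
#' cull), pick the component with the largest leading eigenvalue (ties by
#' index), split it with [propose_split()], refit with [fit_hem()], and
#' accept the split only if the BIC drops by more than `bic_drop_threshold`
#' and every refit component passes QC; otherwise the pre-split fit is kept
#' and refinement stops. The procedure uses only image information and is
#' fully deterministic.
#'
#' @param patch Numeric intensity matrix.
#' @param init An initial `hem_fit` (unfitted is fine), e.g. [hem_init()].
#' @param bic_drop_threshold Required BIC decrease to accept a split
#'   (default 10, a conventionally strong evidence gap).
#' @param limits [qc_limits()] used for culling.
#' @param max_components Safety cap on the number of Gaussians (default 6).
#' @param tol,max_iter,cov_floor,fix_background_weight Passed to [fit_hem()].
#' @param debug When `TRUE`, attach a `refine_log` attribute (one entry per
#'   round: BIC before/after, accepted flag, culled components).
#' @return The refined `hem_fit`; may have zero Gaussian components when
#'   everything was culled.
#' @export
refine_event <- function(patch, init, bic_drop_threshold = 10,
                         limits = qc_limits(), max_components = 6L,
                         tol = 1e-8, max_iter = 200L, cov_floor = 0.04,
                         fix_background_weight = NULL, debug = FALSE) {
  refit <- function(f) fit_hem(patch, f, tol = tol, max_iter = max_iter,
                               cov_floor = cov_floor,
                               fix_background_weight = fix_background_weight)
  cull_pass <- function(f) {
    if (length(f$components) == 0) return(list(fit = f, culled = integer()))
    status <- purrr::map_chr(f$components, validate_component,
                             limits = limits)
    empty <- purrr::map_lgl(f$components, ~ isTRUE(.x$empty))
    bad <- which(status != "valid" | empty)
    if (length(bad) > 0) {
      f <- cull_components(f, bad)
      if (length(f$components) > 0) f <- refit(f)
    }
    list(fit = f, culled = bad)
  }
  current <- refit(init)
  rounds <- list()
  repeat {
    cp <- cull_pass(current)
    current <- cp$fit
    if (length(current$components) == 0 ||
        length(current$components) >= max_components) break
    bic_cur <- compute_bic(current, patch)
    lmax <- purrr::map_dbl(current$components,
                           ~ eigen2_closed_form(.x$cov)$values[1])
    target <- which.max(lmax)
    sp <- propose_split(current$components[[target]], cov_floor = cov_floor)
    cand <- current
    children <- purrr::map(1:2, function(i) {
      list(mean = sp$child_means[i, ], cov = sp$child_cov,
           weight = sp$child_weight, empty = FALSE)
    })
    cand$components <- c(cand$components[-target], children)
    cand <- refit(cand)
    bic_new <- compute_bic(cand, patch)
    cand_ok <- all(purrr::map_chr(cand$components, validate_component,
                                  limits = limits) == "valid") &&
      !any(purrr::map_lgl(cand$components, ~ isTRUE(.x$empty)))
    accepted <- cand_ok && (bic_cur - bic_new) > bic_drop_threshold
    rounds[[length(rounds) + 1L]] <- list(
      n_before = length(current$components), target = target,
      bic_before = bic_cur, bic_after = bic_new, accepted = accepted,
      culled = cp$culled)
    if (!accepted) break
    current <- cand
  }
  # final safeguard: never return a component that fails QC
  final <- cull_pass(current)
  current <- final$fit
  if (debug) attr(current, "refine_log") <- rounds
  current
}
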