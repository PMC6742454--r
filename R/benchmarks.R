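#' Cohen's d between two samples
#'
#' Standardized mean difference using the pooled standard deviation.
#'
#' @param x,y Numeric samples.
#' @return Scalar effect size (sign follows `mean(x) - mean(y)`).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

# greedy nearest matching of detected events to true spots within a radius
match_detections <- function(events, truth, radius = 3) {
  matched_truth <- rep(FALSE, nrow(truth))
  matched_event <- rep(FALSE, nrow(events))
  if (nrow(events) > 0 && nrow(truth) > 0) {
    d <- outer(events$row, truth$row, `-`)^2 +
      outer(events$col, truth$col, `-`)^2
    repeat {
      i <- arrayInd(which.min(d), dim(d))
      if (d[i] > radius^2) break
      matched_event[i[1]] <- TRUE
      matched_truth[i[2]] <- TRUE
      d[i[1], ] <- Inf
      d[, i[2]] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  list(truth = matched_truth, event = matched_event)
}

#' Detection operating point on simulated fields
#'
#' Trains the detector on simulated labeled patches, calibrates its threshold
#' by cross-validation, scans `n_images` independent fields, and reports the
#' true positive rate over all true spots and the per-window false positive
#' rate (false events / scored windows).
#'
#' @param n_images Number of evaluation fields (default 20).
#' @param spots_per_image Spots per field.
#' @param snr_range Per-field SNR range (uniform; default 20--100).
#' @param image_size Field size in pixels.
#' @param w Window size.
#' @param match_radius Centroid match radius in pixels.
#' @param seed Integer seed.
#' @return A list: `tpr`, `fpr_per_window`, `threshold`, `cv_tpr`, `cv_fpr`,
#'   `n_truth`, `n_windows`, `n_false_events`.
#' @export
detection_benchmark <- function(n_images = 20L, spots_per_image = 12L,
                                snr_range = c(20, 100),
                                image_size = c(160, 160), w = 15L,
                                match_radius = 3, seed = 1L) {
  train <- simulated_training_set(n_images = 8L, spots_per_image = 12L,
                                  snr_range = snr_range, w = w,
                                  seed = seed, image_size = image_size)
  cal <- calibrate_threshold(train$spots, train$background, folds = 5L)
  det <- train_detector(train$spots, train$background)
  det$threshold <- cal$threshold
  snrs <- withr::with_seed(seed + 11L,
                           stats::runif(n_images, snr_range[1], snr_range[2]))
  n_truth <- 0L; n_tp <- 0L; n_fp <- 0L; n_windows <- 0L
  for (i in seq_len(n_images)) {
    f <- spot_field(spots_per_image, image_size = image_size, snr = snrs[i],
                    seed = seed + 1000L + i)
    map <- scan_image(f$image, det)
    ev <- detect_events(map, cal$threshold)
    m <- match_detections(ev, f$truth, radius = match_radius)
    n_truth <- n_truth + nrow(f$truth)
    n_tp <- n_tp + sum(m$truth)
    n_fp <- n_fp + sum(!m$event)
    n_windows <- n_windows + sum(!is.na(map$values))
  }
  list(tpr = n_tp / n_truth, fpr_per_window = n_fp / n_windows,
       threshold = cal$threshold, cv_tpr = cal$cv_tpr, cv_fpr = cal$cv_fpr,
       n_truth = n_truth, n_windows = n_windows, n_false_events = n_fp)
}

#' Photometry and diameter recovery on the three-tier bead series
#'
#' Simulates the calibration bead series with [bead_series()], fits every
#' bead with the heterogeneous EM (one Gaussian + local uniform background,
#' seeded at the patch centre), and summarises fluorescence linearity against
#' expected photons, adjacent-tier effect sizes, and diameter recovery.
#'
#' @param n_per_level Beads per tier (default 300).
#' @param seed Integer seed.
#' @param base_photons Passed to [bead_series()].
#' @return A list with the per-bead `measurements` tibble, per-tier `summary`
#'   tibble, and scalars `fluorescence_r2` (tier means vs expected photons),
#'   `cohens_d_12`, `cohens_d_23` (adjacent tiers, dim to bright),
#'   `mean_diameter_um`, `diameter_cv_pct_lowest_snr`.
#' @export
bead_benchmark <- function(n_per_level = 300L, seed = 1L,
                           base_photons = 400) {
  beads <- bead_series(n_per_level = n_per_level, seed = seed,
                       base_photons = base_photons)
  fit_one <- function(image) {
    patch <- image$pixels
    ctr <- (dim(patch) + 1) / 2
    fit <- fit_hem(patch, hem_init(patch, ctr,
                                   pixel_size_um = image$pixel_size_um))
    tibble::tibble(
      fluorescence = measure_fluorescence(fit, patch, 1),
      diameter_um = estimate_diameter(fit, 1, image$pixel_size_um),
      converged = fit$converged)
  }
  meas <- dplyr::bind_cols(
    dplyr::select(beads, "tier", "mesf_level", "reference_mesf", "snr",
                  "total_photons", true_diameter_um = "diameter_um"),
    purrr::map_dfr(beads$image, fit_one))
  summ <- dplyr::summarise(
    dplyr::group_by(meas, .data$tier, .data$mesf_level, .data$snr),
    true_photons = .data$total_photons[1],
    mean_fluorescence = mean(.data$fluorescence),
    cv_fluorescence_pct = 100 * stats::sd(.data$fluorescence) /
      mean(.data$fluorescence),
    mean_diameter_um = mean(.data$diameter_um),
    cv_diameter_pct = 100 * stats::sd(.data$diameter_um) /
      mean(.data$diameter_um),
    .groups = "drop")
  fl <- split(meas$fluorescence, meas$tier)
  list(
    measurements = meas, summary = summ,
    fluorescence_r2 = stats::cor(summ$mean_fluorescence,
                                 summ$true_photons)^2,
    cohens_d_12 = cohens_d(fl[[1]], fl[[2]]),
    cohens_d_23 = cohens_d(fl[[2]], fl[[3]]),
    mean_diameter_um = mean(meas$diameter_um),
    diameter_cv_pct_lowest_snr =
      summ$cv_diameter_pct[which.min(summ$snr)])
}

#' Cluster-splitting accuracy on simulated doublets and triplets
#'
#' Draws `n_cases` clusters (k in {2, 3}, separations 4--8 px, brightness
#' ratios 1--3, SNR 10--30), runs the recursive refinement from a single
#' centred Gaussian, and scores a case correct when the refined fit has
#' exactly k components. Also refines `n_isolated` isolated spots and counts
#' spurious splits (more than one component recovered).
#'
#' @param n_cases Number of cluster cases (default 200).
#' @param n_isolated Number of isolated-spot controls (default 50).
#' @param seed Integer seed.
#' @param bic_drop_threshold Passed to [refine_event()].
#' @return A list: `accuracy` (fraction of clusters with the correct count),
#'   `n_cases`, `spurious_splits`, `n_isolated`, and the per-case `cases`
#'   tibble.
#' @export
splitting_benchmark <- function(n_cases = 200L, n_isolated = 50L, seed = 1L,
                                bic_drop_threshold = 10) {
  pars <- withr::with_seed(seed + 29L, tibble::tibble(
    k = sample(c(2L, 3L), n_cases, replace = TRUE),
    separation_px = stats::runif(n_cases, 4, 8),
    ratio = stats::runif(n_cases, 1, 3),
    snr = stats::runif(n_cases, 10, 30),
    case_seed = sample.int(2^30, n_cases)))
  run_case <- function(k, separation_px, ratio, snr, case_seed) {
    photons <- 1000 * c(1, 1 / ratio, 1)[seq_len(k)]
    f <- cluster_field(k, separation_px, photons = photons, snr = snr,
                       seed = case_seed)
    patch <- f$image$pixels
    ctr <- (dim(patch) + 1) / 2
    fit <- refine_event(patch, hem_init(patch, ctr),
                        bic_drop_threshold = bic_drop_threshold)
    length(fit$components)
  }
  pars$n_found <- purrr::pmap_int(
    pars[, c("k", "separation_px", "ratio", "snr", "case_seed")], run_case)
  pars$correct <- pars$n_found == pars$k
  iso_pars <- withr::with_seed(seed + 31L, tibble::tibble(
    dr = stats::runif(n_isolated, -0.5, 0.5),
    dc = stats::runif(n_isolated, -0.5, 0.5),
    s = sample.int(2^30, n_isolated)))
  iso_found <- vapply(seq_len(n_isolated), function(i) {
    tr <- spot_truth(13 + iso_pars$dr[i], 13 + iso_pars$dc[i], 1000,
                     7.5 / (3 * fwhm_factor()))
    amp <- 1000 * centre_pixel_mass(tr$sigma_major_px[1])
    sp <- field_spec(c(25, 25), background_level = (amp / 20)^2,
                     spots = tr, seed = iso_pars$s[i])
    f <- render_field(sp)
    fit <- refine_event(f$image$pixels, hem_init(f$image$pixels, c(13, 13)),
                        bic_drop_threshold = bic_drop_threshold)
    length(fit$components)
  }, integer(1))
  list(accuracy = mean(pars$correct), n_cases = n_cases,
       spurious_splits = sum(iso_found > 1), n_isolated = n_isolated,
       isolated_found = iso_found, cases = pars)
}
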