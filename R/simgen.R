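#' Ground-truth description of one simulated spot
#'
#' Builds the truth table used by the simulator: one row per spot with its
#' sub-pixel centre, expected integrated signal in photons, Gaussian spread
#' along the two principal axes, orientation of the major axis (radians,
#' measured from the +row axis towards +col), and the physical diameter the
#' spread corresponds to at the given pixel size (FWHM convention,
#' `diameter = pixel_size * 2 * sqrt(2 * log(2)) * sqrt(sigma_major * sigma_minor)`).
#'
#' @param row,col Sub-pixel centre positions (1-based pixel-centre coords).
#' @param total_photons Expected integrated signal per spot (counts, >= 0).
#' @param sigma_major_px,sigma_minor_px Gaussian spread along the principal
#'   axes, in pixels (> 0). `sigma_minor_px` defaults to `sigma_major_px`.
#' @param orientation_rad Major-axis orientation in radians.
#' @param pixel_size_um Pixel size used to fill `diameter_um`.
#' @return A tibble with columns `spot_id`, `row`, `col`, `total_photons`,
#'   `sigma_major_px`, `sigma_minor_px`, `orientation_rad`, `diameter_um`.
#' @export
spot_truth <- function(row, col, total_photons,
                       sigma_major_px, sigma_minor_px = sigma_major_px,
                       orientation_rad = 0, pixel_size_um = 3) {
  n <- length(row)
  tb <- tibble::tibble(
    spot_id = seq_len(n),
    row = as.numeric(row),
    col = as.numeric(col),
    total_photons = rep_len(as.numeric(total_photons), n),
    sigma_major_px = rep_len(as.numeric(sigma_major_px), n),
    sigma_minor_px = rep_len(as.numeric(sigma_minor_px), n),
    orientation_rad = rep_len(as.numeric(orientation_rad), n)
  )
  if (any(tb$total_photons < 0)) abort("`total_photons` must be >= 0")
  if (any(tb$sigma_major_px <= 0) || any(tb$sigma_minor_px <= 0)) {
    abort("sigma components must be > 0")
  }
  tb$diameter_um <- pixel_size_um * fwhm_factor() *
    sqrt(tb$sigma_major_px * tb$sigma_minor_px)
  tb
}

#' Specification of a simulated field of view
#'
#' @param image_size `(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size in micrometres (default 3, the
#'   cell-astronomy regime where a 7.5 um bead spans 3-4 pixels).
#' @param background_level Mean background counts per pixel (>= 0).
#' @param noise `"poisson"` (default; counts are Poisson draws around the
#'   expected photon image), `"none"`, or `list(type = "gaussian", sd = s)`.
#' @param spots A [spot_truth()] tibble (may have zero rows).
#' @param seed Integer seed; the same spec and seed give a bit-identical image.
#' @return A `field_spec` list.
#' @export
field_spec <- function(image_size = c(128, 128), pixel_size_um = 3,
                       background_level = 5, noise = "poisson",
                       spots = spot_truth(numeric(), numeric(), numeric(),
                                          numeric()),
                       seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 1))
  if (background_level < 0) abort("`background_level` must be >= 0")
  if (is.character(noise)) noise <- list(type = noise)
  if (!noise$type %in% c("poisson", "gaussian", "none")) {
    abort("noise must be 'poisson', 'gaussian' or 'none'")
  }
  if (noise$type == "gaussian" && is.null(noise$sd)) {
    abort("gaussian noise needs `sd`")
  }
  structure(
    list(image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
         background_level = background_level, noise = noise, spots = spots,
         seed = as.integer(seed)),
    class = "field_spec"
  )
}

# expected photon image of one spot, integrated over pixel footprints.
# axis-aligned / isotropic spots use exact error-function (pnorm) differences;
# rotated anisotropic spots fall back to 7x7 sub-pixel quadrature.
spot_expected_counts <- function(nr, nc, row, col, photons,
                                 smaj, smin, ang) {
  out <- matrix(0, nr, nc)
  reach <- ceiling(6 * smaj + 1)
  r0 <- max(1L, floor(row - reach)); r1 <- min(nr, ceiling(row + reach))
  c0 <- max(1L, floor(col - reach)); c1 <- min(nc, ceiling(col + reach))
  if (r0 > r1 || c0 > c1) return(out)
  rs <- r0:r1; cs <- c0:c1
  iso <- abs(smaj - smin) < 1e-12
  axis_aligned <- iso || abs(sin(2 * ang)) < 1e-12
  if (axis_aligned) {
    # sigma along rows is the major axis when ang ~ 0, minor when ang ~ pi/2
    swap <- !iso && abs(cos(ang)) < abs(sin(ang))
    sr <- if (swap) smin else smaj
    sc <- if (swap) smaj else smin
    pr <- stats::pnorm((rs + 0.5 - row) / sr) -
      stats::pnorm((rs - 0.5 - row) / sr)
    pc <- stats::pnorm((cs + 0.5 - col) / sc) -
      stats::pnorm((cs - 0.5 - col) / sc)
    out[rs, cs] <- photons * outer(pr, pc)
  } else {
    s <- 7L
    off <- (seq_len(s) - (s + 1) / 2) / s
    ca <- cos(ang); sa <- sin(ang)
    acc <- matrix(0, length(rs), length(cs))
    for (dr in off) for (dc in off) {
      x1 <- outer(rs + dr - row, rep(1, length(cs)))
      x2 <- outer(rep(1, length(rs)), cs + dc - col)
      u <- (ca * x1 + sa * x2) / smaj
      v <- (-sa * x1 + ca * x2) / smin
      acc <- acc + exp(-0.5 * (u^2 + v^2))
    }
    acc <- acc / (s^2) / (2 * pi * smaj * smin)
    out[rs, cs] <- photons * acc
  }
  out
}

#' Render a simulated field of view with ground truth
#'
#' The expected image is `background_level` plus, for every spot, a bivariate
#' Gaussian integrated over each pixel footprint (so totals are conserved even
#' though spots span only a few pixels); the configured noise model is then
#' applied. Rendering is deterministic given the spec (which includes the
#' seed).
#'
#' @param spec A [field_spec()].
#' @return A list with elements `image` ([raster_image()]) and `truth` (the
#'   spec's [spot_truth()] tibble, unchanged).
#' @export
#' @examples
#' sp <- field_spec(c(48, 48), spots = spot_truth(24, 24, 8000, 1.1), seed = 2)
#' f <- render_field(sp)
#' sum(f$image$pixels) / (48 * 48)
render_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  tr <- spec$spots
  if (nrow(tr) > 0 &&
      (any(tr$row < 1) || any(tr$row > nr) ||
       any(tr$col < 1) || any(tr$col > nc))) {
    abort("spot centre outside the image; rejecting field spec")
  }
  expected <- matrix(spec$background_level, nr, nc)
  if (nrow(tr) > 0) {
    for (i in seq_len(nrow(tr))) {
      expected <- expected + spot_expected_counts(
        nr, nc, tr$row[i], tr$col[i], tr$total_photons[i],
        tr$sigma_major_px[i], tr$sigma_minor_px[i], tr$orientation_rad[i])
    }
  }
  px <- withr::with_seed(spec$seed, switch(
    spec$noise$type,
    none = expected,
    poisson = matrix(stats::rpois(length(expected), expected), nr, nc),
    gaussian = pmax(0, expected +
                      matrix(stats::rnorm(length(expected),
                                          sd = spec$noise$sd), nr, nc))
  ))
  list(
    image = raster_image(px, pixel_size_um = spec$pixel_size_um,
                         source_id = sprintf("sim-%d", spec$seed)),
    truth = tr
  )
}

# expected mass landing in a spot's centre pixel, averaged over uniform
# sub-pixel offsets: calibrates amplitude <-> SNR for an isotropic sigma
centre_pixel_mass <- function(sigma_px, n_quad = 201L) {
  d <- seq(-0.5, 0.5, length.out = n_quad)
  g <- stats::pnorm((0.5 - d) / sigma_px) - stats::pnorm((-0.5 - d) / sigma_px)
  mean(g)^2
}

#' Reference values of the three-level MESF bead calibration series
#'
#' Manufacturer-reported MESF intensities (with their coefficients of
#' variation) and the image signal-to-noise ratio tier at which each bead
#' level was imaged, used by [bead_series()] and by the linearity worked
#' example. Bead diameter is 7.5 um for every level.
#'
#' @return A tibble with one row per MESF level (2, 3, 4), dimmest first.
#' @export
mesf_bead_reference <- function() {
  tibble::tibble(
    mesf_level = c(2L, 3L, 4L),
    reference_mesf = c(18882, 138201, 624803),
    reference_cv_pct = c(2.07, 1.24, 0.42),
    snr = c(7.8, 23.5, 102.0)
  )
}

#' Simulate the three-tier calibration bead series
#'
#' Generates `n_per_level` beads for each of the three MESF levels as small
#' single-bead images. All beads have true diameter 7.5 um; expected total
#' photons are proportional to the reference MESF intensities; and each
#' tier's background level is solved (each level is its own sample, imaged
#' separately) so that the expected centre-pixel SNR --- (peak signal above
#' background mean) / background sd, Poisson background --- matches the
#' tier's target.
#'
#' @param n_per_level Beads per MESF level (>= 1).
#' @param seed Integer seed.
#' @param base_photons Expected total photons of the dimmest (MESF level 2)
#'   tier; brighter tiers scale by the MESF ratios.
#' @param pixel_size_um Pixel size (um); default 3.
#' @param patch_size Side of each single-bead image (odd, default 25).
#' @return A tibble with one row per bead: tier metadata, the ground truth
#'   columns of [spot_truth()], the tier background level, and a list-column
#'   `image` of [raster_image()] objects.
#' @export
bead_series <- function(n_per_level = 300L, seed = 1L, base_photons = 400,
                        pixel_size_um = 3, patch_size = 25L) {
  stopifnot(n_per_level >= 1, patch_size %% 2 == 1)
  ref <- mesf_bead_reference()
  sigma <- 7.5 / (pixel_size_um * fwhm_factor())
  photons <- base_photons * ref$reference_mesf / ref$reference_mesf[1]
  amp <- photons * centre_pixel_mass(sigma)
  background <- (amp / ref$snr)^2
  ctr <- (patch_size + 1) / 2
  withr::with_seed(seed, {
    rows <- purrr::pmap(
      list(tier = seq_len(3), photons = photons, bg = background),
      function(tier, photons, bg) {
        offs_r <- stats::runif(n_per_level, -0.5, 0.5)
        offs_c <- stats::runif(n_per_level, -0.5, 0.5)
        seeds <- sample.int(.Machine$integer.max, n_per_level)
        beads <- purrr::map(seq_len(n_per_level), function(i) {
          tr <- spot_truth(ctr + offs_r[i], ctr + offs_c[i], photons, sigma,
                           pixel_size_um = pixel_size_um)
          sp <- field_spec(c(patch_size, patch_size),
                           pixel_size_um = pixel_size_um,
                           background_level = bg, noise = "poisson",
                           spots = tr, seed = seeds[i])
          render_field(sp)
        })
        tb <- purrr::map_dfr(beads, "truth")
        tb$spot_id <- seq_len(n_per_level)
        tb$tier <- tier
        tb$background_level <- bg
        tb$image <- purrr::map(beads, "image")
        tb
      })
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(
    out, dplyr::mutate(ref, tier = dplyr::row_number()), by = "tier")
  dplyr::relocate(out, "tier", "mesf_level", "reference_mesf", "snr")
}

#' Measure the signal-to-noise ratio of a known spot
#'
#' SNR is defined as the spot's centre-pixel signal above the background
#' mean, divided by the background standard deviation; background statistics
#' are taken from pixels farther than `exclude_sigma` spreads from any listed
#' spot centre.
#'
#' @param image A [raster_image()].
#' @param truth A [spot_truth()] tibble for the image.
#' @param exclude_sigma Exclusion radius around each spot, in units of its
#'   major-axis sigma (default 5).
#' @return A numeric vector of per-spot SNR values.
#' @export
measure_spot_snr <- function(image, truth, exclude_sigma = 5) {
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  rr <- row(px); cc <- col(px)
  bg_mask <- matrix(TRUE, nr, nc)
  for (i in seq_len(nrow(truth))) {
    d2 <- (rr - truth$row[i])^2 + (cc - truth$col[i])^2
    bg_mask <- bg_mask & d2 > (exclude_sigma * truth$sigma_major_px[i])^2
  }
  if (sum(bg_mask) < 16) abort("too few background pixels to estimate SNR")
  mu <- mean(px[bg_mask]); s <- stats::sd(px[bg_mask])
  peak <- px[cbind(round(truth$row), round(truth$col))]
  (peak - mu) / s
}

#' Simulate a small cluster of two or three cells
#'
#' Places `k` spots at exact pairwise centre distance `separation_px`
#' (doublets collinear, triplets an equilateral triangle) at the image
#' centre, with optional heterogeneous brightness and size. The background
#' level is solved from `snr` for the brightest spot (Poisson background).
#'
#' @param k Number of cells, 2 or 3.
#' @param separation_px Pairwise centre distance in pixels (> 0).
#' @param photons Expected total photons per spot; scalar or length `k`.
#' @param sigma_px Isotropic spread per spot (pixels); scalar or length `k`.
#' @param snr Target centre-pixel SNR of the brightest spot.
#' @param image_size `(rows, cols)`; default 41 x 41.
#' @param pixel_size_um Pixel size (um).
#' @param angle Orientation of the cluster axis in radians; drawn uniformly
#'   from the seed when `NULL`.
#' @param noise Noise model as in [field_spec()].
#' @param seed Integer seed.
#' @return A list with `image` and `truth`, as [render_field()].
#' @export
cluster_field <- function(k, separation_px, photons = 1000,
                          sigma_px = 7.5 / (3 * fwhm_factor()), snr = 20,
                          image_size = c(41, 41), pixel_size_um = 3,
                          angle = NULL, noise = "poisson", seed = 1L) {
  if (!k %in% c(2L, 3L)) abort("`k` must be 2 or 3")
  if (separation_px <= 0) abort("`separation_px` must be > 0")
  photons <- rep_len(photons, k)
  sigma_px <- rep_len(sigma_px, k)
  ctr <- (image_size + 1) / 2
  ang <- if (is.null(angle)) {
    withr::with_seed(seed + 1L, stats::runif(1, 0, pi))
  } else angle
  if (k == 2L) {
    t_ang <- ang + c(0, pi)
    radius <- separation_px / 2
  } else {
    t_ang <- ang + c(0, 2 * pi / 3, 4 * pi / 3)
    radius <- separation_px / sqrt(3)
  }
  rows <- ctr[1] + radius * cos(t_ang)
  cols <- ctr[2] + radius * sin(t_ang)
  amp <- photons * vapply(sigma_px, centre_pixel_mass, numeric(1))
  background <- (max(amp) / snr)^2
  tr <- spot_truth(rows, cols, photons, sigma_px,
                   pixel_size_um = pixel_size_um)
  sp <- field_spec(image_size, pixel_size_um = pixel_size_um,
                   background_level = background, noise = noise,
                   spots = tr, seed = seed)
  render_field(sp)
}

#' Scatter a set of identical well-separated spots across a field
#'
#' Convenience generator for detection and end-to-end experiments: spot
#' centres are drawn uniformly (with a margin) under a minimum pairwise
#' distance constraint, at a background level solved from `snr`.
#'
#' @param n_spots Number of spots.
#' @param image_size `(rows, cols)` pixels.
#' @param snr Target centre-pixel SNR.
#' @param photons Expected total photons per spot.
#' @param sigma_px Isotropic spread (pixels).
#' @param min_separation_px Minimum pairwise centre distance.
#' @param margin_px Margin kept free of spot centres at the borders.
#' @param pixel_size_um Pixel size (um).
#' @param noise Noise model as in [field_spec()].
#' @param seed Integer seed.
#' @return A list with `image` and `truth`, as [render_field()].
#' @export
spot_field <- function(n_spots, image_size = c(160, 160), snr = 20,
                       photons = 1000, sigma_px = 7.5 / (3 * fwhm_factor()),
                       min_separation_px = 12, margin_px = 10,
                       pixel_size_um = 3, noise = "poisson", seed = 1L) {
  amp <- photons * centre_pixel_mass(sigma_px)
  background <- (amp / snr)^2
  pos <- withr::with_seed(seed + 7L, {
    acc <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(acc) < n_spots && tries < 20000L) {
      cand <- c(stats::runif(1, 1 + margin_px, image_size[1] - margin_px),
                stats::runif(1, 1 + margin_px, image_size[2] - margin_px))
      ok <- nrow(acc) == 0 ||
        min(sqrt((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2)) >=
          min_separation_px
      if (ok) acc <- rbind(acc, cand)
      tries <- tries + 1L
    }
    if (nrow(acc) < n_spots) abort("could not place spots; lower the density")
    acc
  })
  tr <- spot_truth(pos[, 1], pos[, 2], photons, sigma_px,
                   pixel_size_um = pixel_size_um)
  sp <- field_spec(image_size, pixel_size_um = pixel_size_um,
                   background_level = background, noise = noise,
                   spots = tr, seed = seed)
  render_field(sp)
}

#' Write a ground-truth table as CSV
#'
#' @param truth A [spot_truth()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(
    truth[, c("spot_id", "row", "col", "total_photons", "sigma_major_px",
              "sigma_minor_px", "orientation_rad", "diameter_um")],
    path, row.names = FALSE)
  invisible(path)
}
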