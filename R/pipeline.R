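#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full pipeline. Defaults encode the
#' imaging regime the method targets: 3 um/px, 15 px windows, 10 um expected
#' cell diameter.
#'
#' @param pixel_size_um Physical pixel size (um, default 3).
#' @param window Detector window size (odd, default 15).
#' @param threshold Detection posterior cut; `NULL` uses the detector's
#'   calibrated threshold.
#' @param pad Patch pad around event bounding boxes; `NULL` uses the window
#'   half-width.
#' @param tol,max_iter EM convergence settings (see [fit_hem()]).
#' @param init_diameter_um Initial Gaussian scale (see [hem_init()]).
#' @param cov_floor Covariance eigenvalue floor (px^2).
#' @param offset Camera offset subtracted (and clamped at 0) before fitting.
#' @param background_scope `"local"` (uniform fitted per patch) or
#'   `"global"` (one shared background fraction estimated in a first pass,
#'   then held fixed in a refit).
#' @param bic_drop_threshold BIC gap required to accept a split.
#' @param max_components Cap on Gaussians per event.
#' @param qc [qc_limits()]; `NULL` builds defaults at `pixel_size_um`.
#' @return A `hem_config` list.
#' @export
hem_config <- function(pixel_size_um = 3, window = 15L, threshold = NULL,
                       pad = NULL, tol = 1e-8, max_iter = 200L,
                       init_diameter_um = 10, cov_floor = 0.04, offset = 0,
                       background_scope = c("local", "global"),
                       bic_drop_threshold = 10, max_components = 6L,
                       qc = NULL) {
  background_scope <- match.arg(background_scope)
  structure(
    list(pixel_size_um = pixel_size_um, window = as.integer(window),
         threshold = threshold, pad = pad, tol = tol,
         max_iter = as.integer(max_iter),
         init_diameter_um = init_diameter_um, cov_floor = cov_floor,
         offset = offset, background_scope = background_scope,
         bic_drop_threshold = bic_drop_threshold,
         max_components = as.integer(max_components),
         qc = qc %||% qc_limits(pixel_size_um = pixel_size_um)),
    class = "hem_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their [hem_config()]
#' defaults. QC limits may be given under a `qc:` mapping.
#'
#' @param path YAML file path.
#' @return A `hem_config`.
#' @export
read_hem_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(hem_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  }
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_limits, raw$qc)
  do.call(hem_config, raw)
}

empty_event_table <- function() {
  tb <- tibble::tibble(
    image_id = character(), event_id = integer(), component_id = integer(),
    row = numeric(), col = numeric(), fluorescence = numeric(),
    sigma_eff_px = numeric(), diameter_um = numeric(),
    background_weight = numeric(), n_iterations = integer(),
    converged = logical(), qc_status = character(), edge = logical(),
    rmin = integer(), rmax = integer(), cmin = integer(), cmax = integer(),
    peak_posterior = numeric())
  class(tb) <- c("hem_event_table", class(tb))
  tb
}

measure_event <- function(patch, evt, config, fix_bg = NULL) {
  ctr <- c(evt$row - evt$rmin + 1, evt$col - evt$cmin + 1)
  init <- hem_init(patch, ctr, pixel_size_um = config$pixel_size_um,
                   init_diameter_um = config$init_diameter_um)
  fit <- refine_event(patch, init,
                      bic_drop_threshold = config$bic_drop_threshold,
                      limits = config$qc,
                      max_components = config$max_components,
                      tol = config$tol, max_iter = config$max_iter,
                      cov_floor = config$cov_floor,
                      fix_background_weight = fix_bg)
  n <- length(fit$components)
  base <- tibble::tibble(
    event_id = evt$event_id, edge = evt$edge,
    rmin = evt$rmin, rmax = evt$rmax, cmin = evt$cmin, cmax = evt$cmax,
    peak_posterior = evt$peak_posterior)
  if (n == 0) {
    out <- dplyr::mutate(
      base, component_id = 0L, row = evt$row, col = evt$col,
      fluorescence = NA_real_, sigma_eff_px = NA_real_,
      diameter_um = NA_real_, background_weight = fit$background$weight,
      n_iterations = fit$n_iterations, converged = fit$converged,
      qc_status = "rejected(no_component)")
    return(list(rows = out, fit = fit))
  }
  fl <- measure_fluorescence(fit, patch)
  rows <- purrr::map_dfr(seq_len(n), function(c) {
    g <- fit$components[[c]]
    dplyr::mutate(
      base, component_id = c,
      row = g$mean[1] + evt$rmin - 1, col = g$mean[2] + evt$cmin - 1,
      fluorescence = fl[c], sigma_eff_px = det(g$cov)^0.25,
      diameter_um = estimate_diameter(fit, c, config$pixel_size_um),
      background_weight = fit$background$weight,
      n_iterations = fit$n_iterations, converged = fit$converged,
      qc_status = validate_component(g, config$qc))
  })
  list(rows = rows, fit = fit)
}

#' Run the full quantification pipeline on one image
#'
#' Detection, per-event heterogeneous EM fitting, recursive cluster
#' refinement, QC, and measurement: image in, event table out. Events are
#' processed independently, so the output does not depend on processing
#' order; the whole pipeline is deterministic for a fixed image and
#' configuration. QC-rejected components are kept in the table with their
#' `qc_status` set, never silently dropped; per-event fitting failures are
#' flagged `"failed"` and the run continues.
#'
#' @param image A [raster_image()].
#' @param detector A trained (and normally calibrated) [train_detector()]
#'   model.
#' @param config A [hem_config()].
#' @return A `hem_event_table` tibble, one row per fitted Gaussian component
#'   (plus flagged rows for empty or failed events), with a `run_manifest`
#'   attribute (stage counts).
#' @export
run_pipeline <- function(image, detector, config = hem_config()) {
  stopifnot(inherits(image, "raster_image"),
            inherits(detector, "lda_detector"))
  thr <- config$threshold %||% detector$threshold
  if (is.na(thr %||% NA_real_)) {
    abort("no detection threshold: calibrate the detector or set one in the config")
  }
  px <- pmax(image$pixels - config$offset, 0)
  map <- scan_image(px, detector)
  pad <- config$pad %||% map$valid_margin
  events <- detect_events(map, thr, pad = pad)
  out <- empty_event_table()
  n_failed <- 0L
  fix_bg <- NULL
  passes <- if (config$background_scope == "global") 2L else 1L
  for (pass in seq_len(passes)) {
    rows <- vector("list", nrow(events))
    bg_w <- numeric(0); bg_mass <- numeric(0)
    n_failed <- 0L
    for (i in seq_len(nrow(events))) {
      evt <- events[i, ]
      patch <- px[evt$rmin:evt$rmax, evt$cmin:evt$cmax]
      res <- tryCatch(measure_event(patch, evt, config, fix_bg = fix_bg),
                      error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        rows[[i]] <- tibble::tibble(
          event_id = evt$event_id, component_id = 0L,
          row = evt$row, col = evt$col, fluorescence = NA_real_,
          sigma_eff_px = NA_real_, diameter_um = NA_real_,
          background_weight = NA_real_, n_iterations = NA_integer_,
          converged = FALSE, qc_status = "failed", edge = evt$edge,
          rmin = evt$rmin, rmax = evt$rmax, cmin = evt$cmin,
          cmax = evt$cmax, peak_posterior = evt$peak_posterior)
      } else {
        rows[[i]] <- res$rows
        bg_w <- c(bg_w, res$fit$background$weight)
        bg_mass <- c(bg_mass, sum(patch))
      }
    }
    if (pass == 1L && passes == 2L && length(bg_w) > 0) {
      fix_bg <- sum(bg_w * bg_mass) / sum(bg_mass)
    }
  }
  tb <- dplyr::bind_rows(rows)
  if (nrow(tb) > 0) {
    tb$image_id <- image$source_id
    tb <- dplyr::relocate(tb, "image_id")
    tb <- dplyr::arrange(tb, .data$event_id, .data$component_id)
  } else {
    tb <- empty_event_table()
  }
  class(tb) <- c("hem_event_table", setdiff(class(tb), "hem_event_table"))
  ev_status <- if (nrow(tb) > 0) {
    dplyr::summarise(
      dplyr::group_by(tb, .data$event_id),
      any_valid = any(.data$qc_status == "valid"),
      failed = all(.data$qc_status == "failed"))
  } else tibble::tibble(any_valid = logical(), failed = logical())
  attr(tb, "run_manifest") <- list(
    image_id = image$source_id,
    windows_scored = sum(!is.na(map$values)),
    threshold = thr,
    detected_events = nrow(events),
    valid_events = sum(ev_status$any_valid),
    rejected_events = sum(!ev_status$any_valid & !ev_status$failed),
    failed_events = sum(ev_status$failed),
    valid_rows = sum(tb$qc_status == "valid"),
    background_scope = config$background_scope,
    global_background_weight = fix_bg)
  tb
}

#' Squared linearity of recovered fluorescence against a reference series
#'
#' Squared Pearson correlation between exactly three tier-mean fluorescence
#' values and their three reference intensities, rounded to 4 decimals. With
#' the reference values of [mesf_bead_reference()] and the recovered means of
#' the bead worked example this is the calibration linearity figure of merit.
#'
#' @param mean_fluorescences Three tier-mean recovered fluorescences.
#' @param reference_mesf Three reference intensities.
#' @return Squared Pearson correlation, rounded to 4 decimals.
#' @export
#' @examples
#' bead_linearity_check(c(372.3, 1197.4, 4851.3), c(18882, 138201, 624803))
bead_linearity_check <- function(mean_fluorescences, reference_mesf) {
  if (length(mean_fluorescences) != 3 || length(reference_mesf) != 3) {
    abort("exactly three paired values are required")
  }
  if (stats::sd(mean_fluorescences) == 0 || stats::sd(reference_mesf) == 0) {
    abort("zero variance in one of the vectors")
  }
  round(stats::cor(mean_fluorescences, reference_mesf)^2, 4)
}

#' Write / read an event table as CSV
#'
#' Numeric fields are serialized with 17 significant digits, so a
#' write-then-read round trip is lossless.
#'
#' @param table A `hem_event_table` (or compatible tibble).
#' @param path CSV path.
#' @return `path` (write) or the restored `hem_event_table` (read).
#' @export
write_event_table <- function(table, path) {
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) "" else sprintf("%.17g", v)
      }, character(1))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  proto <- empty_event_table()
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = "")
  if (nrow(df) == 0 && ncol(df) == 0) return(proto)
  tb <- tibble::as_tibble(df)
  for (nm in names(proto)) {
    if (nm %in% names(tb)) {
      tb[[nm]] <- switch(class(proto[[nm]])[1],
                         integer = as.integer(tb[[nm]]),
                         numeric = as.numeric(tb[[nm]]),
                         logical = as.logical(tb[[nm]]),
                         character = as.character(tb[[nm]]))
    }
  }
  class(tb) <- c("hem_event_table", class(tibble::tibble()))
  tb
}

#' Cytometry-style scatter plot of an event table
#'
#' Diameter against fluorescence, one point per valid component --- the same
#' view a flow cytometer's forward-scatter-vs-fluorescence plot gives.
#' `autoplot()` returns the ggplot; [plot_scatter()] writes it to a file.
#'
#' @param object A `hem_event_table`.
#' @param log_fluorescence Log-scale the fluorescence axis (default `TRUE`).
#' @param exclude_edge Drop border-clipped events (default `TRUE`; their
#'   truncated tails bias fluorescence low).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hem_event_table <- function(object, log_fluorescence = TRUE,
                                     exclude_edge = TRUE, ...) {
  df <- dplyr::filter(object, .data$qc_status == "valid")
  if (exclude_edge) df <- dplyr::filter(df, !.data$edge)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter_um,
                                        y = .data$fluorescence)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "diameter (µm)", y = "fluorescence (counts)") +
    ggplot2::theme_minimal()
  if (log_fluorescence) p <- p + ggplot2::scale_y_log10()
  p
}

#' @param table A `hem_event_table` with at least one valid row.
#' @param out_path Output file; format by extension (pdf, png, or svg).
#' @param width,height Device size in inches.
#' @rdname autoplot.hem_event_table
#' @export
plot_scatter <- function(table, out_path, log_fluorescence = TRUE,
                         exclude_edge = TRUE, width = 5, height = 4) {
  n_valid <- sum(table$qc_status == "valid" &
                   (!exclude_edge | !table$edge))
  if (n_valid < 1) {
    warn("no valid rows to plot; no file written")
    return(invisible(NULL))
  }
  p <- autoplot.hem_event_table(table, log_fluorescence = log_fluorescence,
                                exclude_edge = exclude_edge)
  ggplot2::ggsave(out_path, p, width = width, height = height)
  invisible(out_path)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a heterogeneous mixture fit
#'
#' One row per Gaussian component plus one for the uniform background.
#'
#' @param x A `hem_fit`.
#' @param pixel_size_um Pixel size used for `diameter_um`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `type`, `row`, `col`,
#'   `weight`, `sigma_eff_px`, `diameter_um`.
#' @export
tidy.hem_fit <- function(x, pixel_size_um = 3, ...) {
  n <- length(x$components)
  gs <- purrr::map_dfr(seq_len(n), function(c) {
    g <- x$components[[c]]
    tibble::tibble(component = c, type = "gaussian",
                   row = g$mean[1], col = g$mean[2], weight = g$weight,
                   sigma_eff_px = det(g$cov)^0.25,
                   diameter_um = pixel_size_um * fwhm_factor() *
                     det(g$cov)^0.25)
  })
  dplyr::bind_rows(gs, tibble::tibble(
    component = n + 1L, type = "background", row = NA_real_, col = NA_real_,
    weight = x$background$weight, sigma_eff_px = NA_real_,
    diameter_um = NA_real_))
}

#' One-line summary of a heterogeneous mixture fit
#'
#' @param x A `hem_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_components`, `background_weight`, `logLik`,
#'   `n_iterations`, `converged`.
#' @export
glance.hem_fit <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$components),
    background_weight = x$background$weight,
    logLik = if (length(x$loglik_trace) > 0) {
      x$loglik_trace[length(x$loglik_trace)]
    } else NA_real_,
    n_iterations = x$n_iterations,
    converged = x$converged)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
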