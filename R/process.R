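#' Detect the contact point and convert a cycle to force vs indentation
#'
#' Turns a raw force-distance cycle in instrument coordinates into
#' baseline-corrected force versus indentation depth. The procedure is fully
#' automatic:
#'
#' 1. A linear baseline is fitted to the far (non-contact) 30% of the
#'    approach piezo range and subtracted from both segments.
#' 2. The initial contact estimate is the first approach sample whose
#'    corrected force crosses `max(rms_multiplier x baseline RMS,
#'    contact_threshold)`.
#' 3. The estimate is refined by back-extrapolating the Sneddon law: over
#'    the low-force window, `sqrt(F)` is linear in indentation, and the
#'    intercept of that line locates the true contact point.
#'
#' Indentation is piezo travel minus cantilever deflection,
#' `delta = (z0 - z) - (F - baseline)/k`, so the total indentation reached
#' at the 2 nN setpoint depends on the sample stiffness. The approach is
#' clipped at contact (`delta >= 0`); the retract keeps its
#' negative-indentation tail, where any adhesion dip lives.
#'
#' Failures are flagged, not raised: `no_contact` when the threshold is
#' never crossed, `noisy_baseline` when the baseline residual RMS exceeds
#' tolerance, `low_max_force` when the approach does not reach 80% of the
#' setpoint. Flagged curves are excluded from aggregation downstream.
#'
#' @param curve An `fd_curve` (see [generate_curve()], [read_fd_curve()]).
#' @param cfg A [processing_config()].
#'
#' @return An `fd_processed` object: list with `approach` and `retract`
#'   tibbles (`indentation`, `force`), `contact_height`, `baseline`
#'   (intercept, slope, rms), `max_indentation`, `flags` (character vector)
#'   and the original `metadata`.
#' @export
#' @examples
#' p <- detect_contact_point(generate_curve(curve_spec(seed = 1)))
#' p$contact_height
#' p$flags
detect_contact_point <- function(curve, cfg = processing_config()) {
  validate_fd_curve(curve)
  stopifnot(inherits(cfg, "processing_config"))
  k <- curve$metadata$spring_constant
  app <- dplyr::arrange(curve$approach, dplyr::desc(.data$piezo_height))
  flags <- character(0)

  z_range <- diff(range(app$piezo_height))
  z_cut <- max(app$piezo_height) - cfg$baseline_fraction * z_range
  base_idx <- app$piezo_height >= z_cut
  base_fit <- lm(force ~ piezo_height, data = app[base_idx, ])
  base_at <- function(z) coef(base_fit)[1] + coef(base_fit)[2] * z
  rms <- sqrt(mean(stats::residuals(base_fit)^2))
  if (rms > cfg$baseline_rms_tol) flags <- c(flags, "noisy_baseline")

  f_corr <- app$force - base_at(app$piezo_height)
  threshold <- max(cfg$rms_multiplier * rms, cfg$contact_threshold)
  cross <- which(f_corr >= threshold)
  # demand sustained contact: crossing followed by another above-threshold
  # sample, so a single noise spike cannot fake a contact point
  cross <- cross[cross < nrow(app) & c(f_corr[pmin(cross + 1L, nrow(app))] >=
                                         threshold)]
  if (length(cross) == 0) {
    flags <- c(flags, "no_contact")
    return(new_fd_processed(curve, NA_real_, base_fit, rms, flags, cfg))
  }
  z0 <- app$piezo_height[cross[1]]

  # Sneddon back-extrapolation: sqrt(F) ~ indentation is linear; shift z0 so
  # the regression line passes through the origin
  d <- (z0 - app$piezo_height) - f_corr / k
  in_win <- f_corr >= threshold & f_corr <= cfg$sneddon_window[2] & d > 0
  if (sum(in_win) >= 5) {
    fit <- lm(sqrt(f_corr[in_win]) ~ d[in_win])
    a <- coef(fit)[2]
    b <- coef(fit)[1]
    if (is.finite(a) && a > 0) {
      shift <- b / a
      if (abs(shift) < 5e-7) z0 <- z0 + shift
    }
  }

  if (max(f_corr) < cfg$usable_fraction * curve$metadata$setpoint_force)
    flags <- c(flags, "low_max_force")

  new_fd_processed(curve, z0, base_fit, rms, flags, cfg)
}

new_fd_processed <- function(curve, z0, base_fit, rms, flags, cfg) {
  k <- curve$metadata$spring_constant
  base_at <- function(z) coef(base_fit)[1] + coef(base_fit)[2] * z
  mk <- function(seg, clip) {
    f <- seg$force - base_at(seg$piezo_height)
    if (is.na(z0)) {
      out <- tibble::tibble(indentation = rep(NA_real_, nrow(seg)), force = f)
      return(out)
    }
    delta <- (z0 - seg$piezo_height) - f / k
    out <- tibble::tibble(indentation = delta, force = f)
    if (clip) out <- dplyr::filter(out, .data$indentation >= 0)
    dplyr::arrange(out, .data$indentation)
  }
  approach <- mk(dplyr::arrange(curve$approach,
                                dplyr::desc(.data$piezo_height)), clip = TRUE)
  retract <- mk(curve$retract, clip = FALSE)
  structure(list(
    approach = approach,
    retract = retract,
    contact_height = unname(z0),
    baseline = list(intercept = unname(coef(base_fit)[1]),
                    slope = unname(coef(base_fit)[2]), rms = rms),
    max_indentation = if (is.na(z0) || nrow(approach) == 0) 0
                      else max(approach$indentation),
    flags = flags,
    metadata = curve$metadata
  ), class = "fd_processed")
}

#' @export
print.fd_processed <- function(x, ...) {
  cat("<fd_processed>", x$metadata$curve_id, "\n")
  if (is.na(x$contact_height)) {
    cat("  no contact detected\n")
  } else {
    cat(sprintf("  contact height: %.4g um; max indentation: %.1f nm\n",
                x$contact_height * 1e6, x$max_indentation * 1e9))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
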