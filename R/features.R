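#' Fit the Sneddon conical-contact model for the apparent Young's modulus
#'
#' Least-squares fit of `F(delta) = 2 E tan(alpha) / (pi (1 - nu^2)) *
#' delta^2` to the approach samples whose force lies in the shallow
#' indentation window (default 0-250 pN). Because the model is linear in E,
#' the least-squares estimate is closed-form:
#' `E_hat = pi (1 - nu^2) / (2 tan alpha) * sum(F delta^2) / sum(delta^4)`.
#'
#' @param p An `fd_processed` curve.
#' @param force_window Closed force window (N); defaults to the
#'   configuration's 0-250 pN modulus window.
#' @param cfg A [processing_config()].
#'
#' @return The fitted apparent Young's modulus (Pa) with attributes
#'   `n_window` (samples used) and `rss` (residual sum of squares, N^2).
#' @export
fit_sneddon <- function(p, force_window = NULL, cfg = processing_config()) {
  stopifnot(inherits(p, "fd_processed"))
  if ("no_contact" %in% p$flags)
    abort("no contact point: modulus undefined", class = "rbcmech_no_contact")
  if (is.null(force_window)) force_window <- cfg$sneddon_window
  a <- dplyr::filter(p$approach,
                     .data$force >= force_window[1],
                     .data$force <= force_window[2],
                     .data$indentation >= 0)
  if (nrow(a) < cfg$min_window_samples)
    abort(sprintf("only %d approach samples in the force window (need %d)",
                  nrow(a), cfg$min_window_samples),
          class = "rbcmech_insufficient_window")
  md <- p$metadata
  geom <- 2 * tan(md$tip_half_angle * pi / 180) / (pi * (1 - md$poisson_ratio^2))
  d2 <- a$indentation^2
  c_hat <- sum(a$force * d2) / sum(d2^2)
  e_hat <- c_hat / geom
  if (!is.finite(e_hat) || e_hat <= 0)
    abort("Sneddon fit produced a non-positive modulus",
          class = "rbcmech_nonpositive_fit")
  structure(e_hat, n_window = nrow(a), rss = sum((a$force - c_hat * d2)^2))
}

#' Fit the large-indentation stiffness slope
#'
#' Ordinary least-squares slope of force versus indentation depth over the
#' approach samples whose force lies in the 250-750 pN window, beyond the
#' parabolic shallow-contact regime. This "AFM stiffness" S (N/m) is the
#' force needed per unit deformation at large indentations, where the cell
#' is squeezed against the dish much as it is squeezed in the capillary
#' microcirculation; it deliberately includes the substrate contribution and
#' is used as a comparative marker, not a pure material constant. The slope
#' is positive for stiffening contact.
#'
#' @inheritParams fit_sneddon
#' @param force_window Closed force window (N); default 250-750 pN.
#' @return The slope S (N/m) with attributes `n_window` and `rss`.
#' @export
fit_stiffness_slope <- function(p, force_window = NULL,
                                cfg = processing_config()) {
  stopifnot(inherits(p, "fd_processed"))
  if ("no_contact" %in% p$flags)
    abort("no contact point: slope undefined", class = "rbcmech_no_contact")
  if (is.null(force_window)) force_window <- cfg$slope_window
  if (nrow(p$approach) == 0 || max(p$approach$force) < force_window[2])
    abort("approach never reaches the upper window force",
          class = "rbcmech_insufficient_window")
  a <- dplyr::filter(p$approach,
                     .data$force >= force_window[1],
                     .data$force <= force_window[2])
  if (nrow(a) < cfg$min_window_samples)
    abort(sprintf("only %d approach samples in the force window (need %d)",
                  nrow(a), cfg$min_window_samples),
          class = "rbcmech_insufficient_window")
  fit <- lm(force ~ indentation, data = a)
  s <- unname(coef(fit)[2])
  if (!is.finite(s) || s <= 0)
    abort("stiffness-slope fit is non-positive",
          class = "rbcmech_nonpositive_fit")
  structure(s, n_window = nrow(a), rss = sum(stats::residuals(fit)^2))
}

#' Dissipated indentation energy
#'
#' Trapezoidal areas under the approach and retract branches over the common
#' indentation support `[0, delta_max]`; the dissipated energy is their
#' difference, `DE = A_E - A_R`. The retract is interpolated onto the
#' approach grid where the grids differ. By default, negative (adhesive)
#' retract forces are clipped at zero before integrating `A_R`, so that the
#' hysteresis stays a fraction in [0, 1]; the adhesion dip is accounted for
#' separately by [compute_work_of_adhesion()]. Set
#' `include_negative_retract = TRUE` in the configuration to keep them.
#'
#' @inheritParams fit_sneddon
#' @return A one-row tibble with `dissipated_energy`, `area_approach`,
#'   `area_retract` (J).
#' @export
compute_dissipation <- function(p, cfg = processing_config()) {
  stopifnot(inherits(p, "fd_processed"))
  if ("no_contact" %in% p$flags || p$max_indentation <= 0)
    return(tibble::tibble(dissipated_energy = NA_real_,
                          area_approach = NA_real_, area_retract = NA_real_))
  app <- dplyr::distinct(p$approach, .data$indentation, .keep_all = TRUE)
  ret <- dplyr::filter(p$retract, .data$indentation >= 0,
                       .data$indentation <= p$max_indentation)
  ret <- dplyr::distinct(ret, .data$indentation, .keep_all = TRUE)
  if (nrow(app) < 2 || nrow(ret) < 2)
    return(tibble::tibble(dissipated_energy = NA_real_,
                          area_approach = NA_real_, area_retract = NA_real_))
  f_ret <- approx(ret$indentation, ret$force, xout = app$indentation,
                  rule = 2)$y
  if (!cfg$include_negative_retract) f_ret <- pmax(f_ret, 0)
  a_e <- pracma::trapz(app$indentation, app$force)
  a_r <- pracma::trapz(app$indentation, f_ret)
  tibble::tibble(dissipated_energy = a_e - a_r,
                 area_approach = a_e, area_retract = a_r)
}

#' Indentation hysteresis
#'
#' Fractional energy dissipated over one cycle,
#' `H = (A_E - A_R) / A_E`, i.e. the dissipated energy normalized by the
#' approach energy. With non-negative clipped areas, `H` lies in [0, 1].
#'
#' @inheritParams fit_sneddon
#' @return Dimensionless hysteresis, `NA` when the approach area vanishes.
#' @export
compute_hysteresis <- function(p, cfg = processing_config()) {
  d <- compute_dissipation(p, cfg)
  if (is.na(d$area_approach) || d$area_approach <= 0) return(NA_real_)
  d$dissipated_energy / d$area_approach
}

#' Work of adhesion
#'
#' Energy of the adhesion dip on the retract branch: the magnitude of the
#' integrated force over the contiguous region where the retract drops below
#' baseline by more than the noise tolerance, extended to the surrounding
#' zero crossings. This is the energy needed to separate the tip from the
#' cell after indentation. Returns 0 (no flag) when no sample drops below
#' the tolerance -- the situation for the vast majority of curves.
#'
#' @inheritParams fit_sneddon
#' @return Work of adhesion (J), non-negative, with attribute
#'   `adhesion_present`.
#' @export
compute_work_of_adhesion <- function(p, cfg = processing_config()) {
  stopifnot(inherits(p, "fd_processed"))
  ret <- dplyr::arrange(p$retract, .data$indentation)
  if (nrow(ret) < 2 || all(is.na(ret$indentation)))
    return(structure(0, adhesion_present = FALSE))
  below <- which(ret$force < -cfg$adhesion_tol)
  if (length(below) == 0) return(structure(0, adhesion_present = FALSE))
  # contiguous block around the deepest sample, widened to the zero crossings
  deepest <- below[which.min(ret$force[below])]
  lo <- deepest
  while (lo > 1 && ret$force[lo - 1] < 0) lo <- lo - 1
  hi <- deepest
  while (hi < nrow(ret) && ret$force[hi + 1] < 0) hi <- hi + 1
  lo <- max(lo - 1, 1)
  hi <- min(hi + 1, nrow(ret))
  block <- ret[lo:hi, ]
  wa <- abs(pracma::trapz(block$indentation, pmin(block$force, 0)))
  structure(wa, adhesion_present = TRUE)
}

#' Extract all mechanical features from one processed curve
#'
#' Runs the five per-curve extractors -- apparent Young's modulus (Sneddon
#' fit), AFM stiffness slope, dissipated energy, hysteresis and work of
#' adhesion -- and collects them into a single tidy row. Extractors whose
#' preconditions fail (window unreachable, non-positive fit) yield `NA` for
#' that feature and add a flag, rather than raising: invalid pixels are
#' dropped per-feature during aggregation.
#'
#' @inheritParams fit_sneddon
#' @return A one-row tibble: identifiers, `contact_height`,
#'   `max_indentation`, `youngs_modulus`, `stiffness`, `dissipated_energy`,
#'   `hysteresis`, `work_of_adhesion`, `area_approach`, `area_retract`,
#'   `sneddon_n`, `slope_n`, `usable`, `flags` (comma-collapsed string).
#' @export
#' @examples
#' p <- detect_contact_point(generate_curve(curve_spec(seed = 1)))
#' extract_curve_features(p)
extract_curve_features <- function(p, cfg = processing_config()) {
  stopifnot(inherits(p, "fd_processed"))
  flags <- p$flags
  grab <- function(f, flag) {
    tryCatch(f(), error = function(e) {
      flags <<- c(flags, flag)
      NA_real_
    })
  }
  e <- grab(function() fit_sneddon(p, cfg = cfg), "modulus_fit_failed")
  s <- grab(function() fit_stiffness_slope(p, cfg = cfg), "slope_window_unreachable")
  d <- compute_dissipation(p, cfg)
  h <- compute_hysteresis(p, cfg)
  wa <- compute_work_of_adhesion(p, cfg)
  if (isTRUE(attr(wa, "adhesion_present"))) flags <- c(flags, "adhesion_present")
  md <- p$metadata
  tibble::tibble(
    patient_id = md$patient_id %||% NA_character_,
    cell_id = md$cell_id %||% NA_character_,
    curve_id = md$curve_id %||% NA_character_,
    contact_height = p$contact_height,
    max_indentation = p$max_indentation,
    youngs_modulus = as.numeric(e),
    stiffness = as.numeric(s),
    dissipated_energy = d$dissipated_energy,
    hysteresis = h,
    work_of_adhesion = as.numeric(wa),
    area_approach = d$area_approach,
    area_retract = d$area_retract,
    sneddon_n = attr(e, "n_window") %||% NA_integer_,
    slope_n = attr(s, "n_window") %||% NA_integer_,
    usable = !any(c("no_contact", "noisy_baseline", "low_max_force") %in% flags),
    flags = paste(unique(flags), collapse = ",")
  )
}

#' Process every pixel of a cell map
#'
#' Applies [detect_contact_point()] and [extract_curve_features()] to each
#' curve of an 8x8 map tibble (see [generate_cell_map()] or
#' [read_cell_map()]).
#'
#' @param map A map tibble with a `curve` list-column and `row`/`col`.
#' @param cfg A [processing_config()].
#' @return A tibble of per-pixel features (one row per pixel) with `row`,
#'   `col` and the [extract_curve_features()] columns.
#' @export
process_map <- function(map, cfg = processing_config()) {
  stopifnot(is.data.frame(map), "curve" %in% names(map))
  feats <- purrr::map(map$curve, function(cv) {
    extract_curve_features(detect_contact_point(cv, cfg), cfg)
  })
  out <- dplyr::bind_cols(
    dplyr::select(as_tibble(map), -dplyr::any_of("curve")),
    dplyr::bind_rows(feats)
  )
  for (a in c("cell_id", "patient_id", "substrate_plane"))
    attr(out, a) <- attr(map, a)
  out
}
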