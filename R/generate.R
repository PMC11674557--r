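#' Specification for one synthetic force-distance cycle
#'
#' Parameters of the forward model used to generate a single approach/retract
#' cycle with known ground truth. The approach follows the Sneddon conical
#' contact law F = 2 E tan(alpha) / (pi (1 - nu^2)) * delta^2 after contact,
#' optionally blending into a stiffer linear regime at depth so that the
#' large-indentation slope is controllable independently of the modulus
#' (mimicking the growing substrate contribution under a thin cell). The
#' retract is a hysteresis-scaled copy of the approach, with an optional
#' triangular adhesion dip below baseline after pull-off.
#'
#' @param true_modulus Apparent Young's modulus E (Pa) of the shallow
#'   indentation regime.
#' @param linear_slope Slope (N/m) of the linear regime entered once the
#'   approach force exceeds `transition_force`; `NULL` keeps the pure
#'   Sneddon parabola all the way to the setpoint.
#' @param transition_force Force (N) at which the parabola hands over to the
#'   linear regime; default 250 pN, the upper edge of the modulus-fit window.
#' @param hysteresis_ratio Fraction of the approach energy dissipated: the
#'   retract force is `(1 - hysteresis_ratio)` times the approach force at
#'   the same indentation.
#' @param adhesion_depth Depth (N) of the triangular adhesion dip on the
#'   retract; 0 disables it.
#' @param adhesion_width Width (m) of the adhesion dip along the tip-sample
#'   separation axis.
#' @param contact_height Piezo height (m) of the contact point.
#' @param pre_contact_range Piezo travel (m) recorded before contact (the
#'   baseline region).
#' @param spring_constant Cantilever spring constant k (N/m).
#' @param tip_half_angle Conical tip half-angle (degrees).
#' @param poisson_ratio Poisson ratio; 0.5 for an incompressible cell.
#' @param setpoint_force Maximum indentation force (N); default 2 nN.
#' @param indentation_rate Piezo speed (m/s), metadata only.
#' @param noise_sd Gaussian force noise SD (N) added to both segments.
#' @param baseline_offset Constant force offset (N) applied to the whole
#'   cycle (uncorrected deflection zero).
#' @param samples_per_segment Number of samples in the approach segment.
#' @param curve_id,cell_id,patient_id Identifiers carried in the metadata.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#'
#' @return A list of class `curve_spec`.
#' @export
#' @examples
#' fd <- generate_curve(curve_spec(true_modulus = 1500, noise_sd = 0))
#' fd
curve_spec <- function(true_modulus = 1500,
                       linear_slope = NULL,
                       transition_force = 250e-12,
                       hysteresis_ratio = 0.48,
                       adhesion_depth = 0,
                       adhesion_width = 200e-9,
                       contact_height = 5e-6,
                       pre_contact_range = 1.5e-6,
                       spring_constant = 0.05,
                       tip_half_angle = 20,
                       poisson_ratio = 0.5,
                       setpoint_force = 2e-9,
                       indentation_rate = 5e-6,
                       noise_sd = 0,
                       baseline_offset = 0,
                       samples_per_segment = 300,
                       curve_id = "curve_1",
                       cell_id = "cell_1",
                       patient_id = "patient_1",
                       seed = NULL) {
  stopifnot(true_modulus > 0, hysteresis_ratio >= 0, hysteresis_ratio <= 1,
            adhesion_depth >= 0, adhesion_width > 0, noise_sd >= 0,
            spring_constant > 0, tip_half_angle > 0, tip_half_angle < 90,
            setpoint_force > 0, samples_per_segment >= 100)
  if (!is.null(linear_slope)) stopifnot(linear_slope > 0)
  structure(as.list(environment()), class = "curve_spec")
}

# Sneddon prefactor c in F = c * delta^2 (N / m^2)
sneddon_coefficient <- function(modulus, half_angle_deg, poisson_ratio) {
  2 * modulus * tan(half_angle_deg * pi / 180) / (pi * (1 - poisson_ratio^2))
}

# forward force law of the generator, vectorized over indentation depth
forward_force <- function(delta, coef, linear_slope, transition_force) {
  f <- coef * pmax(delta, 0)^2
  if (!is.null(linear_slope)) {
    delta_t <- sqrt(transition_force / coef)
    lin <- transition_force + linear_slope * (delta - delta_t)
    f <- ifelse(delta > delta_t, lin, f)
  }
  f
}

#' Generate one synthetic force-distance cycle
#'
#' Runs the forward model of [curve_spec()] and returns the cycle in raw
#' instrument coordinates (piezo height vs force), exactly as an instrument
#' export would provide it: the indentation axis is folded back into piezo
#' travel plus cantilever deflection, `z = z0 - delta - F/k`, so that
#' [detect_contact_point()] has to undo the conversion.
#'
#' The generating ground truth (modulus, slope, hysteresis ratio, adhesion
#' work, contact height, maximum indentation) is stored in the `"truth"`
#' attribute for round-trip testing.
#'
#' @param spec A [curve_spec()].
#' @return An `fd_curve`: list with `approach` and `retract` tibbles
#'   (`piezo_height`, `force`, both ordered in acquisition time) and a
#'   `metadata` list.
#' @export
generate_curve <- function(spec = curve_spec()) {
  stopifnot(inherits(spec, "curve_spec"))
  gen <- function() generate_curve_impl(spec)
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, gen()) else gen()
}

generate_curve_impl <- function(spec) {
  k <- spec$spring_constant
  z0 <- spec$contact_height
  coef <- sneddon_coefficient(spec$true_modulus, spec$tip_half_angle,
                              spec$poisson_ratio)
  # maximum indentation at the setpoint force
  if (is.null(spec$linear_slope) || spec$setpoint_force <= spec$transition_force) {
    delta_max <- sqrt(spec$setpoint_force / coef)
  } else {
    delta_t <- sqrt(spec$transition_force / coef)
    delta_max <- delta_t +
      (spec$setpoint_force - spec$transition_force) / spec$linear_slope
  }

  n <- spec$samples_per_segment
  n_pre <- max(30L, round(0.3 * n))
  n_con <- n - n_pre

  # free ramp scales with the contact travel, as a sensible acquisition
  # would choose it, so the non-contact baseline region stays a sizeable
  # fraction of the total piezo range whatever the sample stiffness
  pre_range <- max(spec$pre_contact_range,
                   0.75 * (delta_max + spec$setpoint_force / k))
  z_pre <- seq(z0 + pre_range, z0, length.out = n_pre + 1L)[1:n_pre]
  f_pre <- rep(0, n_pre)
  delta_con <- seq(0, delta_max, length.out = n_con)
  f_con <- forward_force(delta_con, coef, spec$linear_slope,
                         spec$transition_force)
  z_con <- z0 - delta_con - f_con / k

  approach <- tibble::tibble(
    piezo_height = c(z_pre, z_con),
    force = c(f_pre, f_con)
  )

  # retract: scaled copy of the contact part, then adhesion dip, then free
  f_ret_con <- (1 - spec$hysteresis_ratio) * rev(f_con)
  delta_ret <- rev(delta_con)
  if (spec$adhesion_depth > 0) {
    w <- spec$adhesion_width
    # odd length so the apex at -w/2 is sampled exactly
    delta_adh <- seq(0, -w, length.out = 51L)[-1L]
    f_adh <- -spec$adhesion_depth * (1 - abs(delta_adh + w / 2) / (w / 2))
    free_from <- -w
  } else {
    delta_adh <- numeric(0)
    f_adh <- numeric(0)
    free_from <- 0
  }
  delta_free <- seq(free_from, -pre_range, length.out = 31L)[-1L]
  f_free <- rep(0, length(delta_free))

  delta_all <- c(delta_ret, delta_adh, delta_free)
  f_all <- c(f_ret_con, f_adh, f_free)
  retract <- tibble::tibble(
    piezo_height = z0 - delta_all - f_all / k,
    force = f_all
  )

  if (spec$noise_sd > 0) {
    approach$force <- approach$force + rnorm(nrow(approach), 0, spec$noise_sd)
    retract$force <- retract$force + rnorm(nrow(retract), 0, spec$noise_sd)
  }
  if (spec$baseline_offset != 0) {
    approach$force <- approach$force + spec$baseline_offset
    retract$force <- retract$force + spec$baseline_offset
  }

  curve <- new_fd_curve(approach, retract, metadata = list(
    spring_constant = k,
    tip_half_angle = spec$tip_half_angle,
    poisson_ratio = spec$poisson_ratio,
    setpoint_force = spec$setpoint_force,
    indentation_rate = spec$indentation_rate,
    curve_id = spec$curve_id,
    cell_id = spec$cell_id,
    patient_id = spec$patient_id
  ))
  attr(curve, "truth") <- list(
    modulus = spec$true_modulus,
    slope = spec$linear_slope,
    hysteresis_ratio = spec$hysteresis_ratio,
    work_of_adhesion = 0.5 * spec$adhesion_depth * spec$adhesion_width,
    contact_height = z0,
    delta_max = delta_max
  )
  curve
}

new_fd_curve <- function(approach, retract, metadata) {
  structure(list(approach = approach, retract = retract, metadata = metadata),
            class = "fd_curve")
}

validate_fd_curve <- function(curve) {
  stopifnot(inherits(curve, "fd_curve"))
  for (seg in c("approach", "retract")) {
    x <- curve[[seg]]
    if (nrow(x) < 50) abort(paste0(seg, " segment has fewer than 50 samples"),
                            class = "rbcmech_invalid_curve")
    if (any(!is.finite(x$force)) || any(!is.finite(x$piezo_height)))
      abort("non-finite values in curve", class = "rbcmech_invalid_curve")
    d <- diff(x$piezo_height)
    if (!(all(d < 0) || all(d > 0)))
      abort(paste0(seg, " piezo height is not strictly monotone"),
            class = "rbcmech_invalid_curve")
  }
  invisible(curve)
}

#' @export
print.fd_curve <- function(x, ...) {
  cat("<fd_curve>", x$metadata$curve_id, "\n")
  cat("  approach:", nrow(x$approach), "samples; retract:",
      nrow(x$retract), "samples\n")
  cat(sprintf("  k = %.3g N/m, setpoint = %.3g nN\n",
              x$metadata$spring_constant, x$metadata$setpoint_force * 1e9))
  invisible(x)
}

#' Generate a synthetic 8x8 elasticity map
#'
#' Builds the grid of force-distance cycles an AFM force-map acquisition
#' would produce over a single red blood cell sitting on a flat dish: cell
#' pixels follow a spherical-cap height profile (contact point raised above
#' the substrate plane) with the mechanics of `spec`; the surrounding pixels
#' are bare, much stiffer substrate. The generator's cell/substrate footprint
#' is stored per pixel in `is_cell_truth`.
#'
#' @param spec A [curve_spec()] describing the cell-pixel mechanics.
#' @param apex_height Cell apex height (m) above the substrate plane.
#' @param cell_radius Footprint radius (m) of the spherical cap.
#' @param scan_size Side length (m) of the square scan area.
#' @param grid Pixels per side; force maps here are 8x8 (64 curves).
#' @param substrate_modulus Apparent modulus (Pa) used for substrate pixels.
#' @param substrate_plane Piezo height (m) of the substrate contact plane.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per pixel: `row`, `col`, `x`, `y`,
#'   `is_cell_truth`, `truth_height` and a `curve` list-column of
#'   `fd_curve` objects. Attributes `cell_id`, `patient_id`,
#'   `substrate_plane` are set.
#' @export
generate_cell_map <- function(spec = curve_spec(),
                              apex_height = 2.64e-6,
                              cell_radius = 3.75e-6,
                              scan_size = 12e-6,
                              grid = 8L,
                              substrate_modulus = 1e6,
                              substrate_plane = 5e-6,
                              seed = NULL) {
  stopifnot(apex_height >= 0, cell_radius > 0, scan_size > 0, grid >= 2)
  if (2 * cell_radius >= scan_size)
    abort("cell footprint does not fit inside the scan area",
          class = "rbcmech_footprint_overflow")
  gen <- function() {
    centers <- (seq_len(grid) - (grid + 1) / 2) * (scan_size / grid)
    px <- tidyr::expand_grid(row = seq_len(grid), col = seq_len(grid))
    px$x <- centers[px$col]
    px$y <- centers[px$row]
    # cap centred on the pixel centre nearest the scan middle, so the grid
    # samples the apex and the recovered cell height can equal the true one
    c0 <- centers[ceiling((grid + 1) / 2)]
    r <- sqrt((px$x - c0)^2 + (px$y - c0)^2)
    if (apex_height > 0) {
      # sphere radius from cap height h and footprint radius a
      rs <- (cell_radius^2 + apex_height^2) / (2 * apex_height)
      h <- ifelse(r < cell_radius,
                  sqrt(pmax(rs^2 - r^2, 0)) - (rs - apex_height), 0)
      h <- pmax(h, 0)
    } else {
      h <- rep(0, nrow(px))
    }
    px$truth_height <- h
    px$is_cell_truth <- h > 0
    px$curve <- purrr::pmap(list(px$row, px$col, h), function(i, j, hij) {
      s <- spec
      s$seed <- NULL
      s$curve_id <- sprintf("r%dc%d", i, j)
      s$contact_height <- substrate_plane + hij
      if (hij <= 0) {
        s$true_modulus <- substrate_modulus
        s$linear_slope <- NULL
        s$hysteresis_ratio <- 0.05
        s$adhesion_depth <- 0
      }
      generate_curve(s)
    })
    attr(px, "cell_id") <- spec$cell_id
    attr(px, "patient_id") <- spec$patient_id
    attr(px, "substrate_plane") <- substrate_plane
    attr(px, "apex_height") <- apex_height
    px
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

#' Calibration targets for the synthetic cohort generator
#'
#' Group-wise medians and interquartile ranges, one row per variable, that
#' the default two-group cohort generator is calibrated to: a control group
#' of type 1 diabetes patients without microvascular complications (CTRL)
#' and a pathological group with confirmed complications (MC). Mechanical
#' variables (right-skewed) use a log-normal family; demographic and
#' biochemical variables use a truncated normal. All values are in the
#' units of the `unit` column (SI joules for energies, N/m for stiffness).
#'
#' @return A tibble with columns `variable`, `label`, `unit`, `family`,
#'   `ctrl_median`, `ctrl_q1`, `ctrl_q3`, `mc_median`, `mc_q1`, `mc_q3`,
#'   `missing_ok` (whether the variable may carry missing-at-random holes),
#'   `upper` (truncation bound).
#' @export
#' @examples
#' default_cohort_targets()
default_cohort_targets <- function() {
  tr <- function(variable, label, unit, family, cm, c1, c3, mm, m1, m3,
                 missing_ok, upper = Inf) {
    tibble::tibble(variable = variable, label = label, unit = unit,
                   family = family, ctrl_median = cm, ctrl_q1 = c1,
                   ctrl_q3 = c3, mc_median = mm, mc_q1 = m1, mc_q3 = m3,
                   missing_ok = missing_ok, upper = upper)
  }
  dplyr::bind_rows(
    tr("age", "Age", "years", "normal", 46, 32, 50, 43, 40, 48, FALSE),
    tr("duration", "Disease duration", "years", "normal", 22, 10, 32, 33, 28, 36, FALSE),
    tr("hba1c", "HbA1c", "%", "normal", 7.2, 6.7, 7.7, 7.4, 6.9, 7.8, TRUE),
    tr("glucose", "Glucose", "mg/dL", "normal", 134, 104, 180, 134, 106, 148, TRUE),
    tr("creatinine", "Creatinine", "mg/dL", "normal", 0.77, 0.67, 0.89, 0.72, 0.67, 0.85, TRUE),
    tr("egfr", "eGFR", "mL/min/1.73m2", "normal", 105, 96, 118, 108, 101, 129, TRUE),
    tr("total_chol", "Total cholesterol", "mg/dL", "normal", 170, 155, 189, 188, 170, 197, TRUE),
    tr("hdl", "HDL", "mg/dL", "normal", 57, 52, 68, 62, 48, 68, TRUE),
    tr("ldl", "LDL", "mg/dL", "normal", 97, 88, 112, 112, 84, 116, TRUE),
    tr("triglycerides", "Triglycerides", "mg/dL", "lognormal", 58, 45, 73, 74, 62, 115, TRUE),
    tr("hemoglobin", "Hemoglobin", "g/dL", "normal", 14.95, 13.95, 15.47, 14.10, 13.08, 15.25, TRUE),
    tr("hematocrit", "Hematocrit", "%", "normal", 43.6, 40.9, 45.2, 42.1, 38.0, 44.4, TRUE),
    tr("rbc_count", "RBC count", "1e12/L", "normal", 5.06, 4.89, 5.22, 4.67, 4.53, 4.87, TRUE),
    tr("mcv", "MCV", "fL", "normal", 86.9, 83.4, 89.6, 89.3, 86.8, 92.6, TRUE),
    tr("mchc", "MCHC", "g/dL", "normal", 33.95, 33.20, 35.03, 34.40, 33.70, 34.50, TRUE),
    tr("platelets", "Platelets", "1e9/L", "normal", 218, 203, 256, 213, 204, 274, TRUE),
    tr("fibrinogen", "Fibrinogen", "mg/dL", "normal", 280, 248, 297, 276, 254, 295, TRUE),
    tr("azotemia", "Azotemia", "mg/dL", "normal", 15.0, 12.0, 17.0, 14.5, 11.2, 18.8, TRUE),
    tr("albumin", "Albumin", "g/L", "normal", 42, 41, 44, 43, 40, 44.5, TRUE),
    tr("serum_iron", "Serum iron", "ug/dL", "normal", 92, 64, 110, 63, 53, 80, TRUE),
    tr("youngs_modulus", "E", "Pa", "lognormal", 1065, 938, 1385, 1290, 984, 1860, FALSE),
    tr("dissipation", "Dissipated energy", "J", "lognormal", 3.79e-16, 3.11e-16, 4.50e-16, 3.45e-16, 2.24e-16, 4.19e-16, FALSE),
    tr("hysteresis", "Hysteresis", "adim", "lognormal", 0.48, 0.40, 0.52, 0.45, 0.37, 0.51, FALSE, upper = 0.999),
    tr("adhesion", "Work of adhesion", "J", "lognormal", 0.96e-17, 0.73e-17, 1.12e-17, 1.03e-17, 0.65e-17, 1.67e-17, FALSE),
    tr("stiffness", "AFM stiffness", "N/m", "lognormal", 0.0021, 0.0020, 0.0022, 0.0027, 0.0022, 0.0041, FALSE)
  )
}

#' Specification for a synthetic two-group cohort
#'
#' @param n_ctrl,n_mc Patients per group; defaults 22 controls / 16 cases.
#' @param cells_per_patient Cells measured per patient (>= 10 for inclusion).
#' @param missing_rate Probability that a biochemical value is missing
#'   (completely at random).
#' @param cell_sigma Log-scale SD of cell-to-cell variation around a
#'   patient's mechanical mean.
#' @param adhesion_prevalence Named fractions of curves with a measurable
#'   adhesion dip per group; adhesion is sporadic in controls and much more
#'   frequent in the pathological group.
#' @param sex_prop_f Named per-group probabilities of female sex.
#' @param targets Calibration table, see [default_cohort_targets()].
#' @param with_maps If `TRUE`, the pipeline `simulate` stage also writes raw
#'   curve maps per patient.
#' @param seed Optional integer seed.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ctrl = 22L, n_mc = 16L,
                        cells_per_patient = 10L,
                        missing_rate = 0.08,
                        cell_sigma = 0.35,
                        adhesion_prevalence = c(CTRL = 0.05, MC = 0.25),
                        sex_prop_f = c(CTRL = 4 / 22, MC = 5 / 16),
                        targets = default_cohort_targets(),
                        with_maps = FALSE,
                        seed = NULL) {
  stopifnot(n_ctrl >= 2, n_mc >= 2, cells_per_patient >= 1,
            missing_rate >= 0, missing_rate <= 0.3,
            all(targets$ctrl_median > 0 | targets$family == "normal"))
  structure(as.list(environment()), class = "cohort_spec")
}

# draw n values whose median/IQR converge to the target as n grows
draw_from_target <- function(n, family, med, q1, q3, lower = 0, upper = Inf) {
  z75 <- qnorm(0.75)
  draw <- if (family == "lognormal") {
    sdlog <- log(q3 / q1) / (2 * z75)
    function(m) rlnorm(m, meanlog = log(med), sdlog = sdlog)
  } else {
    s <- (q3 - q1) / (2 * z75)
    function(m) rnorm(m, mean = med, sd = s)
  }
  x <- draw(n)
  for (i in 1:20) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- draw(sum(bad))
  }
  pmin(pmax(x, lower), upper)
}

#' Generate a calibrated synthetic patient cohort
#'
#' Draws a two-group patient table whose per-group medians and IQRs converge
#' to the calibration targets as the group sizes grow: mechanical means from
#' log-normal distributions (right-skewed, as pooled single-cell moduli are),
#' demographics and blood biochemistry from truncated normals, female sex
#' from per-group proportions, and missing-completely-at-random holes in the
#' biochemical panel. Group differences (stiffness up, RBC count down,
#' triglycerides up in the pathological group) follow directly from the
#' group-specific targets.
#'
#' Per-cell mechanical values (log-normal scatter around each patient's
#' mean) are attached as the `"cells"` attribute for pooled distribution
#' analyses such as [cullen_frey()].
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient: `patient_id`, `group`
#'   (factor CTRL/MC), `sex`, and one column per calibration variable.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 42))
#' dplyr::count(cohort, group)
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  gen <- function() generate_cohort_impl(spec)
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, gen()) else gen()
}

generate_cohort_impl <- function(spec) {
  tg <- spec$targets
  groups <- c(rep("CTRL", spec$n_ctrl), rep("MC", spec$n_mc))
  n <- length(groups)
  cohort <- tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    group = factor(groups, levels = c("CTRL", "MC")),
    sex = factor(ifelse(runif(n) < spec$sex_prop_f[groups], "F", "M"),
                 levels = c("F", "M"))
  )
  for (i in seq_len(nrow(tg))) {
    row <- tg[i, ]
    x <- numeric(n)
    for (g in c("CTRL", "MC")) {
      idx <- groups == g
      pre <- if (g == "CTRL") "ctrl" else "mc"
      x[idx] <- draw_from_target(sum(idx), row$family,
                                 row[[paste0(pre, "_median")]],
                                 row[[paste0(pre, "_q1")]],
                                 row[[paste0(pre, "_q3")]],
                                 lower = 0, upper = row$upper)
    }
    if (row$missing_ok && spec$missing_rate > 0) {
      x[runif(n) < spec$missing_rate] <- NA_real_
    }
    cohort[[row$variable]] <- x
  }
  # per-cell mechanical values scattered around the patient means;
  # the -sigma^2/2 shift keeps the patient mean centred on the drawn value
  sg <- spec$cell_sigma
  cells <- tidyr::expand_grid(patient_id = cohort$patient_id,
                              cell = seq_len(spec$cells_per_patient))
  cells <- dplyr::left_join(
    cells,
    dplyr::select(cohort, "patient_id", "group", "youngs_modulus",
                  "stiffness", "hysteresis"),
    by = "patient_id"
  )
  m <- nrow(cells)
  cells <- dplyr::mutate(
    cells,
    cell_id = sprintf("%s_C%02d", .data$patient_id, .data$cell),
    youngs_modulus = .data$youngs_modulus * rlnorm(m, -sg^2 / 2, sg),
    stiffness = .data$stiffness * rlnorm(m, -(sg / 2)^2 / 2, sg / 2),
    hysteresis = pmin(.data$hysteresis * rlnorm(m, -(sg / 3)^2 / 2, sg / 3), 0.99),
    has_adhesion = runif(m) < spec$adhesion_prevalence[as.character(.data$group)]
  ) %>%
    dplyr::select("patient_id", "cell_id", "group", "youngs_modulus",
                  "stiffness", "hysteresis", "has_adhesion")
  attr(cohort, "cells") <- cells
  cohort
}
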