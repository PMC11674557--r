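#' Curve-processing configuration
#'
#' Collects the thresholds and fit windows used to turn a raw force-distance
#' cycle into force-versus-indentation form and to extract mechanical
#' parameters. All values are SI (N, m, J).
#'
#' @param baseline_fraction Fraction of the approach piezo range (taken from
#'   the far, non-contact end) used to fit the linear force baseline.
#' @param contact_threshold Minimum baseline-corrected force (N) that counts
#'   as tip-sample contact. The working threshold is
#'   `max(contact_threshold, rms_multiplier * baseline RMS)`.
#' @param rms_multiplier Multiplier on the baseline residual RMS in the
#'   contact threshold.
#' @param baseline_rms_tol Baseline residual RMS (N) above which the curve is
#'   flagged `noisy_baseline`.
#' @param sneddon_window Closed force window (N) for the Sneddon fit of the
#'   apparent Young's modulus; default 0-250 pN.
#' @param slope_window Closed force window (N) for the large-indentation
#'   stiffness slope; default 250-750 pN.
#' @param min_window_samples Minimum number of approach samples required
#'   inside a fit window.
#' @param usable_fraction Fraction of the setpoint force the approach must
#'   reach for the curve to count as usable.
#' @param adhesion_tol Force tolerance (N): retract forces below
#'   `-adhesion_tol` define the adhesion dip.
#' @param include_negative_retract If `TRUE`, negative retract forces enter
#'   the retract area A_R (so hysteresis can exceed 1 on adhesive curves);
#'   the default clips them at zero and accounts for the dip separately in
#'   the work of adhesion.
#'
#' @return A list of class `processing_config`.
#' @export
#' @examples
#' cfg <- processing_config()
#' cfg$sneddon_window
processing_config <- function(baseline_fraction = 0.3,
                              contact_threshold = 1e-11,
                              rms_multiplier = 3,
                              baseline_rms_tol = 2e-11,
                              sneddon_window = c(0, 250e-12),
                              slope_window = c(250e-12, 750e-12),
                              min_window_samples = 10,
                              usable_fraction = 0.8,
                              adhesion_tol = 1e-11,
                              include_negative_retract = FALSE) {
  stopifnot(baseline_fraction > 0, baseline_fraction < 1,
            contact_threshold > 0,
            length(sneddon_window) == 2, sneddon_window[1] < sneddon_window[2],
            length(slope_window) == 2, slope_window[1] < slope_window[2],
            min_window_samples >= 2)
  structure(list(
    baseline_fraction = baseline_fraction,
    contact_threshold = contact_threshold,
    rms_multiplier = rms_multiplier,
    baseline_rms_tol = baseline_rms_tol,
    sneddon_window = sneddon_window,
    slope_window = slope_window,
    min_window_samples = min_window_samples,
    usable_fraction = usable_fraction,
    adhesion_tol = adhesion_tol,
    include_negative_retract = include_negative_retract
  ), class = "processing_config")
}

#' Cell-map aggregation configuration
#'
#' @param substrate_threshold Height (m) above the fitted substrate plane
#'   below which a pixel is classified as bare substrate; default 500 nm,
#'   far above piezo noise and far below a red-blood-cell apex (~2.5 um).
#' @param plane_quantile Quantile of per-pixel contact heights used as the
#'   robust substrate plane estimate.
#' @param min_cell_pixels Minimum number of cell pixels for a usable 8x8 map.
#' @param min_cells Minimum number of usable cells for a patient-level mean.
#'
#' @return A list of class `aggregation_config`.
#' @export
aggregation_config <- function(substrate_threshold = 500e-9,
                               plane_quantile = 0.1,
                               min_cell_pixels = 8,
                               min_cells = 10) {
  stopifnot(substrate_threshold > 0, plane_quantile >= 0, plane_quantile <= 0.5,
            min_cell_pixels >= 1, min_cells >= 1)
  structure(list(
    substrate_threshold = substrate_threshold,
    plane_quantile = plane_quantile,
    min_cell_pixels = min_cell_pixels,
    min_cells = min_cells
  ), class = "aggregation_config")
}

#' Cohort-statistics configuration
#'
#' @param alpha Two-sided significance level for tests and CIs.
#' @param power_target Minimum Fisher-z power required for a Spearman
#'   correlation to be flagged significant.
#' @param screen_alpha Univariate p-value threshold admitting a variable into
#'   the stepwise candidate set.
#' @param n_boot Number of bootstrap replicates for the Cullen-Frey cloud.
#'
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05,
                         power_target = 0.8,
                         screen_alpha = 0.25,
                         n_boot = 500) {
  stopifnot(alpha > 0, alpha < 1, power_target > 0, power_target < 1,
            n_boot >= 200)
  structure(list(alpha = alpha, power_target = power_target,
                 screen_alpha = screen_alpha, n_boot = n_boot),
            class = "stats_config")
}

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations plus the synthetic-cohort
#' specification and a master seed, for [run_pipeline()].
#'
#' @param processing A [processing_config()].
#' @param aggregation An [aggregation_config()].
#' @param stats A [stats_config()].
#' @param synthetic A [cohort_spec()].
#' @param seed Integer master seed for every randomized step.
#' @param auc_variables Variables reported in the AUC table of the `report`
#'   stage.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(processing = processing_config(),
                            aggregation = aggregation_config(),
                            stats = stats_config(),
                            synthetic = cohort_spec(),
                            seed = 1L,
                            auc_variables = c("duration", "triglycerides",
                                              "rbc_count", "mcv",
                                              "youngs_modulus", "stiffness")) {
  structure(list(processing = processing, aggregation = aggregation,
                 stats = stats, synthetic = synthetic,
                 seed = as.integer(seed), auc_variables = auc_variables),
            class = "pipeline_config")
}
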