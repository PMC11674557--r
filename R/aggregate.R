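#' Classify map pixels as cell or bare substrate
#'
#' Each force map covers the whole cell plus a portion of unoccupied dish
#' surface, which must be removed before averaging. The substrate plane is
#' estimated as a robust low quantile of the per-pixel contact heights;
#' pixels whose contact point lies within `substrate_threshold` of that
#' plane, or that carry disqualifying flags, are excluded from the cell
#' mask.
#'
#' @param pixels Per-pixel feature tibble from [process_map()] (needs
#'   `contact_height`, `usable`, `flags`).
#' @param cfg An [aggregation_config()].
#'
#' @return `pixels` with a logical `is_cell` column and a `height_above_plane`
#'   column; the fitted plane is stored in the `"substrate_plane_fit"`
#'   attribute. Errors with class `rbcmech_unusable_map` when fewer than
#'   `min_cell_pixels` cell pixels remain.
#' @export
classify_pixels <- function(pixels, cfg = aggregation_config()) {
  stopifnot(is.data.frame(pixels), "contact_height" %in% names(pixels))
  ch <- pixels$contact_height
  ok <- is.finite(ch)
  if (!any(ok))
    abort("no pixel has a contact point", class = "rbcmech_unusable_map")
  plane <- unname(quantile(ch[ok], cfg$plane_quantile, na.rm = TRUE))
  out <- dplyr::mutate(
    as_tibble(pixels),
    height_above_plane = .data$contact_height - plane,
    is_cell = is.finite(.data$contact_height) &
      .data$height_above_plane > cfg$substrate_threshold &
      .data$usable
  )
  if (sum(out$is_cell, na.rm = TRUE) < cfg$min_cell_pixels)
    abort(sprintf("only %d cell pixels after masking (need %d)",
                  sum(out$is_cell, na.rm = TRUE), cfg$min_cell_pixels),
          class = "rbcmech_unusable_map")
  for (a in c("cell_id", "patient_id"))
    attr(out, a) <- attr(pixels, a)
  attr(out, "substrate_plane_fit") <- plane
  out
}

#' Cell height from the contact-point topography
#'
#' Height of the cell apex above the substrate plane: the maximum, over cell
#' pixels, of contact height minus the fitted plane.
#'
#' @param pixels A classified pixel tibble from [classify_pixels()]; an
#'   unclassified tibble is classified first.
#' @param cfg An [aggregation_config()].
#' @return Cell height (m).
#' @export
compute_cell_height <- function(pixels, cfg = aggregation_config()) {
  if (!"is_cell" %in% names(pixels)) pixels <- classify_pixels(pixels, cfg)
  max(pixels$height_above_plane[pixels$is_cell], na.rm = TRUE)
}

#' Per-cell mechanical means
#'
#' Classifies each cell's pixels, drops the substrate, and averages each
#' mechanical feature over the remaining cell pixels. Features missing on a
#' pixel (e.g. the slope window unreachable on a thin rim pixel) are dropped
#' from that pixel's contribution only, not the whole pixel. Maps that fail
#' classification are dropped with a warning.
#'
#' @param pixels Feature tibble for one or more cells (rows = pixels), with
#'   `patient_id` and `cell_id` columns, as produced by stacking
#'   [process_map()] outputs.
#' @param cfg An [aggregation_config()].
#' @return A tibble with one row per usable cell: identifiers, per-feature
#'   means, `cell_height`, `n_pixels`.
#' @export
summarize_cells <- function(pixels, cfg = aggregation_config()) {
  stopifnot(is.data.frame(pixels))
  feats <- c("youngs_modulus", "stiffness", "dissipated_energy",
             "hysteresis", "work_of_adhesion")
  split_cells <- split(as_tibble(pixels),
                       list(pixels$patient_id, pixels$cell_id), drop = TRUE)
  rows <- purrr::map(split_cells, function(px) {
    cl <- tryCatch(classify_pixels(px, cfg), error = function(e) {
      warn(sprintf("cell %s dropped: %s", px$cell_id[1], conditionMessage(e)))
      NULL
    })
    if (is.null(cl)) return(NULL)
    cell <- dplyr::filter(cl, .data$is_cell)
    out <- tibble::tibble(patient_id = px$patient_id[1],
                          cell_id = px$cell_id[1],
                          n_pixels = nrow(cell),
                          cell_height = compute_cell_height(cl, cfg))
    for (f in feats) out[[f]] <- mean(cell[[f]], na.rm = TRUE)
    out
  })
  dplyr::bind_rows(rows)
}

#' Patient-level aggregation of cell means
#'
#' The patient value of each mechanical parameter is the unweighted mean of
#' its per-cell means (cells weighted equally regardless of how many usable
#' pixels each contributed), mirroring a two-level design: pixels within a
#' cell, cells within a patient.
#'
#' @param cells Per-cell tibble from [summarize_cells()].
#' @param cfg An [aggregation_config()]; patients with fewer than
#'   `min_cells` usable cells raise `rbcmech_insufficient_cells` (set
#'   `min_cells = 1` to keep them).
#' @return A tibble with one row per patient: per-feature means,
#'   `cell_height_mean`, `n_cells`.
#' @export
aggregate_patients <- function(cells, cfg = aggregation_config()) {
  stopifnot(is.data.frame(cells), nrow(cells) > 0)
  out <- cells %>%
    group_by(.data$patient_id) %>%
    summarise(n_cells = dplyr::n(),
              cell_height_mean = mean(.data$cell_height, na.rm = TRUE),
              across(c("youngs_modulus", "stiffness", "dissipated_energy",
                       "hysteresis", "work_of_adhesion"),
                     ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  short <- out$patient_id[out$n_cells < cfg$min_cells]
  if (length(short) > 0)
    abort(sprintf("patients with fewer than %d usable cells: %s",
                  cfg$min_cells, paste(short, collapse = ", ")),
          class = "rbcmech_insufficient_cells")
  out
}
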