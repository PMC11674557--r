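#' Write a force-distance curve to a plain-text file
#'
#' Tab-separated export: `# key: value` header lines carrying the
#' acquisition metadata, followed by the columns
#' `segment  piezo_height_m  force_N`. Doubles are written with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param curve An `fd_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fd_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  md <- curve$metadata
  hdr <- c(
    sprintf("# spring_constant_N_per_m: %.17g", md$spring_constant),
    sprintf("# tip_half_angle_deg: %.17g", md$tip_half_angle),
    sprintf("# poisson_ratio: %.17g", md$poisson_ratio),
    sprintf("# setpoint_N: %.17g", md$setpoint_force),
    sprintf("# indentation_rate_m_per_s: %.17g", md$indentation_rate),
    sprintf("# curve_id: %s", md$curve_id),
    sprintf("# cell_id: %s", md$cell_id),
    sprintf("# patient_id: %s", md$patient_id),
    "segment\tpiezo_height_m\tforce_N"
  )
  body <- c(
    sprintf("approach\t%.17g\t%.17g", curve$approach$piezo_height,
            curve$approach$force),
    sprintf("retract\t%.17g\t%.17g", curve$retract$piezo_height,
            curve$retract$force)
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a force-distance curve file
#'
#' Parses the format of [write_fd_curve()]. Header parsing is tolerant to
#' comment dialects: any number of leading `#`/`;`/`%` characters and
#' either `:` or `=` as the key-value separator.
#'
#' @param path Curve file path.
#' @return An `fd_curve`.
#' @export
read_fd_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*[#;%]", lines)
  meta <- list()
  for (ln in lines[is_comment]) {
    body <- sub("^\\s*[#;%]+\\s*", "", ln)
    m <- regmatches(body, regexec("^([^:=]+)[:=]\\s*(.*)$", body))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  num <- function(key, default = NA_real_) {
    v <- suppressWarnings(as.numeric(meta[[key]]))
    if (length(v) == 0 || is.na(v)) default else v
  }
  # base-R parsing: correctly-rounded doubles so the round trip is bit-exact
  tab <- tryCatch(
    utils::read.delim(text = lines[!is_comment], sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("malformed curve file '%s'", path),
                              class = "rbcmech_malformed_file"))
  need <- c("segment", "piezo_height_m", "force_N")
  if (!all(need %in% names(tab)))
    abort(sprintf("malformed curve file '%s': missing columns", path),
          class = "rbcmech_malformed_file")
  if (!is.numeric(tab$piezo_height_m) || !is.numeric(tab$force_N) ||
      any(!is.finite(tab$piezo_height_m)) || any(!is.finite(tab$force_N)))
    abort(sprintf("malformed curve file '%s': non-numeric data", path),
          class = "rbcmech_malformed_file")
  seg <- function(s) {
    x <- tab[tab$segment == s, ]
    tibble::tibble(piezo_height = x$piezo_height_m, force = x$force_N)
  }
  curve <- new_fd_curve(seg("approach"), seg("retract"), metadata = list(
    spring_constant = num("spring_constant_N_per_m", 0.05),
    tip_half_angle = num("tip_half_angle_deg", 20),
    poisson_ratio = num("poisson_ratio", 0.5),
    setpoint_force = num("setpoint_N", 2e-9),
    indentation_rate = num("indentation_rate_m_per_s", 5e-6),
    curve_id = meta[["curve_id"]] %||% basename(path),
    cell_id = meta[["cell_id"]] %||% NA_character_,
    patient_id = meta[["patient_id"]] %||% NA_character_
  ))
  validate_fd_curve(curve)
  curve
}

#' Write a cell map as a curve directory plus manifest
#'
#' One curve file per pixel and a JSON manifest recording grid coordinates,
#' identifiers, and (for synthetic maps) the generator's ground-truth
#' footprint.
#'
#' @param map A map tibble (see [generate_cell_map()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cell_map <- function(map, dir) {
  stopifnot(is.data.frame(map), "curve" %in% names(map))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("curve_r%dc%d.txt", map$row, map$col)
  purrr::walk2(map$curve, files, function(cv, f)
    write_fd_curve(cv, file.path(dir, f)))
  manifest <- list(
    cell_id = attr(map, "cell_id") %||% map$curve[[1]]$metadata$cell_id,
    patient_id = attr(map, "patient_id") %||% map$curve[[1]]$metadata$patient_id,
    grid = nrow(map),
    pixels = purrr::pmap(list(map$row, map$col, files,
                              map$is_cell_truth %||% rep(NA, nrow(map))),
                         function(r, c, f, tr)
                           list(row = r, col = c, file = f,
                                is_cell_truth = tr))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cell map directory
#'
#' @param dir Directory written by [write_cell_map()].
#' @return A map tibble with `row`, `col`, `is_cell_truth` and a `curve`
#'   list-column.
#' @export
read_cell_map <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    abort(sprintf("no manifest.json in '%s'", dir),
          class = "rbcmech_malformed_file")
  mf <- jsonlite::read_json(mf_path)
  px <- purrr::map_dfr(mf$pixels, function(p)
    tibble::tibble(row = p$row, col = p$col, file = p$file,
                   is_cell_truth = p$is_cell_truth %||% NA))
  px$curve <- purrr::map(px$file, function(f)
    read_fd_curve(file.path(dir, f)))
  out <- dplyr::select(px, -"file")
  attr(out, "cell_id") <- mf$cell_id
  attr(out, "patient_id") <- mf$patient_id
  out
}
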