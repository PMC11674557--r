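#' Run a pipeline stage
#'
#' Ties the modules together into a reproducible workflow with five
#' subcommands, each writing deterministic artifact files:
#'
#' * `simulate` -- generate the synthetic cohort (`cohort.csv`, per-cell
#'   values in `cells.csv`, and raw curve maps under `maps/` when
#'   `config$synthetic$with_maps` is set).
#' * `extract` -- read every curve file under `input`, detect contact
#'   points and extract per-curve features (`features.csv`); unreadable
#'   files are skipped and listed in `exclusions.log`.
#' * `aggregate` -- mask substrate pixels and average features per cell and
#'   per patient (`patients.csv`) from `input/features.csv`.
#' * `stats` -- marker summary table (`summary.csv`), AUC table
#'   (`auc_table.csv`), logistic model reports (`models.json`) and
#'   Cullen-Frey coordinates (`cullen_frey.csv`) from `input/cohort.csv`.
#' * `report` -- `stats` plus a `report.json` master record (seed, counts,
#'   artifact list).
#'
#' Every randomized step is seeded from `config$seed`, so re-running a
#' subcommand on unchanged inputs reproduces identical artifacts.
#'
#' @param command One of `"simulate"`, `"extract"`, `"aggregate"`,
#'   `"stats"`, `"report"`.
#' @param config A [pipeline_config()].
#' @param input Input directory (stage dependent; not used by `simulate`).
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a named list of artifact paths.
#' @export
#' @examples
#' \donttest{
#' out <- tempfile()
#' run_pipeline("simulate", pipeline_config(seed = 1), out_dir = out)
#' run_pipeline("report", pipeline_config(seed = 1), input = out,
#'              out_dir = out)
#' }
run_pipeline <- function(command = c("simulate", "extract", "aggregate",
                                     "stats", "report"),
                         config = pipeline_config(), input = NULL,
                         out_dir = ".") {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", command, sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  switch(command,
    simulate = pipeline_simulate(config, out_dir, log_msg),
    extract = pipeline_extract(config, input, out_dir, log_msg),
    aggregate = pipeline_aggregate(config, input, out_dir, log_msg),
    stats = pipeline_stats(config, input, out_dir, log_msg),
    report = pipeline_report(config, input, out_dir, log_msg)
  )
}

pipeline_simulate <- function(config, out_dir, log_msg) {
  spec <- config$synthetic
  if (is.null(spec$seed)) spec$seed <- config$seed
  cohort <- generate_cohort(spec)
  cells <- attr(cohort, "cells")
  cohort_path <- file.path(out_dir, "cohort.csv")
  cells_path <- file.path(out_dir, "cells.csv")
  readr::write_csv(cohort, cohort_path)
  readr::write_csv(cells, cells_path)
  log_msg("cohort of %d patients (%d CTRL / %d MC), seed %d",
          nrow(cohort), sum(cohort$group == "CTRL"),
          sum(cohort$group == "MC"), spec$seed)
  paths <- list(cohort = cohort_path, cells = cells_path)
  if (isTRUE(spec$with_maps)) {
    maps_dir <- file.path(out_dir, "maps")
    withr::with_seed(spec$seed + 1L, {
      for (i in seq_len(nrow(cells))) {
        cl <- cells[i, ]
        cs <- curve_spec(
          true_modulus = cl$youngs_modulus,
          linear_slope = cl$stiffness,
          hysteresis_ratio = min(cl$hysteresis, 0.95),
          adhesion_depth = if (cl$has_adhesion) 100e-12 else 0,
          cell_id = cl$cell_id, patient_id = cl$patient_id
        )
        map <- generate_cell_map(cs)
        write_cell_map(map, file.path(maps_dir, cl$patient_id, cl$cell_id))
      }
    })
    log_msg("wrote %d cell maps under %s", nrow(cells), maps_dir)
    paths$maps <- maps_dir
  }
  invisible(paths)
}

pipeline_extract <- function(config, input, out_dir, log_msg) {
  if (is.null(input) || !dir.exists(input))
    abort("extract needs an input directory of curve files",
          class = "rbcmech_bad_input")
  files <- list.files(input, pattern = "\\.txt$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0)
    abort(sprintf("no curve files found under '%s'", input),
          class = "rbcmech_bad_input")
  excluded <- character(0)
  feats <- purrr::map(files, function(f) {
    tryCatch({
      cv <- read_fd_curve(f)
      extract_curve_features(detect_contact_point(cv, config$processing),
                             config$processing)
    }, error = function(e) {
      excluded <<- c(excluded, sprintf("%s\t%s", f, conditionMessage(e)))
      NULL
    })
  })
  features <- dplyr::bind_rows(feats)
  features_path <- file.path(out_dir, "features.csv")
  readr::write_csv(features, features_path)
  excl_path <- file.path(out_dir, "exclusions.log")
  writeLines(excluded, excl_path)
  log_msg("extracted %d of %d curves (%d excluded)", nrow(features),
          length(files), length(excluded))
  invisible(list(features = features_path, exclusions = excl_path))
}

pipeline_aggregate <- function(config, input, out_dir, log_msg) {
  fp <- file.path(input %||% ".", "features.csv")
  if (!file.exists(fp))
    abort("aggregate needs input/features.csv", class = "rbcmech_bad_input")
  features <- readr::read_csv(fp, show_col_types = FALSE, progress = FALSE)
  cells <- summarize_cells(features, config$aggregation)
  patients <- aggregate_patients(cells, config$aggregation)
  cells_path <- file.path(out_dir, "cell_means.csv")
  patients_path <- file.path(out_dir, "patients.csv")
  readr::write_csv(cells, cells_path)
  readr::write_csv(patients, patients_path)
  log_msg("aggregated %d pixels -> %d cells -> %d patients",
          nrow(features), nrow(cells), nrow(patients))
  invisible(list(cell_means = cells_path, patients = patients_path))
}

pipeline_stats <- function(config, input, out_dir, log_msg) {
  cp <- file.path(input %||% ".", "cohort.csv")
  if (!file.exists(cp))
    abort("stats needs input/cohort.csv", class = "rbcmech_bad_input")
  cohort <- readr::read_csv(cp, show_col_types = FALSE, progress = FALSE)
  cohort$group <- factor(cohort$group, levels = c("CTRL", "MC"))
  cohort$sex <- factor(cohort$sex)

  sm <- summarize_cohort(cohort, cfg = config$stats)
  summary_path <- file.path(out_dir, "summary.csv")
  readr::write_csv(as_tibble(sm), summary_path)

  auc_tbl <- dplyr::filter(as_tibble(sm),
                           .data$variable %in% config$auc_variables) %>%
    dplyr::select("variable", "auc", "auc_ci_low", "auc_ci_high")
  auc_path <- file.path(out_dir, "auc_table.csv")
  readr::write_csv(auc_tbl, auc_path)

  model1 <- fit_logistic(cohort, c("stiffness", "duration"),
                         scale = c(stiffness = 1000))
  model2 <- fit_logistic(cohort, c("stiffness", "rbc_count"),
                         scale = c(stiffness = 1000))
  candidates <- screen_candidates(
    cohort, vars = setdiff(names(cohort), c("patient_id", "group", "sex")),
    cfg = config$stats)
  selected <- if (length(candidates) > 0)
    stepwise_aic(cohort, candidates, scale = c(stiffness = 1000)) else NULL
  cv_acc <- loocv_accuracy(cohort, c("stiffness", "rbc_count"))
  models <- list(
    model1 = model_report(model1),
    model2 = model_report(model2),
    stepwise = if (!is.null(selected)) c(model_report(selected), list(
      candidates = candidates, selected = attr(selected, "selected"))),
    loocv = list(predictors = c("stiffness", "rbc_count"),
                 accuracy = as.numeric(cv_acc),
                 n = attr(cv_acc, "n"),
                 n_failed_folds = attr(cv_acc, "n_failed_folds")),
    seed = config$seed
  )
  models_path <- file.path(out_dir, "models.json")
  jsonlite::write_json(models, models_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  # pooled per-cell moduli when available, per-patient means otherwise
  cellp <- file.path(input %||% ".", "cells.csv")
  pooled <- if (file.exists(cellp)) {
    readr::read_csv(cellp, show_col_types = FALSE, progress = FALSE)
  } else {
    dplyr::select(cohort, "patient_id", "group", "youngs_modulus")
  }
  cf <- purrr::imap_dfr(split(pooled$youngs_modulus, pooled$group),
                        function(x, g) {
    r <- cullen_frey(x, n_boot = config$stats$n_boot, seed = config$seed)
    dplyr::bind_rows(
      tibble::tibble(group = g, kind = "observed",
                     skewness_sq = r$skewness_sq, kurtosis = r$kurtosis),
      dplyr::mutate(r$boot, group = g, kind = "bootstrap")
    )
  })
  cf_path <- file.path(out_dir, "cullen_frey.csv")
  readr::write_csv(cf, cf_path)
  log_msg("stats on %d patients: %d markers summarized, %d stepwise candidates",
          nrow(cohort), nrow(sm), length(candidates))
  invisible(list(summary = summary_path, auc_table = auc_path,
                 models = models_path, cullen_frey = cf_path))
}

model_report <- function(m) {
  list(predictors = m$predictors,
       coefficients = as.list(setNames(tidy(m)$estimate, tidy(m)$term)),
       p_values = as.list(setNames(tidy(m)$p.value, tidy(m)$term)),
       lr_chisq = m$lr_chisq, model_p = m$model_p,
       pseudo_r2 = m$pseudo_r2, aic = m$aic, n = m$n,
       scale = as.list(m$scale))
}

pipeline_report <- function(config, input, out_dir, log_msg) {
  arts <- pipeline_stats(config, input, out_dir, log_msg)
  report <- list(
    seed = config$seed,
    generated = "synthetic cohort analysis report",
    artifacts = purrr::map_chr(arts, basename),
    auc_variables = config$auc_variables
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE)
  log_msg("report written to %s", report_path)
  invisible(c(arts, list(report = report_path)))
}
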