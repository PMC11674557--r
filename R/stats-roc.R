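#' ROC-AUC with DeLong confidence interval
#'
#' Area under the ROC curve for a continuous marker against a binary label,
#' with the nonparametric DeLong variance estimate and normal-approximation
#' confidence interval. The AUC equals the Mann-Whitney probability that a
#' randomly chosen case exceeds a randomly chosen control, with half credit
#' for ties. The CI is compared with 0.5 (a random classifier) to flag
#' discriminative markers.
#'
#' @param values Numeric marker values.
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   higher/`TRUE` level is the case class).
#' @param direction `"auto"` (default) orients the marker so the AUC is the
#'   better of the two directions, as published biomarker tables do;
#'   `"<"` fixes AUC = P(case > control) (+ half ties); `">"` the reverse.
#' @param conf_level Confidence level for the CI.
#'
#' @return A one-row tibble: `auc`, `ci_low`, `ci_high`, `se`,
#'   `excludes_half`, `n_case`, `n_ctrl`, `direction`.
#' @export
#' @examples
#' roc_auc_delong(c(1, 3, 2, 4), c(0, 0, 1, 1), direction = "<")
roc_auc_delong <- function(values, labels, direction = c("auto", "<", ">"),
                           conf_level = 0.95) {
  direction <- match.arg(direction)
  lab <- as_binary_labels(labels)
  keep <- !is.na(values) & !is.na(lab)
  values <- values[keep]; lab <- lab[keep]
  if (length(unique(lab)) < 2)
    abort("both classes must be present", class = "rbcmech_degenerate_labels")
  r <- pROC::roc(response = lab, predictor = values,
                 levels = c(FALSE, TRUE), direction = pick_direction(values, lab, direction),
                 quiet = TRUE)
  # pROC warns when a separated marker makes the DeLong variance zero; the
  # degenerate CI it returns is the correct limit here
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong",
                                      conf.level = conf_level))
  auc <- as.numeric(pROC::auc(r))
  se <- suppressWarnings(sqrt(pROC::var(r)))
  tibble::tibble(
    auc = auc, ci_low = ci[1], ci_high = ci[3], se = se,
    excludes_half = ci[1] > 0.5 || ci[3] < 0.5,
    n_case = sum(lab), n_ctrl = sum(!lab),
    direction = r$direction
  )
}

pick_direction <- function(values, lab, direction) {
  if (direction != "auto") return(direction)
  # orient so the AUC is at least 0.5 (pair-counting comparison of the two
  # orientations, robust to median ties)
  a <- pair_auc(values, lab)
  if (a >= 0.5) "<" else ">"
}

# Mann-Whitney AUC with half tie credit: P(case > ctrl) + 0.5 P(case == ctrl)
pair_auc <- function(values, lab) {
  rk <- rank(values)
  n1 <- sum(lab); n0 <- sum(!lab)
  (sum(rk[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) > 2)
      abort("labels must have two levels", class = "rbcmech_degenerate_labels")
    return(labels == levels(droplevels(labels))[2])
  }
  u <- sort(unique(labels[!is.na(labels)]))
  if (length(u) > 2) abort("labels must be binary",
                           class = "rbcmech_degenerate_labels")
  labels == max(u)
}

#' Compare two ROC curves (DeLong test)
#'
#' Two-sided DeLong z-test for the difference between the AUCs of two
#' markers measured on the same patients (paired, default) or on independent
#' samples.
#'
#' @param values_a,values_b Marker values. For a paired comparison both must
#'   be measured on the same patients, in the same order as `labels`.
#' @param labels Binary labels shared by both markers.
#' @param paired Paired comparison (same patients) or unpaired.
#' @param direction Marker orientation, shared by both curves (the DeLong
#'   difference test requires a common direction); `"<"` means cases take
#'   larger values. Orient a down-going marker (e.g. RBC count) by negating
#'   it or passing `">"`.
#' @return A one-row tibble: `auc_a`, `auc_b`, `auc_difference`,
#'   `statistic`, `p_value`, `method`.
#' @export
compare_roc <- function(values_a, values_b, labels, paired = TRUE,
                        direction = "<") {
  lab <- as_binary_labels(labels)
  if (paired && (length(values_a) != length(values_b) ||
                 length(values_a) != length(lab)))
    abort("paired comparison requires markers and labels of equal length",
          class = "rbcmech_mismatched_index")
  keep <- !is.na(lab) & !is.na(values_a) & !is.na(values_b)
  ra <- pROC::roc(lab[keep], values_a[keep], levels = c(FALSE, TRUE),
                  direction = direction, quiet = TRUE)
  rb <- pROC::roc(lab[keep], values_b[keep], levels = c(FALSE, TRUE),
                  direction = direction, quiet = TRUE)
  da <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  tst <- tryCatch(
    pROC::roc.test(ra, rb, method = "delong", paired = paired),
    error = function(e) NULL
  )
  p <- if (is.null(tst) || !is.finite(tst$p.value)) {
    # identical markers: zero AUC difference with zero variance
    if (abs(da) < .Machine$double.eps^0.5) 1 else NA_real_
  } else tst$p.value
  stat <- if (is.null(tst)) NA_real_ else unname(tst$statistic)
  if (!is.finite(stat) && identical(p, 1)) stat <- 0
  tibble::tibble(auc_a = as.numeric(pROC::auc(ra)),
                 auc_b = as.numeric(pROC::auc(rb)),
                 auc_difference = da, statistic = stat, p_value = p,
                 method = paste0("DeLong ", if (paired) "paired " else "",
                                 "test"))
}
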