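#' Case-control marker summary table
#'
#' Per-variable group summaries and tests for a two-group cohort table:
#' continuous variables get group medians with interquartile range, the
#' case-minus-control median difference, a Wilcoxon-Mann-Whitney p-value
#' (exact when both groups together have at most 20 untied observations,
#' normal approximation with tie correction otherwise) and the DeLong
#' ROC-AUC with 95% CI; categorical variables get Fisher's exact test when
#' any expected cell count is below 5 and the chi-square test otherwise.
#' Missing values are dropped per variable (complete-case pairwise, valid
#' under missingness completely at random).
#'
#' @param data Cohort tibble, one row per patient, with a two-level group
#'   column.
#' @param group Name of the group column (factor; the `case` level is the
#'   pathological group).
#' @param case Level of `group` treated as the case class.
#' @param vars Variables to summarize; default all columns except the group
#'   and identifier columns (character/factor columns are treated as
#'   categorical).
#' @param cfg A [stats_config()].
#'
#' @return A tibble of class `marker_summary`: `variable`, `type`,
#'   `n_ctrl`, `n_case`, group medians and quartiles, `median_difference`,
#'   `p_value`, `test`, `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `auc_excludes_half`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' summarize_cohort(cohort)
summarize_cohort <- function(data, group = "group", case = "MC",
                             vars = NULL, cfg = stats_config()) {
  stopifnot(is.data.frame(data), group %in% names(data))
  g <- data[[group]]
  if (!case %in% g) abort("case level absent from group column",
                          class = "rbcmech_degenerate_labels")
  if (is.null(vars)) {
    vars <- setdiff(names(data), c(group, "patient_id", "cell_id", "curve_id"))
  }
  rows <- purrr::map(vars, function(v) {
    x <- data[[v]]
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]
    gi <- g[keep] == case
    if (length(unique(gi)) < 2 || sum(gi) < 2 || sum(!gi) < 2) {
      warn(sprintf("variable '%s' skipped: a group is empty after dropping missing values", v))
      return(NULL)
    }
    if (is.numeric(x)) {
      q_ctrl <- quantile(x[!gi], c(0.25, 0.5, 0.75), names = FALSE)
      q_case <- quantile(x[gi], c(0.25, 0.5, 0.75), names = FALSE)
      exact <- (length(x) <= 20) && !any(duplicated(x))
      p <- suppressWarnings(
        wilcox.test(x[gi], x[!gi], exact = exact, correct = TRUE)$p.value)
      roc <- roc_auc_delong(x, gi, conf_level = 1 - cfg$alpha)
      tibble::tibble(
        variable = v, type = "continuous",
        n_ctrl = sum(!gi), n_case = sum(gi),
        ctrl_median = q_ctrl[2], ctrl_q1 = q_ctrl[1], ctrl_q3 = q_ctrl[3],
        case_median = q_case[2], case_q1 = q_case[1], case_q3 = q_case[3],
        median_difference = q_case[2] - q_ctrl[2],
        p_value = p, test = "Wilcoxon rank sum",
        auc = roc$auc, auc_ci_low = roc$ci_low, auc_ci_high = roc$ci_high,
        auc_excludes_half = roc$excludes_half
      )
    } else {
      tab <- table(factor(gi, levels = c(FALSE, TRUE)), droplevels(factor(x)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- any(expected < 5)
      p <- if (use_fisher) fisher.test(tab)$p.value
           else suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
      tibble::tibble(
        variable = v, type = "categorical",
        n_ctrl = sum(!gi), n_case = sum(gi),
        ctrl_median = NA_real_, ctrl_q1 = NA_real_, ctrl_q3 = NA_real_,
        case_median = NA_real_, case_q1 = NA_real_, case_q3 = NA_real_,
        median_difference = NA_real_,
        p_value = p,
        test = if (use_fisher) "Fisher's exact" else "Pearson's chi-squared",
        auc = NA_real_, auc_ci_low = NA_real_, auc_ci_high = NA_real_,
        auc_excludes_half = NA
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("marker_summary", class(out))
  out
}

#' Z-score normalization of a cohort table
#'
#' Standardizes each numeric variable to zero mean and unit SD across all
#' patients (for heatmap display of heterogeneous panels); missing values
#' stay missing. Zero-variance variables become all-missing with a warning.
#'
#' @param data Cohort tibble.
#' @param vars Variables to normalize; default all numeric columns.
#' @return The tibble with the selected columns replaced by z-scores.
#' @export
zscore_normalize <- function(data, vars = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(vars)) vars <- names(data)[purrr::map_lgl(data, is.numeric)]
  out <- as_tibble(data)
  for (v in vars) {
    x <- out[[v]]
    if (sum(!is.na(x)) < 2) {
      warn(sprintf("variable '%s' has fewer than 2 observed values; left as is", v))
      next
    }
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warn(sprintf("variable '%s' has zero variance; set to missing", v))
      out[[v]] <- NA_real_
    } else {
      out[[v]] <- (x - mean(x, na.rm = TRUE)) / s
    }
  }
  out
}

#' Power-filtered Spearman correlation matrix
#'
#' Spearman rank correlations between two sets of variables (typically
#' mechanical vs demographic/biochemical), computed on pairwise-complete
#' observations. A pair is flagged `significant` only when (a) the two-sided
#' p-value is below `alpha` and (b) the pairwise sample size reaches the
#' target power to detect the observed correlation magnitude under the
#' Fisher-z approximation -- so that weak correlations which the sample
#' could not reliably detect are reported but not flagged.
#'
#' @param data Cohort tibble.
#' @param x_vars,y_vars Character vectors of variable names; every x-y pair
#'   is evaluated.
#' @param cfg A [stats_config()] (uses `alpha` and `power_target`).
#' @param min_n Minimum pairwise-complete observations; smaller pairs are
#'   skipped (`NA` rho).
#' @return A tibble: `x`, `y`, `n`, `rho`, `p_value`, `power`,
#'   `significant`.
#' @export
spearman_matrix <- function(data, x_vars, y_vars, cfg = stats_config(),
                            min_n = 5) {
  stopifnot(is.data.frame(data), all(c(x_vars, y_vars) %in% names(data)))
  grid <- tidyr::expand_grid(x = x_vars, y = y_vars)
  purrr::pmap_dfr(grid, function(x, y) {
    xv <- data[[x]]; yv <- data[[y]]
    keep <- !is.na(xv) & !is.na(yv)
    n <- sum(keep)
    if (n < min_n)
      return(tibble::tibble(x = x, y = y, n = n, rho = NA_real_,
                            p_value = NA_real_, power = NA_real_,
                            significant = FALSE))
    ct <- suppressWarnings(cor.test(xv[keep], yv[keep], method = "spearman",
                                    exact = FALSE))
    rho <- unname(ct$estimate)
    pw <- fisher_z_power(rho, n, cfg$alpha)
    tibble::tibble(x = x, y = y, n = n, rho = rho, p_value = ct$p.value,
                   power = pw,
                   significant = is.finite(ct$p.value) &&
                     ct$p.value < cfg$alpha && pw >= cfg$power_target)
  })
}

# power to detect a correlation of magnitude rho at two-sided alpha with n
# pairs, Fisher-z approximation
fisher_z_power <- function(rho, n, alpha = 0.05) {
  if (!is.finite(rho) || n < 4) return(NA_real_)
  r <- min(abs(rho), 0.999999)
  pnorm(sqrt(n - 3) * atanh(r) - qnorm(1 - alpha / 2))
}
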