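#' Logistic marker model for case-control status
#'
#' Maximum-likelihood logistic regression of case status on at most a
#' couple of markers -- with 16 cases, models with more than two predictors
#' are unreliable, so a warning is raised above two. Fitted on complete
#' cases. Reports Wald p-values per coefficient, the likelihood-ratio
#' chi-square against the null model with its p-value, McFadden's
#' pseudo-R-squared, AIC, and convergence/separation diagnostics.
#'
#' @param data Cohort tibble.
#' @param predictors Character vector of predictor columns.
#' @param response Name of the two-level response column.
#' @param case Level of `response` modelled as the event.
#' @param scale Optional named numeric vector of multipliers applied to
#'   predictors before fitting (e.g. `c(stiffness = 1000)` to express a
#'   stiffness coefficient per mN/m instead of per N/m).
#'
#' @return An object of class `mc_logistic` with [tidy()], [glance()],
#'   [predict()] and [print()] methods.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 3))
#' m <- fit_logistic(cohort, c("stiffness", "rbc_count"),
#'                   scale = c(stiffness = 1000))
#' tidy(m)
#' glance(m)
fit_logistic <- function(data, predictors, response = "group", case = "MC",
                         scale = NULL) {
  stopifnot(is.data.frame(data), all(predictors %in% names(data)),
            response %in% names(data))
  if (length(predictors) > 2)
    warn("more than two predictors for a small case-control sample; interpret with caution")
  df <- as_tibble(data)[, c(response, predictors)]
  df <- df[complete.cases(df), ]
  y <- as_binary_labels(if (is.factor(df[[response]]) || is.character(df[[response]]))
    factor(df[[response]]) == case else df[[response]])
  if (length(unique(y)) < 2)
    abort("both classes must be present", class = "rbcmech_degenerate_labels")
  X <- df[, predictors, drop = FALSE]
  if (!is.null(scale)) {
    for (v in names(scale)) if (v %in% names(X)) X[[v]] <- X[[v]] * scale[[v]]
  }
  fd <- dplyr::bind_cols(tibble::tibble(.case = as.numeric(y)), X)
  fit <- suppressWarnings(
    glm(stats::reformulate(predictors, ".case"), data = fd,
        family = binomial()))
  null_fit <- glm(.case ~ 1, data = fd, family = binomial())
  separated <- any(abs(predict(fit, type = "link")) > 15)
  lr <- as.numeric(2 * (logLik(fit) - logLik(null_fit)))
  structure(list(
    fit = fit,
    predictors = predictors,
    response = response,
    case = case,
    scale = scale,
    n = nrow(fd),
    n_case = sum(y),
    lr_chisq = lr,
    model_p = pchisq(lr, df = length(predictors), lower.tail = FALSE),
    pseudo_r2 = 1 - as.numeric(logLik(fit)) / as.numeric(logLik(null_fit)),
    aic = AIC(fit),
    converged = fit$converged,
    separated = separated
  ), class = "mc_logistic")
}

#' @export
print.mc_logistic <- function(x, ...) {
  cat("<mc_logistic>", x$response, "~",
      paste(x$predictors, collapse = " + "), "\n")
  cat(sprintf("  n = %d (%d cases); LR chi2 = %.3f (p = %.4g); McFadden R2 = %.3f; AIC = %.2f\n",
              x$n, x$n_case, x$lr_chisq, x$model_p, x$pseudo_r2, x$aic))
  if (x$separated) cat("  warning: quasi-complete separation detected\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a logistic marker model
#'
#' @param x An `mc_logistic` object.
#' @param exponentiate Report odds ratios instead of log-odds coefficients.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (and `odds_ratio` columns when `exponentiate = TRUE`).
#' @method tidy mc_logistic
#' @export
tidy.mc_logistic <- function(x, exponentiate = FALSE, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                        std.error = sm[, 2], statistic = sm[, 3],
                        p.value = sm[, 4])
  if (exponentiate) {
    out$odds_ratio <- exp(out$estimate)
    out$or_ci_low <- exp(out$estimate - qnorm(0.975) * out$std.error)
    out$or_ci_high <- exp(out$estimate + qnorm(0.975) * out$std.error)
  }
  out
}

#' One-row summary of a logistic marker model
#'
#' @param x An `mc_logistic` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_case`, `lr_chisq`, `model_p`,
#'   `pseudo_r2` (McFadden), `aic`, `converged`, `separated`.
#' @method glance mc_logistic
#' @export
glance.mc_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, n_case = x$n_case, lr_chisq = x$lr_chisq,
                 model_p = x$model_p, pseudo_r2 = x$pseudo_r2, aic = x$aic,
                 converged = x$converged, separated = x$separated)
}

#' @export
predict.mc_logistic <- function(object, newdata = NULL,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(predict(object$fit, type = type))
  nd <- as_tibble(newdata)
  if (!is.null(object$scale)) {
    for (v in names(object$scale))
      if (v %in% names(nd)) nd[[v]] <- nd[[v]] * object$scale[[v]]
  }
  predict(object$fit, newdata = nd, type = type)
}

#' Published reference coefficients for the bivariate marker models
#'
#' Log-odds coefficients of the two reference bivariate logistic models for
#' microvascular-complication status in type 1 diabetes: model 1 adjusts
#' AFM stiffness (per mN/m) for disease duration; model 2 combines AFM
#' stiffness with RBC count -- the pair selected by stepwise AIC -- and is
#' the basis of the bivariate probability function used by
#' [predict_mc_probability()].
#'
#' @return A tibble: `model`, `term`, `estimate`, `unit`.
#' @export
reference_model_coefficients <- function() {
  tibble::tibble(
    model = c(1, 1, 1, 2, 2, 2),
    term = c("stiffness", "duration", "(Intercept)",
             "stiffness", "rbc_count", "(Intercept)"),
    estimate = c(1.09, 0.027, -3.82, 1.14, -2.29, 7.84),
    unit = c("per mN/m", "per year", "log-odds",
             "per mN/m", "per 1e12/L", "log-odds")
  )
}

#' Bivariate probability of microvascular complications
#'
#' Evaluates the reference bivariate logistic probability function of
#' carrying microvascular complications from joint measurements of AFM
#' stiffness and RBC count:
#' `p = plogis(1142.357 * stiffness[N/m] - 2.294652 * rbc[1e12/L])`.
#' The published closed-form function carries no intercept; the fitted
#' reference model's intercept (7.84) can be added with
#' `include_intercept = TRUE`. The probability is strictly increasing in
#' stiffness and strictly decreasing in RBC count.
#'
#' @param stiffness AFM stiffness (N/m).
#' @param rbc_count RBC count (1e12/L).
#' @param include_intercept Add the fitted intercept term.
#' @return Probability in (0, 1), vectorized over the inputs.
#' @export
#' @examples
#' predict_mc_probability(0.0027, 4.67)
predict_mc_probability <- function(stiffness, rbc_count,
                                   include_intercept = FALSE) {
  stopifnot(is.numeric(stiffness), is.numeric(rbc_count))
  eta <- 1142.357 * stiffness - 2.294652 * rbc_count +
    if (include_intercept) 7.84 else 0
  plogis(eta)
}

#' Univariate screening of stepwise candidates
#'
#' Returns the continuous variables whose univariate case-control p-value
#' (Wilcoxon) falls below the screening threshold, the entry rule for the
#' stepwise model search.
#'
#' @inheritParams summarize_cohort
#' @param cfg A [stats_config()] (uses `screen_alpha`).
#' @return Character vector of candidate variable names.
#' @export
screen_candidates <- function(data, group = "group", case = "MC",
                              vars = NULL, cfg = stats_config()) {
  sm <- summarize_cohort(data, group = group, case = case, vars = vars,
                         cfg = cfg)
  sm$variable[sm$type == "continuous" & !is.na(sm$p_value) &
                sm$p_value < cfg$screen_alpha]
}

#' Stepwise AIC model selection
#'
#' Backward-forward stepwise logistic regression minimizing AIC, starting
#' from the full model on all candidate markers (those passing the
#' univariate p < 0.25 screen). Deterministic given a fixed candidate
#' ordering; a move is only taken when it strictly lowers the AIC, so ties
#' resolve toward the smaller model.
#'
#' @inheritParams fit_logistic
#' @param candidates Candidate predictor names (see [screen_candidates()]).
#' @return An `mc_logistic` for the selected model.
#' @export
stepwise_aic <- function(data, candidates, response = "group", case = "MC",
                         scale = NULL) {
  if (length(candidates) == 0)
    abort("empty candidate set", class = "rbcmech_empty_candidates")
  df <- as_tibble(data)[, c(response, candidates)]
  df <- df[complete.cases(df), ]
  y <- as_binary_labels(if (is.factor(df[[response]]) || is.character(df[[response]]))
    factor(df[[response]]) == case else df[[response]])
  fd <- dplyr::bind_cols(tibble::tibble(.case = as.numeric(y)),
                         df[, candidates, drop = FALSE])
  full <- suppressWarnings(glm(stats::reformulate(candidates, ".case"),
                               data = fd, family = binomial()))
  sel <- suppressWarnings(step(full, direction = "both", trace = 0,
                               scope = list(lower = .case ~ 1)))
  kept <- setdiff(attr(stats::terms(sel), "term.labels"), character(0))
  if (length(kept) == 0) kept <- character(0)
  out <- if (length(kept) == 0) {
    warn("stepwise selection kept no predictor; returning intercept-only summary")
    structure(list(fit = sel, predictors = character(0), response = response,
                   case = case, scale = scale, n = nrow(fd), n_case = sum(y),
                   lr_chisq = 0, model_p = 1, pseudo_r2 = 0, aic = AIC(sel),
                   converged = sel$converged, separated = FALSE),
              class = "mc_logistic")
  } else {
    fit_logistic(dplyr::bind_cols(df[response], df[kept]), kept,
                 response = response, case = case, scale = scale)
  }
  attr(out, "candidates") <- candidates
  attr(out, "selected") <- kept
  out
}

#' Leave-one-out cross-validated accuracy
#'
#' Refits the logistic model on every leave-one-out subset, predicts the
#' held-out patient at a 0.5 probability threshold, and reports the
#' fraction classified correctly. Deterministic given the table. Folds on
#' which the refit fails are flagged, excluded, and counted in the
#' `n_failed_folds` attribute.
#'
#' @inheritParams fit_logistic
#' @param threshold Probability threshold for classifying a case.
#' @return Accuracy in `[0, 1]` with attributes `n` and `n_failed_folds`.
#' @export
loocv_accuracy <- function(data, predictors, response = "group", case = "MC",
                           threshold = 0.5) {
  df <- as_tibble(data)[, c(response, predictors)]
  df <- df[complete.cases(df), ]
  n <- nrow(df)
  if (n < 10) abort("need at least 10 complete cases for LOOCV",
                    class = "rbcmech_insufficient_data")
  y <- as_binary_labels(if (is.factor(df[[response]]) || is.character(df[[response]]))
    factor(df[[response]]) == case else df[[response]])
  fd <- dplyr::bind_cols(tibble::tibble(.case = as.numeric(y)),
                         df[, predictors, drop = FALSE])
  fml <- stats::reformulate(predictors, ".case")
  correct <- logical(n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      suppressWarnings(glm(fml, data = fd[-i, ], family = binomial())),
      error = function(e) NULL)
    if (is.null(fit_i) || !fit_i$converged) {
      failed[i] <- TRUE
      next
    }
    p_i <- predict(fit_i, newdata = fd[i, ], type = "response")
    correct[i] <- (p_i >= threshold) == (fd$.case[i] == 1)
  }
  acc <- mean(correct[!failed])
  structure(acc, n = n, n_failed_folds = sum(failed))
}
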