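# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and pROC/stats shortcuts) so that agreement is
# evidence, not circularity.

# AUC by exhaustive pair counting: P(case > control) + 0.5 P(tie)
brute_force_auc <- function(values, labels) {
  cases <- values[as.logical(labels)]
  ctrls <- values[!as.logical(labels)]
  total <- 0
  for (a in cases) for (b in ctrls) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(cases) * length(ctrls))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(m+n, m) assignments of the pooled ranks (untied data only)
enum_wilcoxon_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  w_all <- apply(combos, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  mu <- m * (length(y)) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# two-level mean recomputed from raw pixels: mean over cells of the mean
# over that cell's pixels (cells weighted equally)
brute_force_two_level_mean <- function(pixel_values, cell_ids) {
  cell_means <- tapply(pixel_values, cell_ids, mean, na.rm = TRUE)
  mean(cell_means)
}

# closed-form moments of the log-normal: skewness and non-excess kurtosis
lognormal_moments <- function(sigma) {
  w <- exp(sigma^2)
  list(skewness = (w + 2) * sqrt(w - 1),
       kurtosis = w^4 + 2 * w^3 + 3 * w^2 - 3)
}

# default-parameter noiseless test curves
sneddon_curve <- function(modulus = 1500, ...) {
  generate_curve(curve_spec(true_modulus = modulus, noise_sd = 0, ...))
}

slope_curve <- function(slope = 0.00123, ...) {
  generate_curve(curve_spec(linear_slope = slope, noise_sd = 0, ...))
}

# small cohort table with a known single informative predictor
informative_table <- function(n = 500, beta = 2, n_noise = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (n_noise + 1)), ncol = n_noise + 1)
    colnames(x) <- c("signal", paste0("noise", seq_len(n_noise)))
    p <- plogis(beta * x[, "signal"])
    tibble::tibble(group = factor(ifelse(runif(n) < p, "MC", "CTRL"),
                                  levels = c("CTRL", "MC"))) |>
      dplyr::bind_cols(tibble::as_tibble(x))
  })
}
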