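test_that("a constant predictor explains nothing", {
  tab <- tibble::tibble(
    group = factor(rep(c("CTRL", "MC"), 25), levels = c("CTRL", "MC")),
    flat = rep(10, 50)
  )
  m <- fit_logistic(tab, "flat")
  expect_lt(abs(glance(m)$pseudo_r2), 1e-8)
  expect_lt(abs(glance(m)$lr_chisq), 1e-8)
})

test_that("model scaling reports stiffness per mN/m", {
  co <- generate_cohort(cohort_spec(seed = 31))
  m_si <- fit_logistic(co, c("stiffness", "rbc_count"))
  m_mn <- fit_logistic(co, c("stiffness", "rbc_count"),
                       scale = c(stiffness = 1000))
  b_si <- tidy(m_si)$estimate[tidy(m_si)$term == "stiffness"]
  b_mn <- tidy(m_mn)$estimate[tidy(m_mn)$term == "stiffness"]
  expect_equal(b_si, b_mn * 1000, tolerance = 1e-6)
  # scaling a predictor changes neither fit nor discrimination
  expect_equal(glance(m_si)$pseudo_r2, glance(m_mn)$pseudo_r2,
               tolerance = 1e-9)
})

test_that("the bivariate probability function behaves like a logistic surface", {
  expect_equal(predict_mc_probability(1, 4.67), 1, tolerance = 1e-6)
  expect_lt(predict_mc_probability(0, 100), 1e-6)
  # complement symmetry of the logistic
  p <- predict_mc_probability(0.0025, 4.8)
  p_comp <- plogis(-(1142.357 * 0.0025 - 2.294652 * 4.8))
  expect_equal(p + p_comp, 1, tolerance = 1e-12)
  # strictly increasing in stiffness, decreasing in RBC count
  s <- seq(0.001, 0.005, length.out = 20)
  expect_true(all(diff(predict_mc_probability(s, 4.8)) > 0))
  r <- seq(4, 6, length.out = 20)
  expect_true(all(diff(predict_mc_probability(0.0025, r)) < 0))
  # hand-evaluated oracle at the group medians: the pathological-median
  # point scores strictly higher than the control-median point
  p_mc <- exp(1142.357 * 0.0027 - 2.294652 * 4.67) /
    (1 + exp(1142.357 * 0.0027 - 2.294652 * 4.67))
  p_ctrl <- exp(1142.357 * 0.0021 - 2.294652 * 5.06) /
    (1 + exp(1142.357 * 0.0021 - 2.294652 * 5.06))
  expect_equal(predict_mc_probability(0.0027, 4.67), p_mc, tolerance = 1e-12)
  expect_equal(predict_mc_probability(0.0021, 5.06), p_ctrl, tolerance = 1e-12)
  expect_gt(p_mc, p_ctrl)
  # the printed function and the fitted reference model agree on units
  ref <- reference_model_coefficients()
  expect_equal(round(1142.357 / 1000, 2),
               ref$estimate[ref$model == 2 & ref$term == "stiffness"])
})

test_that("stepwise selection keeps the informative variable and never worsens AIC", {
  tab <- informative_table(n = 500, beta = 2, seed = 5)
  sel <- suppressWarnings(
    stepwise_aic(tab, c("signal", "noise1", "noise2", "noise3")))
  expect_true("signal" %in% attr(sel, "selected"))

  # all-noise candidates: selected AIC cannot exceed the full model's
  withr::with_seed(9, {
    noise_tab <- tibble::tibble(
      group = factor(rep(c("CTRL", "MC"), 250), levels = c("CTRL", "MC")),
      a = rnorm(500), b = rnorm(500), c = rnorm(500)
    )
  })
  full <- suppressWarnings(fit_logistic(noise_tab, c("a", "b", "c")))
  sel2 <- suppressWarnings(stepwise_aic(noise_tab, c("a", "b", "c")))
  expect_lte(glance(sel2)$aic, glance(full)$aic + 1e-9)

  expect_error(stepwise_aic(noise_tab, character(0)),
               class = "rbcmech_empty_candidates")
})

test_that("stepwise overselection of noise matches AIC theory", {
  # each pure-noise candidate survives with asymptotic probability
  # P(chi2_1 > 2) ~ 0.157, so the exactly-the-signal rate over 3 noise
  # candidates sits near 0.843^3 ~ 0.60 -- a property of AIC, not a defect
  exact <- vapply(1:100, function(s) {
    tab <- informative_table(n = 500, beta = 2, seed = 2000 + s)
    sel <- suppressWarnings(
      stepwise_aic(tab, c("signal", "noise1", "noise2", "noise3")))
    identical(attr(sel, "selected"), "signal")
  }, logical(1))
  expect_gt(mean(exact), 0.4)
  expect_lt(mean(exact), 0.8)
})

test_that("candidate screening applies the univariate p threshold", {
  tab <- informative_table(n = 300, beta = 2, seed = 8)
  cands <- screen_candidates(tab, vars = c("signal", "noise1", "noise2",
                                           "noise3"))
  expect_true("signal" %in% cands)
  sm <- summarize_cohort(tab, vars = c("signal", "noise1", "noise2", "noise3"))
  expect_setequal(cands, sm$variable[sm$p_value < 0.25])
})

test_that("LOOCV is exact on a hand-traceable table and cross-checks cv.glm", {
  # perfectly separable: every fold classifies its held-out patient right
  sep <- tibble::tibble(
    group = factor(rep(c("CTRL", "MC"), each = 10), levels = c("CTRL", "MC")),
    x = c(rnorm(10, -5, 0.1), rnorm(10, 5, 0.1))
  )
  expect_equal(as.numeric(loocv_accuracy(sep, "x")), 1.0)

  # explicit manual loop oracle on a small non-separable table
  withr::with_seed(4, {
    tab <- tibble::tibble(
      group = factor(rep(c("CTRL", "MC"), 10), levels = c("CTRL", "MC")),
      x = rnorm(20) + 0.8 * rep(c(0, 1), 10)
    )
  })
  manual <- vapply(seq_len(nrow(tab)), function(i) {
    fit <- glm(I(group == "MC") ~ x, data = tab[-i, ], family = binomial())
    p <- predict(fit, newdata = tab[i, ], type = "response")
    (p >= 0.5) == (tab$group[i] == "MC")
  }, logical(1))
  expect_equal(as.numeric(loocv_accuracy(tab, "x")), mean(manual))

  # independent implementation: boot::cv.glm with a 0.5-threshold cost
  skip_if_not_installed("boot")
  df <- data.frame(y = as.numeric(tab$group == "MC"), x = tab$x)
  fit <- glm(y ~ x, data = df, family = binomial())
  cost <- function(r, pi) mean((pi >= 0.5) == r)
  cv <- boot::cv.glm(df, fit, cost = cost, K = nrow(df))
  expect_equal(as.numeric(loocv_accuracy(tab, "x")), cv$delta[1],
               tolerance = 1e-9)

  # labels independent of the predictor: accuracy near the majority rate
  accs <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      null_tab <- tibble::tibble(
        group = factor(rep(c("CTRL", "MC"), c(120, 80)),
                       levels = c("CTRL", "MC")),
        x = rnorm(200)
      )
    })
    as.numeric(loocv_accuracy(null_tab, "x"))
  }, numeric(1))
  expect_equal(mean(accs), 0.6, tolerance = 0.1)

  expect_error(loocv_accuracy(sep[1:5, ], "x"),
               class = "rbcmech_insufficient_data")
})
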