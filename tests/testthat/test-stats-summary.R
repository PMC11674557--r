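make_table <- function(ctrl, mc) {
  tibble::tibble(
    group = factor(rep(c("CTRL", "MC"), c(length(ctrl), length(mc))),
                   levels = c("CTRL", "MC")),
    marker = c(ctrl, mc)
  )
}

test_that("Wilcoxon summary handles identical and separated samples", {
  same <- make_table(c(1, 2, 3, 4), c(1, 2, 3, 4))
  sm <- summarize_cohort(same, vars = "marker")
  expect_equal(sm$p_value, 1)
  expect_equal(sm$median_difference, 0)

  sep <- make_table(c(1, 2, 3), c(4, 5, 6))
  sm2 <- summarize_cohort(sep, vars = "marker")
  expect_equal(sm2$p_value, 0.1)
  expect_equal(sm2$median_difference, 3)
  expect_equal(sm2$auc, 1)
})

test_that("small-sample Wilcoxon p equals the full rank enumeration", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      m <- sample(3:6, 1); n <- sample(3:6, 1)
      x <- round(rnorm(m), 6); y <- round(rnorm(n, 0.5), 6)
      sm <- summarize_cohort(make_table(x, y), vars = "marker")
      expect_equal(sm$p_value, enum_wilcoxon_p(y, x), tolerance = 1e-10)
    }
  })
})

test_that("categorical variables route to Fisher or chi-square", {
  tab <- tibble::tibble(
    group = factor(rep(c("CTRL", "MC"), c(22, 16)), levels = c("CTRL", "MC")),
    sex = factor(c(rep("F", 4), rep("M", 18), rep("F", 5), rep("M", 11)))
  )
  sm <- summarize_cohort(tab, vars = "sex")
  expect_equal(sm$type, "categorical")
  expect_equal(sm$test, "Fisher's exact")
  expect_equal(sm$p_value,
               fisher.test(table(tab$group, tab$sex))$p.value)
})

test_that("variables with an empty group are skipped with a warning", {
  tab <- make_table(c(1, 2, 3), c(4, 5, 6))
  tab$broken <- c(1, 2, 3, NA, NA, NA)
  expect_warning(sm <- summarize_cohort(tab, vars = c("marker", "broken")),
                 "skipped")
  expect_equal(sm$variable, "marker")
})

test_that("z-score normalization standardizes and preserves missingness", {
  tab <- tibble::tibble(a = c(1, 2, 3), b = c(5, NA, 9), c = c(2, 2, 2))
  expect_warning(z <- zscore_normalize(tab), "zero variance")
  expect_equal(z$a, c(-1, 0, 1))
  expect_true(is.na(z$b[2]))
  expect_equal(mean(z$b, na.rm = TRUE), 0)
  expect_equal(sd(z$b, na.rm = TRUE), 1)
  expect_true(all(is.na(z$c)))
})

test_that("Spearman rho matches hand computation and the power filter works", {
  x <- 1:10
  sp1 <- spearman_matrix(tibble::tibble(x = x, y = x^2), "x", "y")
  expect_equal(sp1$rho, 1)
  sp2 <- spearman_matrix(tibble::tibble(x = x, y = rev(x)), "x", "y")
  expect_equal(sp2$rho, -1)

  # 6-point table, untied: rho = 1 - 6 sum(d^2) / (n (n^2 - 1))
  xv <- c(3, 1, 4, 9, 2, 6); yv <- c(10, 4, 6, 8, 2, 9)
  d <- rank(xv) - rank(yv)
  rho_oracle <- 1 - 6 * sum(d^2) / (6 * 35)
  sp3 <- spearman_matrix(tibble::tibble(x = xv, y = yv), "x", "y")
  expect_equal(sp3$rho, rho_oracle)

  # a weak correlation at tiny n cannot be powered, hence never flagged
  withr::with_seed(1, {
    tab <- tibble::tibble(x = rnorm(8), y = rnorm(8))
  })
  sp4 <- spearman_matrix(tab, "x", "y")
  expect_false(sp4$significant)

  # pairs below the minimum n are skipped
  sp5 <- spearman_matrix(tibble::tibble(x = c(1, 2, 3, NA, NA, NA),
                                        y = c(2, 1, 3, 4, 5, 6)), "x", "y")
  expect_true(is.na(sp5$rho))
})
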