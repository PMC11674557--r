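test_that("shape statistics hit the normal limit and the log-normal closed form", {
  withr::with_seed(1, x <- rnorm(2e5))
  expect_equal(sample_skewness(x)^2, 0, tolerance = 5e-3)
  expect_equal(sample_kurtosis(x), 3, tolerance = 0.05)

  withr::with_seed(2, y <- rlnorm(2e4, 0, 0.5))
  mom <- lognormal_moments(0.5)
  expect_equal(sample_skewness(y), mom$skewness, tolerance = 0.1)
  expect_equal(sample_kurtosis(y), mom$kurtosis, tolerance = 0.2)
})

test_that("shape estimators agree with independent implementations", {
  skip_if_not_installed("e1071")
  withr::with_seed(3, x <- rlnorm(500, 0, 0.4))
  expect_equal(sample_skewness(x), e1071::skewness(x, type = 1),
               tolerance = 1e-12)
  expect_equal(sample_kurtosis(x), e1071::kurtosis(x, type = 1) + 3,
               tolerance = 1e-12)
})

test_that("the bootstrap cloud is seeded, attainable and sized as requested", {
  withr::with_seed(4, x <- rlnorm(300, 0, 0.4))
  a <- cullen_frey(x, n_boot = 250, seed = 10)
  b <- cullen_frey(x, n_boot = 250, seed = 10)
  expect_identical(a$boot, b$boot)
  expect_equal(nrow(a$boot), 250)
  # every sample satisfies kurtosis >= skewness^2 + 1
  expect_true(all(a$boot$kurtosis >= a$boot$skewness_sq + 1 - 1e-9))
  expect_gte(a$kurtosis, a$skewness_sq + 1)

  c <- cullen_frey(x, n_boot = 250, seed = 11)
  expect_false(identical(a$boot, c$boot))
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(cullen_frey(rep(1, 100)), class = "rbcmech_degenerate_data")
  expect_warning(cullen_frey(rnorm(20), n_boot = 200), "fewer than 30")
})

test_that("observed point matches the descdist reference implementation", {
  skip_if_not_installed("fitdistrplus")
  withr::with_seed(5, x <- rlnorm(400, 0, 0.5))
  ref <- fitdistrplus::descdist(x, method = "sample", boot = NULL,
                                graph = FALSE)
  cf <- cullen_frey(x, n_boot = 200, seed = 1)
  expect_equal(cf$skewness_sq, unname(ref$skewness)^2, tolerance = 1e-10)
  expect_equal(cf$kurtosis, unname(ref$kurtosis), tolerance = 1e-10)
})

test_that("pooled cohort moduli land near the log-normal locus", {
  co <- generate_cohort(cohort_spec(seed = 17))
  cells <- attr(co, "cells")
  by_group <- split(cells$youngs_modulus, cells$group)
  cfs <- lapply(by_group, cullen_frey, n_boot = 200, seed = 2)
  for (cf in cfs) {
    # right-skewed, leptokurtic: in the lower-right region of the plane,
    # near the log-normal curve rather than the normal point
    expect_gt(cf$skewness_sq, 0.05)
    expect_gt(cf$kurtosis, 3)
    sig <- seq(0.05, 1.5, length.out = 400)
    w <- exp(sig^2)
    locus_k <- w^4 + 2 * w^3 + 3 * w^2 - 3
    locus_s2 <- ((w + 2) * sqrt(w - 1))^2
    dist <- min(abs(locus_k[which.min(abs(locus_s2 - cf$skewness_sq))] -
                      cf$kurtosis))
    expect_lt(dist / cf$kurtosis, 0.5)
  }
})
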