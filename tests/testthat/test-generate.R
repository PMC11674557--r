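test_that("curve generation is seeded and reproducible", {
  a <- generate_curve(curve_spec(noise_sd = 5e-12, seed = 11))
  b <- generate_curve(curve_spec(noise_sd = 5e-12, seed = 11))
  c <- generate_curve(curve_spec(noise_sd = 5e-12, seed = 12))
  expect_identical(a$approach, b$approach)
  expect_identical(a$retract, b$retract)
  expect_false(identical(a$approach$force, c$approach$force))
})

test_that("generated curves satisfy the acquisition invariants", {
  for (E in c(500, 1500, 5000)) {
    fd <- sneddon_curve(E)
    expect_gte(nrow(fd$approach), 50)
    expect_gte(nrow(fd$retract), 50)
    expect_true(all(diff(fd$approach$piezo_height) < 0))
    expect_true(all(is.finite(fd$approach$force)))
    # reaches the 2 nN setpoint
    expect_equal(max(fd$approach$force), fd$metadata$setpoint_force,
                 tolerance = 1e-6)
  }
})

test_that("map generator produces an 8x8 grid with a plausible footprint", {
  m <- generate_cell_map(curve_spec(), seed = 3)
  expect_equal(nrow(m), 64)
  expect_equal(sort(unique(m$row)), 1:8)
  # the cap covers part but not all of the scan
  expect_gt(sum(m$is_cell_truth), 8)
  expect_lt(sum(m$is_cell_truth), 64)
  # apex pixel reaches the nominal height
  expect_equal(max(m$truth_height), 2.64e-6, tolerance = 1e-9)
  # zero-height cap means an all-substrate map
  flat <- generate_cell_map(curve_spec(), apex_height = 0, seed = 3)
  expect_true(all(!flat$is_cell_truth))
  expect_error(generate_cell_map(curve_spec(), cell_radius = 7e-6),
               class = "rbcmech_footprint_overflow")
})

test_that("cohort medians converge to the calibration targets", {
  spec <- cohort_spec(n_ctrl = 10000, n_mc = 10000, cells_per_patient = 1,
                      missing_rate = 0, seed = 99)
  co <- generate_cohort(spec)
  tg <- default_cohort_targets()
  for (v in c("stiffness", "rbc_count", "triglycerides", "youngs_modulus")) {
    row <- tg[tg$variable == v, ]
    expect_equal(median(co[[v]][co$group == "CTRL"]), row$ctrl_median,
                 tolerance = 0.02)
    expect_equal(median(co[[v]][co$group == "MC"]), row$mc_median,
                 tolerance = 0.02)
  }
})

test_that("per-group modulus distribution matches the specified log-normal", {
  spec <- cohort_spec(n_ctrl = 5000, n_mc = 2, cells_per_patient = 1,
                      missing_rate = 0, seed = 7)
  co <- generate_cohort(spec)
  tg <- default_cohort_targets()
  row <- tg[tg$variable == "youngs_modulus", ]
  sdlog <- log(row$ctrl_q3 / row$ctrl_q1) / (2 * qnorm(0.75))
  ks <- suppressWarnings(stats::ks.test(co$youngs_modulus[co$group == "CTRL"],
                                        "plnorm", log(row$ctrl_median), sdlog))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("missingness control works and is completely at random", {
  none <- generate_cohort(cohort_spec(missing_rate = 0, seed = 1))
  expect_false(anyNA(dplyr::select(none, -"patient_id")))
  some <- generate_cohort(cohort_spec(missing_rate = 0.15, seed = 1))
  biochem <- default_cohort_targets()$variable[default_cohort_targets()$missing_ok]
  n_missing <- sum(is.na(dplyr::select(some, dplyr::all_of(biochem))))
  expect_gt(n_missing, 0)
  # mechanics and grouping stay complete
  expect_false(anyNA(some$stiffness))
  expect_false(anyNA(some$group))
})

test_that("the default cohort has useful power on the stiffness marker", {
  # at the calibrated 22/16 design the group stiffness difference should be
  # detected by the Wilcoxon test in a majority of replicates
  rej <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_spec(seed = 5000 + s, cells_per_patient = 1))
    suppressWarnings(wilcox.test(stiffness ~ group, data = co)$p.value) < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
})

test_that("cohort generation is reproducible and group effects point the right way", {
  a <- generate_cohort(cohort_spec(seed = 21))
  b <- generate_cohort(cohort_spec(seed = 21))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "cells"), attr(b, "cells"))
  big <- generate_cohort(cohort_spec(n_ctrl = 2000, n_mc = 2000,
                                     cells_per_patient = 1, seed = 2))
  med <- function(v, g) median(big[[v]][big$group == g], na.rm = TRUE)
  expect_gt(med("stiffness", "MC"), med("stiffness", "CTRL"))
  expect_lt(med("rbc_count", "MC"), med("rbc_count", "CTRL"))
  expect_gt(med("triglycerides", "MC"), med("triglycerides", "CTRL"))
})
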