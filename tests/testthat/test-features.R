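test_that("Sneddon fit recovers the generating modulus and scales linearly", {
  p <- detect_contact_point(sneddon_curve(1500))
  expect_equal(as.numeric(fit_sneddon(p)), 1500, tolerance = 1e-3)

  p2 <- detect_contact_point(sneddon_curve(3000))
  expect_equal(as.numeric(fit_sneddon(p2)) / as.numeric(fit_sneddon(p)), 2,
               tolerance = 1e-3)
})

test_that("Sneddon fit is unbiased under force noise", {
  fits <- vapply(1:50, function(s) {
    fd <- generate_curve(curve_spec(true_modulus = 1500, noise_sd = 5e-12,
                                    seed = s))
    as.numeric(fit_sneddon(detect_contact_point(fd)))
  }, numeric(1))
  expect_equal(mean(fits), 1500, tolerance = 0.05)
})

test_that("Sneddon fit errors are classed and informative", {
  p <- detect_contact_point(sneddon_curve(1500))
  expect_error(fit_sneddon(p, force_window = c(1.9e-9, 1.91e-9)),
               class = "rbcmech_insufficient_window")
})

test_that("stiffness slope is exact on an exact line and matches a quadrature oracle", {
  p <- detect_contact_point(slope_curve(0.00123))
  expect_equal(as.numeric(fit_stiffness_slope(p)), 0.00123, tolerance = 1e-9)

  for (s in c(5e-4, 2e-3, 8e-3)) {
    ps <- detect_contact_point(slope_curve(s))
    expect_equal(as.numeric(fit_stiffness_slope(ps)), s, tolerance = 1e-9)
  }

  # pure parabola: compare with the continuous-limit OLS slope over the
  # window, computed by dense numerical quadrature
  fd <- generate_curve(curve_spec(true_modulus = 1500, noise_sd = 0,
                                  samples_per_segment = 4000))
  p2 <- detect_contact_point(fd)
  s_fit <- as.numeric(fit_stiffness_slope(p2))
  cfg <- processing_config()
  coef <- 2 * 1500 * tan(20 * pi / 180) / (pi * (1 - 0.25))
  d1 <- sqrt(cfg$slope_window[1] / coef)
  d2 <- sqrt(cfg$slope_window[2] / coef)
  dd <- seq(d1, d2, length.out = 1e5)
  ff <- coef * dd^2
  s_oracle <- sum((dd - mean(dd)) * (ff - mean(ff))) / sum((dd - mean(dd))^2)
  expect_equal(s_fit, s_oracle, tolerance = 0.005)
})

test_that("slope fit errors when the window is unreachable", {
  fd <- generate_curve(curve_spec(setpoint_force = 0.5e-9))
  p <- detect_contact_point(fd)
  expect_error(fit_stiffness_slope(p), class = "rbcmech_insufficient_window")
})

test_that("dissipation matches closed-form integrals", {
  # retract identical to approach: nothing dissipated
  p0 <- detect_contact_point(generate_curve(curve_spec(hysteresis_ratio = 0)))
  d0 <- compute_dissipation(p0)
  expect_equal(d0$dissipated_energy / d0$area_approach, 0, tolerance = 1e-6)

  # F_R = 0.5 F_A on a pure parabola: A_E = c dmax^3 / 3 analytically
  p <- detect_contact_point(generate_curve(curve_spec(
    true_modulus = 1500, hysteresis_ratio = 0.5)))
  d <- compute_dissipation(p)
  coef <- 2 * 1500 * tan(20 * pi / 180) / (pi * (1 - 0.25))
  dmax <- attr(generate_curve(curve_spec(true_modulus = 1500)), "truth")$delta_max
  a_e_analytic <- coef * dmax^3 / 3
  expect_equal(d$area_approach, a_e_analytic, tolerance = 1e-3)
  expect_equal(d$dissipated_energy, 0.5 * d$area_approach, tolerance = 1e-6)
})

test_that("hysteresis equals the generating ratio exactly", {
  for (h in c(0, 0.2, 0.48, 0.9, 1)) {
    p <- detect_contact_point(generate_curve(curve_spec(hysteresis_ratio = h)))
    expect_equal(compute_hysteresis(p), h, tolerance = 1e-6)
  }
})

test_that("work of adhesion matches the triangle-area oracle", {
  # no dip: zero adhesion on the vast majority of curves
  p0 <- detect_contact_point(generate_curve(curve_spec()))
  wa0 <- compute_work_of_adhesion(p0)
  expect_equal(as.numeric(wa0), 0)
  expect_false(attr(wa0, "adhesion_present"))

  # triangular dip, depth 100 pN over 200 nm: WA = 1/2 * d * w = 1e-17 J
  p <- detect_contact_point(generate_curve(curve_spec(
    adhesion_depth = 100e-12, adhesion_width = 200e-9)))
  wa <- compute_work_of_adhesion(p)
  expect_equal(as.numeric(wa), 0.5 * 100e-12 * 200e-9, tolerance = 1e-3)
  expect_true(attr(wa, "adhesion_present"))

  # trapezoid oracle on the extracted dip itself
  ret <- p$retract[p$retract$force < 0, ]
  oracle <- abs(pracma::trapz(ret$indentation, ret$force))
  expect_equal(as.numeric(wa), oracle, tolerance = 0.02)
})

test_that("noiseless round trip recovers every generating parameter within 0.5%", {
  grid <- expand.grid(E = c(800, 1500, 3000), h = c(0.3, 0.48),
                      s = c(0.0012, 0.003))
  for (i in seq_len(nrow(grid))) {
    fd <- generate_curve(curve_spec(true_modulus = grid$E[i],
                                    hysteresis_ratio = grid$h[i],
                                    linear_slope = grid$s[i],
                                    adhesion_depth = 80e-12))
    feats <- extract_curve_features(detect_contact_point(fd))
    expect_equal(feats$youngs_modulus, grid$E[i], tolerance = 5e-3)
    expect_equal(feats$stiffness, grid$s[i], tolerance = 5e-3)
    expect_equal(feats$hysteresis, grid$h[i], tolerance = 5e-3)
    expect_equal(feats$work_of_adhesion, 0.5 * 80e-12 * 200e-9,
                 tolerance = 5e-3)
    expect_true(feats$usable)
  }
})
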