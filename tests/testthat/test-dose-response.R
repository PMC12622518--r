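make_fit <- function(Rmin = 1, Rmax = 7.46, Kd = 60.68, p = 1) {
  conc <- c(0, 2, 5, 10, 20, 60, 100, 400, 2000)
  fit_dose_response(conc, Rmax + (Rmin - Rmax) / (1 + (conc / Kd)^p))
}

test_that("noiseless calibration points are recovered to machine precision", {
  fit <- make_fit()
  expect_rel_equal(fit$Rmin, 1, 1e-6)
  expect_rel_equal(fit$Rmax, 7.46, 1e-6)
  expect_rel_equal(fit$Kd_uM, 60.68, 1e-6)
  expect_rel_equal(fit$hill_p, 1, 1e-6)
  expect_rel_equal(fit$delta_Rmax, 6.46, 1e-6)

  # with a non-unit Hill slope as well
  fit2 <- make_fit(p = 1.7)
  expect_rel_equal(fit2$Kd_uM, 60.68, 1e-5)
  expect_rel_equal(fit2$hill_p, 1.7, 1e-5)
})

test_that("fitting handles degenerate and disordered inputs", {
  conc <- c(0, 2, 5, 10, 20, 60)
  flat <- fit_dose_response(conc, rep(2.5, 6))
  expect_true("flat_response" %in% flat$flags)
  expect_equal(flat$delta_Rmax, 0)
  expect_lt(abs(flat$Rmax - flat$Rmin), 1e-9)

  # reordering calibration points changes nothing
  r <- 7.46 + (1 - 7.46) / (1 + conc / 60.68)
  o <- c(4, 1, 6, 2, 5, 3)
  f1 <- fit_dose_response(conc, r)
  f2 <- fit_dose_response(conc[o], r[o])
  expect_equal(f1$Kd_uM, f2$Kd_uM, tolerance = 1e-9)

  # rescaling both Rmin and Rmax leaves Kd and p unchanged
  f3 <- fit_dose_response(conc, 3 * r)
  expect_equal(f3$Kd_uM, f1$Kd_uM, tolerance = 1e-6)
  expect_equal(f3$hill_p, f1$hill_p, tolerance = 1e-6)
  expect_equal(f3$Rmin, 3 * f1$Rmin, tolerance = 1e-6)

  expect_error(fit_dose_response(c(1, 2, 3), c(1, 2, 3)), "5 distinct")
  expect_error(fit_dose_response(conc, -r), "positive")
})

test_that("Hill-model algebra holds: limits, midpoint, hand-evaluated point", {
  for (p in c(0.5, 1, 2.3)) {
    fit <- make_fit(p = p)
    expect_equal(predict_ratio(fit, 0), fit$Rmin)
    expect_equal(predict_ratio(fit, fit$Kd_uM), (fit$Rmin + fit$Rmax) / 2,
                 tolerance = 1e-9)
  }
  fit <- make_fit()
  # hand evaluation at conc = 10 Kd with p = 1:
  # R = Rmax - (Rmax - Rmin)/11
  expect_equal(predict_ratio(fit, 10 * fit$Kd_uM),
               fit$Rmax - (fit$Rmax - fit$Rmin) / 11, tolerance = 1e-9)
})

test_that("inversion is the exact inverse of prediction and censors out-of-range ratios", {
  fit <- make_fit(p = 1.4)
  conc <- 10^seq(-1, 4, length.out = 50)
  inv <- invert_dose_response(fit, predict_ratio(fit, conc))
  expect_true(all(inv$censoring == "quantified"))
  expect_rel_equal(inv$conc_uM, conc, 1e-9)

  expect_equal(invert_dose_response(fit, (fit$Rmin + fit$Rmax) / 2)$conc_uM,
               fit$Kd_uM, tolerance = 1e-9)
  expect_equal(invert_dose_response(fit, fit$Rmax + 0.1)$censoring,
               "above_range")
  low <- invert_dose_response(fit, fit$Rmin - 0.01)
  expect_equal(low$censoring, "below_range")
  expect_equal(low$conc_uM, 0)
})

test_that("LOD follows the blank + 3 sd criterion and is monotone in blank noise", {
  fit <- make_fit()
  expect_equal(estimate_lod(fit, rep(fit$Rmin, 5)), 0)
  blanks1 <- fit$Rmin + c(-0.01, 0, 0.01)
  blanks2 <- fit$Rmin + c(-0.02, 0, 0.02)
  lod1 <- estimate_lod(fit, blanks1)
  lod2 <- estimate_lod(fit, blanks2)
  expect_gt(lod1, 0)
  expect_gt(lod2, lod1)
  # hand check: LOD inverts mean + 3 sd exactly
  expect_equal(predict_ratio(fit, lod1), mean(blanks1) + 3 * sd(blanks1),
               tolerance = 1e-9)
  expect_warning(lod_sat <- estimate_lod(fit, c(7.0, 7.4, 7.8)), "saturated")
  expect_true(is.na(lod_sat))
  expect_error(estimate_lod(fit, c(1, 1)), "3 blank")
})

test_that("reference correction cancels a shared pH factor", {
  expect_equal(reference_correct(2, 1), 2)
  g <- 1.37
  expect_equal(reference_correct(2.2 * g, 1.1 * g),
               reference_correct(2.2, 1.1))
  expect_error(reference_correct(2, numeric(0)), class = "missing_reference")

  # simulated pH series: corrected response flat, uncorrected varies
  sc <- scenario_config(seed = 4, dose = list(noise_sd = 0.01))
  g <- gen_ph_series(sc)
  f <- tempfile(fileext = ".csv")
  write.csv(g$table, f, row.names = FALSE, quote = FALSE)
  meas <- attach_reference(read_plate_measurements(f))
  unlink(f)
  corrected <- reference_correct(meas$ratio, meas$reference_ratio)
  expect_gt(sd(meas$ratio) / mean(meas$ratio), 0.05)     # pH drift visible
  expect_lt(sd(corrected) / mean(corrected), 0.03)       # flattened to noise
})

test_that("control normalization uses the control mean as its denominator", {
  ctrl <- c(1.9, 2.0, 2.1)
  expect_equal(normalize_to_control(mean(ctrl), ctrl), 1)
  expect_equal(normalize_to_control(2 * ctrl, ctrl), 2 * ctrl / 2)
  expect_error(normalize_to_control(1, numeric(0)), "empty")

  # corrected-then-normalized matches the hand computation on a toy table
  sensor <- c(2.0, 2.2, 4.0, 4.4, 6.0, 6.6)
  refs <- c(1.0, 1.1, 1.0, 1.1, 1.0, 1.1)
  ctrl_idx <- 1:2
  corrected <- sensor / refs
  byhand <- corrected / mean(corrected[ctrl_idx])
  got <- normalize_to_control(reference_correct(sensor, refs),
                              reference_correct(sensor[ctrl_idx], refs[ctrl_idx]))
  expect_equal(got, byhand)
})

test_that("sample quantification inverts, scales by dilution and censors", {
  fit <- make_fit()
  samples <- data.frame(sample_id = "s1",
                        ratio = predict_ratio(fit, 75))
  q <- quantify_samples(fit, samples, dilution = 4 / 3)
  expect_equal(q$conc_uM, 100, tolerance = 1e-6)
  expect_equal(q$censoring, "quantified")

  # triplicate identical ratios: CI from the fit covariance alone
  trip <- data.frame(sample_id = "s1", ratio = rep(predict_ratio(fit, 75), 3))
  q2 <- quantify_samples(fit, trip)
  expect_equal(q2$conc_uM, 100, tolerance = 1e-6)
  expect_true(q2$ci_high_uM >= q2$conc_uM)

  sat <- data.frame(sample_id = "hot", ratio = fit$Rmax + 1)
  expect_equal(quantify_samples(fit, sat)$censoring, "above_range")
  dim_s <- data.frame(sample_id = "dim", ratio = predict_ratio(fit, 0.05))
  expect_equal(quantify_samples(fit, dim_s, dilution = 1, lod = 0.3)$censoring,
               "below_LOD")
})

test_that("method agreement statistics behave on exact and scaled data", {
  ref <- c(10, 50, 100, 500, 1000)
  a <- method_agreement(ref, ref)
  expect_equal(a$slope, 1)
  expect_equal(a$intercept_uM, 0, tolerance = 1e-9)
  expect_equal(a$r_squared, 1)
  expect_equal(a$mean_relative_error_pct, 0)
  expect_equal(method_agreement(2 * ref, ref)$slope, 2)
  expect_error(method_agreement(ref, rep(5, 5)), "variance")
})
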