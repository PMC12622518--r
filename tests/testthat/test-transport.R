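cal_fit <- function() {
  conc <- c(0, 2, 5, 10, 20, 60, 100, 400, 2000)
  fit_dose_response(conc, 7.46 + (1 - 7.46) / (1 + conc / 60.68))
}

test_that("ratio traces invert to concentration traces with censoring as bounds", {
  fit <- cal_fit()
  t <- seq(0, 300, by = 30)
  flat <- timecourse_to_concentration(fit, t, rep(predict_ratio(fit, 20), 11))
  expect_equal(flat$conc_uM, rep(20, 11), tolerance = 1e-9)

  # a ramp crossing Rmax censors the trailing points
  ramp <- seq(fit$Rmin + 0.5, fit$Rmax + 0.2, length.out = 11)
  tc <- timecourse_to_concentration(fit, t, ramp)
  expect_true(any(tc$censoring == "above_range"))
  expect_true(all(which(tc$censoring == "above_range") >
                    which(tc$censoring == "quantified")[1]))

  # mostly saturated traces are unusable
  expect_error(
    timecourse_to_concentration(fit, t, rep(fit$Rmax + 1, 11)),
    class = "unusable_trace")
  expect_error(timecourse_to_concentration(fit, c(0, 0, 30), rep(2, 3)),
               "strictly increasing")
})

test_that("simulated uptake traces are recovered within 5% RMS in the working range", {
  fit <- cal_fit()
  set.seed(31)
  t <- seq(0, 120, by = 10)
  truth <- 0.8 * t  # uM, linear uptake
  r <- predict_ratio(fit, truth) * (1 + rnorm(length(t), 0, 0.02))
  tc <- timecourse_to_concentration(fit, t, r)
  keep <- truth > 10  # working range of the sensor
  rms <- sqrt(mean(((tc$conc_uM[keep] - truth[keep]) / truth[keep])^2))
  expect_lt(rms, 0.05)
})

test_that("initial rates: linear, flat, concave and adaptive-window cases", {
  t <- seq(0, 60, by = 10)
  expect_equal(initial_rate(t, 3 * t / 60)$rate_uM_per_min, 3,
               tolerance = 1e-9)
  expect_equal(initial_rate(t, rep(5, 7))$rate_uM_per_min, 0,
               tolerance = 1e-12)
  neg <- initial_rate(t, 10 - 0.05 * t)
  expect_true("efflux_or_noise" %in% neg$qc_flags)

  # saturating exponential, true initial slope 5 uM/min, window well
  # inside the time constant tau = 600 s
  tau <- 600
  tfull <- seq(0, 60, by = 5)
  conc <- 5 * tau / 60 * (1 - exp(-tfull / tau))
  est <- initial_rate(tfull, conc, window_s = 60)
  expect_lt(abs(est$rate_uM_per_min - 5) / 5, 0.05)
  # OLS over a concave trace cannot exceed the true initial slope
  expect_lte(est$rate_uM_per_min, 5)

  # adaptive mode trims the curved tail of a longer trace
  tlong <- seq(0, 600, by = 20)
  clong <- 5 * tau / 60 * (1 - exp(-tlong / tau))
  ad <- initial_rate(tlong, clong, adaptive = TRUE)
  expect_lt(ad$window_s, 600)
  expect_lt(abs(ad$rate_uM_per_min - 5) / 5, 0.15)

  expect_error(initial_rate(c(0, 10), c(0, 1)), "3 points")
})

test_that("Michaelis-Menten fits recover exact parameters and are scale-equivariant", {
  S <- c(2, 5, 10, 23.34, 50, 100, 250)
  v <- 10 * S / (23.34 + S)
  fit <- fit_michaelis_menten(S, v)
  expect_rel_equal(fit$Km_uM, 23.34, 1e-6)
  expect_rel_equal(fit$Vmax, 10, 1e-6)
  # v(Km) = Vmax / 2 by definition
  expect_equal(10 * 23.34 / (23.34 + 23.34), 10 / 2)

  f_rate <- fit_michaelis_menten(S, 3 * v)
  expect_rel_equal(f_rate$Vmax, 30, 1e-6)
  expect_rel_equal(f_rate$Km_uM, 23.34, 1e-6)
  f_sub <- fit_michaelis_menten(2 * S, v)
  expect_rel_equal(f_sub$Km_uM, 2 * 23.34, 1e-6)
  expect_rel_equal(f_sub$Vmax, 10, 1e-6)

  narrow <- fit_michaelis_menten(c(200, 300, 400, 600, 800),
                                 10 * c(200, 300, 400, 600, 800) /
                                   (23.34 + c(200, 300, 400, 600, 800)))
  expect_true("substrate_range_narrow" %in% narrow$flags)
  expect_error(fit_michaelis_menten(c(1, 2, 3), c(1, 2, 3)), "5 substrate")
})

test_that("noisy rate data recover Km within the simulation tolerance", {
  set.seed(77)
  S <- c(3, 6, 12, 24, 48, 96, 200, 400)
  errs <- replicate(100, {
    v <- (10 * S / (23.34 + S)) * (1 + rnorm(length(S), 0, 0.05))
    fit_michaelis_menten(S, v)$Km_uM / 23.34 - 1
  })
  expect_lt(median(abs(errs)), 0.15)
})

test_that("transport classification follows the threshold rules", {
  classes <- c(CCCP = "protonophore", PCMB = "thiol",
               iodoacetamide = "metabolic")
  # protonophore-complete, others mild: proton-coupled
  call <- classify_transport(10, c(CCCP = 0.2, PCMB = 9.5,
                                   iodoacetamide = 9.5), classes)
  expect_equal(call$label, "proton_coupled")
  expect_equal(unname(call$percent_inhibition["CCCP"]), 98)

  # programmed 95/10/10 panel at default 90/50 thresholds
  call2 <- classify_transport(10, c(CCCP = 0.5, PCMB = 9, iodoacetamide = 9),
                              classes)
  expect_equal(call2$label, "proton_coupled")

  expect_equal(classify_transport(10, c(CCCP = 10, PCMB = 10,
                                        iodoacetamide = 10), classes)$label,
               "unaffected")
  expect_equal(classify_transport(10, c(PCMB = 0.5, iodoacetamide = 9),
                                  classes)$label, "indeterminate")
  thiol <- classify_transport(10, c(CCCP = 9.5, PCMB = 0.2,
                                    iodoacetamide = 9.5), classes)
  expect_equal(thiol$label, "thiol_sensitive")

  comp <- classify_transport(10, c(CCCP = 0.2), classes,
                             competitor_rates = c(succinate = 4, fumarate = 6))
  expect_equal(unname(comp$competitor_overlap), c(60, 40))
  expect_error(classify_transport(0, c(CCCP = 1), classes), "positive")
})

test_that("generator-to-Km pipeline is scale-equivariant in Vmax", {
  sc1 <- scenario_config(seed = 3, uptake = list(noise_sd = 0))
  sc2 <- scenario_config(seed = 3,
                         uptake = list(noise_sd = 0, Vmax_uM_per_min = 120))
  r1 <- gen_uptake_assay(sc1)$truth$rates$rate_true_uM_per_min
  r2 <- gen_uptake_assay(sc2)$truth$rates$rate_true_uM_per_min
  expect_equal(r2, 2 * r1)
})
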