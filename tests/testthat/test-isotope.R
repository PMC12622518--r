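test_that("element abundance vectors match IUPAC values and normalize", {
  expect_equal(element_isotope_vector("C"), c(0.9893, 0.0107))
  expect_equal(element_isotope_vector("H"), c(0.999885, 0.000115))
  for (el in c("H", "C", "N", "O", "Si", "S"))
    expect_equal(sum(element_isotope_vector(el)), 1, tolerance = 1e-12)
  expect_error(element_isotope_vector("Xx"), "Xx")
})

test_that("formula parsing handles counts, repeats and malformed input", {
  expect_equal(parse_formula("C6H8O7"), c(C = 6L, H = 8L, O = 7L))
  expect_equal(parse_formula("CH4"), c(C = 1L, H = 4L))
  expect_equal(unname(parse_formula("C2HC")["C"]), 3L)  # repeated element
  expect_error(parse_formula("C6#H8"), "parse")
})

test_that("formula distributions match binomial algebra and brute-force enumeration", {
  expect_equal(formula_distribution(setNames(integer(0), character(0))), 1)
  a <- 0.0107
  expect_equal(formula_distribution("C2")[1:3],
               c((1 - a)^2, 2 * (1 - a) * a, a^2), tolerance = 1e-12)

  for (f in c("C3H4O3", "C5H4O3", "C2H5NO2")) {
    counts <- parse_formula(f)
    oracle <- enumerate_distribution(counts)
    got <- formula_distribution(f)
    n <- min(length(oracle), length(got))
    expect_lt(max(abs(got[1:n] - oracle[1:n])), 1e-12)
  }
})

test_that("the correction matrix equals brute-force per-atom enumeration", {
  # direct construction for a single tracer carbon
  M1 <- build_correction_matrix("C1", 1, tracer_purity = 1)
  expect_equal(unname(M1$matrix[, 1]), c(0.9893, 0.0107), tolerance = 1e-12)
  expect_equal(unname(M1$matrix[1:2, 2]), c(0, 1), tolerance = 1e-12)

  # C5 keto-acid skeleton (12 atoms), all tracer carbons, realistic purity
  counts <- parse_formula("C5H4O3")
  M <- build_correction_matrix("C5H4O3", 5, tracer_purity = 0.99)
  for (j in 0:5) {
    oracle <- enumerate_correction_column(counts, 5, j, 0.99)
    n <- min(length(oracle), nrow(M$matrix))
    expect_equal(unname(M$matrix[1:n, j + 1]), unname(oracle[1:n]), tolerance = 1e-10)
  }

  # fewer tracer carbons than formula carbons
  M2 <- build_correction_matrix("C4H5NO2", 3, tracer_purity = 0.995)
  oracle2 <- enumerate_correction_column(parse_formula("C4H5NO2"), 3, 3, 0.995)
  n <- min(length(oracle2), nrow(M2$matrix))
  expect_equal(unname(M2$matrix[1:n, 4]), unname(oracle2[1:n]), tolerance = 1e-10)

  expect_error(build_correction_matrix("C2H4", 3, 0.99), "carbons")
  expect_error(build_correction_matrix("C2H4", 2, 0.8), "purity")
})

test_that("columns are probability distributions; the no-abundance unit-purity limit is the identity", {
  M <- build_correction_matrix("C5H6O5", 5, tracer_purity = 0.99)
  expect_true(all(colSums(M$matrix) <= 1 + 1e-12))
  expect_true(all(colSums(M$matrix) >= 1 - 1e-9))

  zeroed <- list(H = c(1, 0), C = c(1, 0), N = c(1, 0), O = c(1, 0, 0),
                 Si = c(1, 0, 0), S = c(1, 0, 0, 0))
  Mid <- build_correction_matrix("C5H6O5", 5, tracer_purity = 1,
                                 abundances = zeroed)
  expect_equal(unname(Mid$matrix[1:6, ]), diag(6), tolerance = 1e-12)
})

test_that("MID normalization is scale-invariant and replicate averaging commutes", {
  expect_equal(mdv_from_areas(c(900, 0, 0, 0, 0, 100))$fractions,
               c(0.9, 0, 0, 0, 0, 0.1))
  expect_equal(mdv_from_areas(7 * c(900, 0, 0, 0, 0, 100))$fractions,
               mdv_from_areas(c(900, 0, 0, 0, 0, 100))$fractions)
  expect_error(mdv_from_areas(c(0, 0)), "zero")
  expect_error(mdv_from_areas(c(-1, 2)), "nonnegative")

  reps <- list(c(800, 100, 100), c(700, 200, 100), c(900, 50, 50))
  byhand <- colMeans(do.call(rbind, lapply(reps, function(a) a / sum(a))))
  got <- colMeans(do.call(rbind,
                          lapply(reps, function(a) mdv_from_areas(a)$fractions)))
  expect_equal(got, byhand)
})

test_that("NNLS deconvolution inverts the forward convolution", {
  M <- build_correction_matrix("C5H6O5", 5, tracer_purity = 0.99)
  # pure isotopologs come back as unit vectors
  for (j in c(0, 3, 5)) {
    e_j <- replace(numeric(6), j + 1, 1)
    raw <- drop(M$matrix %*% e_j)
    expect_equal(correct_mid(raw, M)$fractions, e_j, tolerance = 1e-8)
  }
  # random nonnegative mixtures, seeded
  set.seed(99)
  for (i in 1:20) {
    x <- runif(6)
    x <- x / sum(x)
    raw <- drop(M$matrix %*% x)
    got <- correct_mid(raw, M)$fractions
    expect_equal(got, x, tolerance = 1e-6)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
  # noisy input still yields a nonnegative unit-sum MID near truth
  set.seed(100)
  x <- c(0.05, 0.02, 0.03, 0.1, 0.3, 0.5)
  raw <- drop(M$matrix %*% x) + rnorm(nrow(M$matrix), 0, 0.01)
  got <- correct_mid(pmax(raw, 0), M)$fractions
  expect_true(all(got >= 0))
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_lt(max(abs(got - x)), 0.02)
})

test_that("flux partition endpoints, midpoint, and mode agreement are exact", {
  H <- c(0.04, 0.02, 0.04, 0.10, 0.20, 0.55, 0.05)
  D <- c(0.20, 0.10, 0.35, 0.25, 0.06, 0.03, 0.01)
  expect_equal(fit_flux_partition(H, H, D)$f_hydroxylation, 1)
  expect_equal(fit_flux_partition(D, H, D)$f_hydroxylation, 0)
  mid <- fit_flux_partition(0.5 * H + 0.5 * D, H, D)
  expect_equal(mid$f_hydroxylation, 0.5, tolerance = 1e-12)
  expect_equal(mid$f_m5_ratio, 0.5, tolerance = 1e-12)
  expect_identical(mid$f_hydroxylation + mid$f_dehydrogenation, 1)

  # the two modes agree exactly when boundaries differ only at m+0/m+5
  H2 <- c(0.3, 0.1, 0.1, 0, 0, 0.5)
  D2 <- c(0.7, 0.1, 0.1, 0, 0, 0.1)
  for (f in c(0.2, 0.6, 0.9338)) {
    fit <- fit_flux_partition(f * H2 + (1 - f) * D2, H2, D2)
    expect_equal(fit$f_full_mdv, fit$f_m5_ratio, tolerance = 1e-12)
    expect_equal(fit$f_full_mdv, f, tolerance = 1e-12)
  }
  expect_error(fit_flux_partition(H, H, H), class = "unidentifiable")
})

test_that("flux partition is monotone in the observed labeled fraction", {
  H <- c(0.3, 0.1, 0.1, 0, 0, 0.5)
  D <- c(0.7, 0.1, 0.1, 0, 0, 0.1)
  fs <- sapply(seq(0.1, 0.5, by = 0.05), function(m5) {
    obs <- c(1 - m5 - 0.2, 0.1, 0.1, 0, 0, m5)
    fit_flux_partition(obs, H, D)$f_hydroxylation
  })
  expect_true(all(diff(fs) >= -1e-12))
})

test_that("bootstrap CI is deterministic, degenerate on identical replicates", {
  H <- c(0.04, 0.02, 0.04, 0.10, 0.20, 0.55, 0.05)
  D <- c(0.20, 0.10, 0.35, 0.25, 0.06, 0.03, 0.01)
  obs <- 0.9 * H + 0.1 * D
  same <- list(obs, obs, obs)
  ci <- bootstrap_flux_ci(same, H, D, seed = 5)$ci_95
  expect_equal(ci[1], ci[2])
  expect_equal(ci[1], 0.9, tolerance = 1e-9)

  set.seed(17)
  reps <- lapply(1:4, function(i) {
    x <- pmax(obs + rnorm(7, 0, 0.01), 0)
    x / sum(x)
  })
  c1 <- bootstrap_flux_ci(reps, H, D, seed = 11)
  c2 <- bootstrap_flux_ci(reps, H, D, seed = 11)
  expect_identical(c1$ci_95, c2$ci_95)
  expect_true(c1$ci_95[1] <= c1$f_hydroxylation,
              c1$ci_95[2] >= c1$f_hydroxylation)
  expect_warning(bootstrap_flux_ci(reps, H, D, n_boot = 50, seed = 1), "100")
  expect_error(bootstrap_flux_ci(reps[1:2], H, D, seed = 1), "3 replicate")
})
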