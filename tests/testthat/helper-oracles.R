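# Independent oracles used across the suite.

# Brute-force isotope-pattern oracle: enumerate every combination of
# per-atom isotope states and accumulate the mass-shift probabilities.
# Tractable for fragments up to ~12 atoms; deliberately independent of the
# package's convolution code path.
enumerate_distribution <- function(counts,
                                   abundances = list(
                                     H = c(0.999885, 0.000115),
                                     C = c(0.9893, 0.0107),
                                     N = c(0.99636, 0.00364),
                                     O = c(0.99757, 0.00038, 0.00205),
                                     Si = c(0.92223, 0.04685, 0.03092))) {
  atoms <- rep(names(counts), counts)
  opts <- lapply(atoms, function(el) abundances[[el]])
  enumerate_atom_states(opts)
}

# Shared enumeration over explicit per-atom probability vectors
# (index 1 = shift 0).  Returns a dense shift-probability vector.
enumerate_atom_states <- function(opts) {
  if (length(opts) == 0) return(1)
  states <- expand.grid(lapply(opts, seq_along))
  shift <- as.matrix(states) - 1
  p <- rep(1, nrow(states))
  for (k in seq_along(opts)) p <- p * opts[[k]][states[[k]]]
  total_shift <- rowSums(shift)
  out <- numeric(max(total_shift) + 1)
  for (i in seq_len(nrow(states)))
    out[total_shift[i] + 1] <- out[total_shift[i] + 1] + p[i]
  out
}

# Brute-force column of the tracer correction operator: j labeled carbon
# positions (13C with probability = purity), n - j unlabeled tracer
# positions (natural 13C), plus the remaining atoms at natural abundance.
enumerate_correction_column <- function(counts, n_tracer, j, purity) {
  ab <- list(H = c(0.999885, 0.000115), C = c(0.9893, 0.0107),
             N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
             Si = c(0.92223, 0.04685, 0.03092))
  rest <- counts
  rest[["C"]] <- rest[["C"]] - n_tracer
  rest <- rest[rest > 0]
  opts <- c(
    rep(list(c(1 - purity, purity)), j),
    rep(list(ab$C), n_tracer - j),
    lapply(rep(names(rest), rest), function(el) ab[[el]]))
  enumerate_atom_states(opts)
}

# Noiseless sigmoidal melt model shared by thermal-shift tests.
logistic_melt <- function(Tv, Tm, width = 1.5, amplitude = 1000,
                          baseline = 100, quench_rate = 0) {
  baseline + amplitude * plogis((Tv - Tm) / width) *
    exp(-quench_rate * pmax(0, Tv - (Tm + 3 * width)))
}

# Convenience: fit a calibration to a generated plate table.
fit_from_table <- function(tab) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
  on.exit(unlink(f))
  fit_dose_response(read_plate_measurements(f))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * pmax(abs(expected), 1e-12)),
              label = sprintf("relative difference %.3g within %.3g",
                              max(abs(object - expected) /
                                    pmax(abs(expected), 1e-12)), tol))
}
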