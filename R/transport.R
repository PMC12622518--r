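#' Convert a sensor ratio time course to intracellular concentration
#'
#' Pointwise inversion of the calibration curve for a reference-corrected
#' ratio trace recorded during an uptake (or efflux) assay. Censored
#' points are carried as bounds: ratios at/below `Rmin` map to 0 uM
#' (`below_range`) and ratios at/above `Rmax` to NA (`above_range`). A
#' trace with more than 50% censored points is rejected as unusable.
#'
#' @param fit a [fit_dose_response()] calibration.
#' @param time_s strictly increasing times in seconds.
#' @param ratio reference-corrected F405/F488 ratios at those times.
#' @param substrate_conc_uM,treatment optional condition labels attached
#'   as attributes.
#' @return data.frame of class `uptake_timecourse` with columns `time_s`,
#'   `conc_uM`, `censoring`.
#' @export
timecourse_to_concentration <- function(fit, time_s, ratio,
                                        substrate_conc_uM = NA_real_,
                                        treatment = "none") {
  stopifnot(length(time_s) == length(ratio))
  if (is.unsorted(time_s, strictly = TRUE))
    stop("times must be strictly increasing")
  inv <- invert_dose_response(fit, ratio)
  if (mean(inv$censoring != "quantified") > 0.5)
    stop_glusense("more than half of the trace is outside the sensor range",
                  "unusable_trace")
  out <- data.frame(time_s = time_s, conc_uM = inv$conc_uM,
                    censoring = inv$censoring, stringsAsFactors = FALSE)
  attr(out, "substrate_conc_uM") <- substrate_conc_uM
  attr(out, "treatment") <- treatment
  class(out) <- c("uptake_timecourse", "data.frame")
  out
}

#' Initial uptake rate of a concentration time course
#'
#' Ordinary least-squares slope of concentration against time over the
#' initial window (default the first 60 s, matching one-minute kinetic
#' sampling). In adaptive mode the window is shrunk from the full trace
#' until the quadratic curvature term of a local polynomial fit is
#' statistically insignificant (|t| < 2), so the reported slope reflects
#' the near-linear initial phase. A negative slope at positive substrate
#' is returned with an `efflux_or_noise` qc flag rather than an error.
#'
#' @param time_s,conc_uM numeric vectors, or a single `uptake_timecourse`
#'   as first argument (censored points are dropped).
#' @param window_s initial window length in seconds (default 60).
#' @param adaptive use the curvature-adaptive window instead.
#' @return list with `rate_uM_per_min`, `n_points`, `window_s`,
#'   `qc_flags`.
#' @export
initial_rate <- function(time_s, conc_uM = NULL, window_s = 60,
                         adaptive = FALSE) {
  if (inherits(time_s, "uptake_timecourse")) {
    tc <- time_s
    keep <- tc$censoring == "quantified" | tc$censoring == "below_range"
    conc_uM <- tc$conc_uM[keep]
    time_s <- tc$time_s[keep]
  }
  ok <- complete.cases(time_s, conc_uM)
  time_s <- time_s[ok]; conc_uM <- conc_uM[ok]
  t0 <- min(time_s)
  if (adaptive) {
    sel <- seq_along(time_s)
    while (length(sel) > 4) {
      fitq <- lm(conc_uM[sel] ~ time_s[sel] + I(time_s[sel]^2))
      tstat <- summary(fitq)$coefficients
      if (nrow(tstat) < 3 || !is.finite(tstat[3, 3]) ||
          abs(tstat[3, 3]) < 2) break
      sel <- sel[-length(sel)]
    }
    idx <- sel
    window_s <- max(time_s[idx]) - t0
  } else {
    idx <- which(time_s <= t0 + window_s)
  }
  if (length(idx) < 3)
    stop("need at least 3 points inside the initial-rate window")
  m <- lm(conc_uM[idx] ~ time_s[idx])
  slope <- unname(coef(m)[2]) * 60  # uM/s -> uM/min
  qc <- character(0)
  if (slope < 0) qc <- c(qc, "efflux_or_noise")
  list(rate_uM_per_min = slope, n_points = length(idx),
       window_s = window_s, qc_flags = qc)
}

#' Michaelis-Menten fit of transport rates
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (Km + S)` to initial
#' rates measured at a series of substrate concentrations
#' (Levenberg-Marquardt, standard errors from the Jacobian-based
#' covariance). A post-hoc warning flag is set when the substrate series
#' does not span at least `[Km/3, 3 Km]` of the estimate. On
#' non-convergence the error message carries a Lineweaver-Burk
#' double-reciprocal estimate as a diagnostic (never reported as the
#' primary result).
#'
#' @param substrate_uM substrate concentrations (>= 5 levels).
#' @param rates initial rates (uM/min) at those concentrations.
#' @return object of class `mm_fit`: list with `Km_uM`, `Vmax`, `se_Km`,
#'   `se_Vmax`, `residual_sd`, `n`, `flags`.
#' @export
fit_michaelis_menten <- function(substrate_uM, rates) {
  stopifnot(length(substrate_uM) == length(rates))
  ok <- complete.cases(substrate_uM, rates)
  S <- substrate_uM[ok]; v <- rates[ok]
  if (length(unique(S)) < 5) stop("need at least 5 substrate levels")
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  km0 <- max(km0, min(S[S > 0]) / 10)
  starts <- unique(c(km0, median(S), min(S[S > 0]) / 2, max(S) / 20))
  f <- NULL
  for (k0 in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                        start = list(Vmax = vmax0, Km = k0),
                        lower = c(Vmax = 0, Km = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) break
  }
  if (is.null(f)) {
    lb <- lm(I(1 / v[v > 0]) ~ I(1 / S[v > 0]))
    km_lb <- unname(coef(lb)[2] / coef(lb)[1])
    stop_glusense(sprintf(
      "Michaelis-Menten fit did not converge (Lineweaver-Burk fallback Km ~ %.3g uM)",
      km_lb), "fit_failure")
  }
  cf <- coef(f)
  se <- tryCatch(sqrt(diag(vcov(f))), error = function(e) c(NA_real_, NA_real_))
  flags <- character(0)
  if (min(S[S > 0]) > cf["Km"] / 3 || max(S) < 3 * cf["Km"])
    flags <- c(flags, "substrate_range_narrow")
  structure(list(Km_uM = unname(cf["Km"]), Vmax = unname(cf["Vmax"]),
                 se_Km = unname(se["Km"]), se_Vmax = unname(se["Vmax"]),
                 residual_sd = sqrt(sum(residuals(f)^2) /
                                      max(length(v) - 2, 1)),
                 n = length(v), flags = flags),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Km = %.4g +/- %.2g uM, Vmax = %.4g +/- %.2g uM/min\n",
              x$Km_uM, x$se_Km, x$Vmax, x$se_Vmax))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Classify the transport mechanism from an inhibitor panel
#'
#' Computes the percent inhibition of the baseline uptake rate for each
#' treatment, `100 * (1 - treated/baseline)`, and derives a mechanistic
#' label from configurable thresholds: the transporter is called
#' `proton_coupled` when a protonophore-class treatment (e.g. CCCP)
#' reaches the complete-suppression threshold while thiol and metabolic
#' inhibitors stay below the partial threshold; `thiol_sensitive` and
#' `metabolically_gated` analogously for their classes; `unaffected` when
#' every treatment stays below the partial threshold; `indeterminate`
#' otherwise or when no protonophore-class treatment was run. Competitor
#' substrates are summarised separately as percent rate reduction.
#'
#' @param baseline_rate untreated uptake rate (> 0), uM/min.
#' @param treated_rates named numeric vector of rates under each
#'   treatment.
#' @param treatment_classes named character vector mapping each treatment
#'   name to a class: `"protonophore"`, `"thiol"`, or `"metabolic"`.
#' @param competitor_rates optional named numeric vector of rates in the
#'   presence of competing substrates.
#' @param complete_threshold percent inhibition regarded as complete
#'   suppression (default 90).
#' @param partial_threshold percent inhibition regarded as a partial
#'   effect (default 50).
#' @return object of class `transport_call`: list with `label`,
#'   `percent_inhibition`, `competitor_overlap`, `thresholds`.
#' @export
classify_transport <- function(baseline_rate, treated_rates,
                               treatment_classes,
                               competitor_rates = NULL,
                               complete_threshold = 90,
                               partial_threshold = 50) {
  if (!is.finite(baseline_rate) || baseline_rate <= 0)
    stop("baseline rate must be positive")
  stopifnot(all(names(treated_rates) %in% names(treatment_classes)))
  inhib <- 100 * (1 - treated_rates / baseline_rate)
  cls <- treatment_classes[names(treated_rates)]
  class_max <- tapply(inhib, cls, max)
  label <- "indeterminate"
  if (!"protonophore" %in% cls) {
    label <- "indeterminate"
  } else if (all(inhib < partial_threshold)) {
    label <- "unaffected"
  } else {
    map <- c(protonophore = "proton_coupled", thiol = "thiol_sensitive",
             metabolic = "metabolically_gated")
    for (cl in names(map)) {
      if (cl %in% names(class_max) && class_max[[cl]] >= complete_threshold &&
          all(class_max[setdiff(names(class_max), cl)] < partial_threshold)) {
        label <- map[[cl]]
        break
      }
    }
  }
  comp <- if (is.null(competitor_rates)) numeric(0)
          else 100 * (1 - competitor_rates / baseline_rate)
  structure(list(label = label, percent_inhibition = inhib,
                 competitor_overlap = comp,
                 thresholds = c(complete = complete_threshold,
                                partial = partial_threshold)),
            class = "transport_call")
}

#' @export
print.transport_call <- function(x, ...) {
  cat("Transport classification:", x$label, "\n")
  for (nm in names(x$percent_inhibition))
    cat(sprintf("  %s: %.1f%% inhibition\n", nm, x$percent_inhibition[[nm]]))
  if (length(x$competitor_overlap))
    for (nm in names(x$competitor_overlap))
      cat(sprintf("  competitor %s: %.1f%% rate reduction\n",
                  nm, x$competitor_overlap[[nm]]))
  invisible(x)
}
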