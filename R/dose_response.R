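#' Hill dose-response model for a ratiometric biosensor
#'
#' The sensor readout is the excitation ratio R = F405/F488, which responds
#' to analyte concentration \eqn{C} (in \eqn{\mu}M) as
#' \deqn{R(C) = R_{max} + \frac{R_{min} - R_{max}}{1 + (C/K_d)^p}}
#' with \eqn{R_{min}} the ratio of the apo sensor, \eqn{R_{max}} the
#' saturated ratio, \eqn{K_d} the apparent dissociation constant and
#' \eqn{p} the Hill slope. At \eqn{C = 0} the model evaluates to
#' \eqn{R_{min}} (the \eqn{(0/K_d)^p} term is exactly 0, no log transform
#' is needed) and at \eqn{C = K_d} to \eqn{(R_{min}+R_{max})/2} for any p.
#'
#' @name dose_response_model
#' @keywords internal
NULL

hill_ratio <- function(conc, Rmin, Rmax, Kd, p) {
  Rmax + (Rmin - Rmax) / (1 + (conc / Kd)^p)
}

#' Fit the Hill dose-response calibration curve
#'
#' Nonlinear least-squares fit of the four-parameter ratiometric Hill model
#' (see [dose_response_model]) to calibration points, by
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) with bound constraints and a
#' small multi-start ladder over the Hill slope.
#'
#' Initialisation: `Rmin` from the mean ratio at the lowest concentration,
#' `Rmax` from the mean ratio at the highest, `Kd` from the concentration
#' whose mean ratio is nearest half-response, `p = 1`; on failure the fit is
#' restarted from p in {0.5, 1, 2}. `Kd` is constrained to
#' `[min positive conc / 10, max conc * 10]` so the calibration never
#' extrapolates an affinity far outside the sampled range, and `p` to
#' `[0.3, 4]` (or fixed to 1 via `fix_p`).
#'
#' @param conc numeric vector of analyte concentrations (uM), or a
#'   data.frame with columns `analyte_conc_uM` and `ratio` (e.g. from
#'   [read_plate_measurements()]).
#' @param ratio numeric vector of measured F405/F488 ratios (ignored when
#'   `conc` is a data.frame).
#' @param fix_p fix the Hill slope at 1 instead of fitting it.
#' @param direction `"on"` for a sensor whose ratio increases with analyte
#'   (Rmax > Rmin expected), `"off"` for the reverse.
#' @return An object of class `dose_response_fit`: a list with elements
#'   `Rmin`, `Rmax`, `Kd_uM`, `hill_p`, `covariance` (4x4, ordered
#'   Rmin/Rmax/Kd/p; zero row/column for a fixed p), `delta_Rmax`
#'   ((Rmax-Rmin)/Rmin), `n_points`, `residual_sd`, `valid_range_uM`
#'   and `flags`.
#' @examples
#' conc <- c(0, 5, 20, 60, 200, 1000)
#' r <- 7.46 + (1 - 7.46) / (1 + conc / 60.68)
#' fit <- fit_dose_response(conc, r)
#' fit$Kd_uM
#' @export
fit_dose_response <- function(conc, ratio = NULL, fix_p = FALSE,
                              direction = c("on", "off")) {
  direction <- match.arg(direction)
  if (is.data.frame(conc)) {
    ratio <- conc$ratio
    conc <- conc$analyte_conc_uM
  }
  if (length(conc) != length(ratio))
    stop("conc and ratio must have the same length")
  ok <- complete.cases(conc, ratio)
  conc <- conc[ok]; ratio <- ratio[ok]
  if (any(ratio <= 0)) stop("ratios must be positive")
  if (length(unique(conc)) < 5 || !any(conc == 0))
    stop("need at least 5 distinct concentrations including 0")

  flags <- character(0)
  rho <- suppressWarnings(cor(conc, ratio, method = "spearman"))
  if (!is.na(rho) && abs(rho) < 0.5) flags <- c(flags, "non_monotone_data")

  means <- tapply(ratio, conc, mean)
  cmeans <- as.numeric(names(means))
  if (sd(ratio) < 1e-12 * mean(ratio)) {
    m <- mean(ratio)
    return(new_dose_response_fit(
      Rmin = m, Rmax = m, Kd_uM = NA_real_, hill_p = NA_real_,
      covariance = matrix(0, 4, 4), n_points = length(ratio),
      residual_sd = 0, valid_range_uM = range(conc[conc > 0], Inf)[1:2],
      flags = c(flags, "flat_response")))
  }

  r_lo <- means[which.min(cmeans)]
  r_hi <- means[which.max(cmeans)]
  if (direction == "on" && r_hi < r_lo) flags <- c(flags, "direction_mismatch")
  half <- (r_lo + r_hi) / 2
  pos <- cmeans[cmeans > 0]
  kd0 <- pos[which.min(abs(means[as.character(pos)] - half))]
  kd_lims <- c(min(pos) / 10, max(pos) * 10)

  fits <- list()
  for (p0 in c(1, 0.5, 2)) {
    f <- tryCatch({
      if (fix_p) {
        minpack.lm::nlsLM(
          ratio ~ Rmax + (Rmin - Rmax) / (1 + (conc / Kd)),
          start = list(Rmin = unname(r_lo), Rmax = unname(r_hi),
                       Kd = unname(kd0)),
          lower = c(Rmin = 1e-9, Rmax = 1e-9, Kd = kd_lims[1]),
          upper = c(Rmin = Inf, Rmax = Inf, Kd = kd_lims[2]),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          ratio ~ Rmax + (Rmin - Rmax) / (1 + (conc / Kd)^p),
          start = list(Rmin = unname(r_lo), Rmax = unname(r_hi),
                       Kd = unname(kd0), p = p0),
          lower = c(Rmin = 1e-9, Rmax = 1e-9, Kd = kd_lims[1], p = 0.3),
          upper = c(Rmin = Inf, Rmax = Inf, Kd = kd_lims[2], p = 4),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
    if (fix_p) break
  }
  if (length(fits) == 0)
    stop_glusense(sprintf(
      "dose-response fit did not converge (start Rmin=%.3g Rmax=%.3g Kd=%.3g)",
      r_lo, r_hi, kd0), "fit_failure")
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  f <- fits[[which.min(rss)]]

  cf <- coef(f)
  vc <- tryCatch(vcov(f), error = function(e) matrix(NA_real_, length(cf), length(cf)))
  cov4 <- matrix(0, 4, 4,
                 dimnames = list(c("Rmin", "Rmax", "Kd", "p"),
                                 c("Rmin", "Rmax", "Kd", "p")))
  idx <- if (fix_p) 1:3 else 1:4
  cov4[idx, idx] <- vc
  dof <- length(ratio) - length(cf)

  kd_hat <- unname(cf["Kd"])
  if (kd_hat <= kd_lims[1] * 1.0001 || kd_hat >= kd_lims[2] * 0.9999)
    flags <- c(flags, "Kd_at_bound")

  new_dose_response_fit(
    Rmin = unname(cf["Rmin"]), Rmax = unname(cf["Rmax"]),
    Kd_uM = kd_hat, hill_p = if (fix_p) 1 else unname(cf["p"]),
    covariance = cov4, n_points = length(ratio),
    residual_sd = sqrt(sum(residuals(f)^2) / max(dof, 1)),
    valid_range_uM = c(min(pos), max(pos)),
    flags = flags, df_residual = dof)
}

#' Confidence interval for the fitted dissociation constant
#'
#' Wald interval for Kd on the log scale (the sampling distribution of an
#' affinity estimate is closer to log-normal), using the Jacobian-based
#' standard error from the fit covariance and a Student-t quantile at the
#' fit's residual degrees of freedom.
#'
#' @param fit a [fit_dose_response()] result.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` in uM.
#' @export
kd_confint <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dose_response_fit"))
  se <- sqrt(fit$covariance["Kd", "Kd"])
  df <- if (is.na(fit$df_residual)) Inf else fit$df_residual
  q <- stats::qt(1 - (1 - level) / 2, df)
  fit$Kd_uM * exp(c(-1, 1) * q * se / fit$Kd_uM)
}

new_dose_response_fit <- function(Rmin, Rmax, Kd_uM, hill_p, covariance,
                                  n_points, residual_sd, valid_range_uM,
                                  flags, df_residual = NA_integer_) {
  out <- list(Rmin = Rmin, Rmax = Rmax, Kd_uM = Kd_uM, hill_p = hill_p,
              covariance = covariance,
              delta_Rmax = (Rmax - Rmin) / Rmin,
              n_points = n_points, residual_sd = residual_sd,
              valid_range_uM = valid_range_uM, flags = flags,
              df_residual = df_residual)
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Ratiometric dose-response fit\n")
  cat(sprintf("  Rmin = %.4g, Rmax = %.4g  (dRmax = %.1f%%)\n",
              x$Rmin, x$Rmax, 100 * x$delta_Rmax))
  cat(sprintf("  Kd = %.4g uM, Hill p = %.3g\n", x$Kd_uM, x$hill_p))
  cat(sprintf("  n = %d points, residual sd = %.3g\n", x$n_points, x$residual_sd))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Maximum fractional ratio change of a fitted sensor
#'
#' `delta_r_max` returns \eqn{\Delta R_{max} = (R_{max} - R_{min})/R_{min}},
#' the standard figure of merit for the dynamic range of a ratiometric
#' sensor (reported as a percentage when multiplied by 100).
#'
#' @param fit a `dose_response_fit`, or a numeric `Rmin` when `Rmax` is
#'   given separately.
#' @param Rmax optional numeric, used with a numeric first argument.
#' @return the fractional maximum ratio change (dimensionless).
#' @export
delta_r_max <- function(fit, Rmax = NULL) {
  if (inherits(fit, "dose_response_fit")) {
    Rmin <- fit$Rmin
    Rmax <- fit$Rmax
  } else {
    Rmin <- fit
  }
  if (is.na(Rmin) || Rmin <= 0) stop("Rmin must be positive")
  (Rmax - Rmin) / Rmin
}

#' Predict the sensor ratio at given concentrations
#'
#' Evaluates the fitted Hill model; `conc = 0` returns `Rmin` exactly and
#' the large-concentration limit is `Rmax`.
#'
#' @param fit a `dose_response_fit`.
#' @param conc numeric vector of concentrations (uM), all `>= 0`.
#' @return numeric vector of predicted F405/F488 ratios.
#' @export
predict_ratio <- function(fit, conc) {
  stopifnot(inherits(fit, "dose_response_fit"), all(conc >= 0))
  hill_ratio(conc, fit$Rmin, fit$Rmax, fit$Kd_uM, fit$hill_p)
}

#' Invert the dose-response curve
#'
#' Maps measured ratios back to concentrations through the exact algebraic
#' inverse \eqn{C = K_d ((R - R_{min})/(R_{max} - R))^{1/p}}. Ratios at or
#' below `Rmin` are censored `"below_range"` (concentration 0, a lower
#' bound) and ratios at or above `Rmax` are censored `"above_range"`
#' (concentration NA); no error is raised for out-of-range ratios.
#'
#' @param fit a `dose_response_fit`.
#' @param R numeric vector of measured ratios.
#' @return data.frame with columns `ratio`, `conc_uM`, `censoring`
#'   (one of `"quantified"`, `"below_range"`, `"above_range"`).
#' @export
invert_dose_response <- function(fit, R) {
  stopifnot(inherits(fit, "dose_response_fit"))
  lo <- pmin(fit$Rmin, fit$Rmax)
  hi <- pmax(fit$Rmin, fit$Rmax)
  conc <- rep(NA_real_, length(R))
  cens <- rep("quantified", length(R))
  below <- R <= lo
  above <- R >= hi
  mid <- !below & !above
  conc[mid] <- fit$Kd_uM *
    ((R[mid] - fit$Rmin) / (fit$Rmax - R[mid]))^(1 / fit$hill_p)
  conc[below] <- 0
  cens[below] <- "below_range"
  cens[above] <- "above_range"
  data.frame(ratio = R, conc_uM = conc, censoring = cens,
             stringsAsFactors = FALSE)
}

#' Limit of detection from blank replicates
#'
#' The LOD is the concentration whose predicted ratio equals
#' `mean(blanks) + 3 * sd(blanks)` (the conventional 3-sigma criterion),
#' obtained by inverting the calibration curve. With noiseless blanks the
#' LOD is 0; if the blank criterion already exceeds `Rmax` the sensor
#' cannot distinguish any concentration from blank and `NA` is returned
#' with a warning.
#'
#' @param fit a `dose_response_fit`.
#' @param blanks numeric vector (>= 3) of replicate ratios measured at
#'   concentration 0.
#' @return the LOD in uM (0 when the blanks are noiseless, NA when the
#'   blank criterion saturates the sensor).
#' @export
estimate_lod <- function(fit, blanks) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (length(blanks) < 3) stop("need at least 3 blank replicates")
  r_crit <- mean(blanks) + 3 * sd(blanks)
  if (sd(blanks) == 0) return(0)
  inv <- invert_dose_response(fit, r_crit)
  if (inv$censoring == "above_range") {
    warning("blank mean + 3 sd exceeds Rmax; LOD undefined (sensor saturated by blank)")
    return(NA_real_)
  }
  inv$conc_uM
}

#' Reference-fluorophore (pH) correction
#'
#' Divides the sensor ratio by the ratio of an unfused reference
#' fluorophore measured under the same conditions. Because sensor and
#' reference share the same chromophore, a common pH-dependent factor
#' multiplies both ratios and cancels in the quotient, stabilising the
#' readout against pH drift.
#'
#' @param sensor_ratio numeric vector of sensor F405/F488 ratios.
#' @param reference_ratio numeric vector (recycled) of reference
#'   fluorophore ratios; must be positive.
#' @return corrected ratios, `sensor_ratio / reference_ratio`.
#' @export
reference_correct <- function(sensor_ratio, reference_ratio) {
  if (length(reference_ratio) == 0 || anyNA(reference_ratio))
    stop_glusense("reference-fluorophore ratios are required for correction",
                  "missing_reference")
  if (any(reference_ratio <= 0)) stop("reference ratios must be positive")
  sensor_ratio / reference_ratio
}

#' Normalize readings to a control condition
#'
#' Divides each value by the mean of the control values, so the control
#' normalizes to 1. Used for figure-style "normalized to control" outputs;
#' the denominator is always the explicit `control_values` argument.
#'
#' @param values numeric vector.
#' @param control_values numeric vector of control readings (non-empty,
#'   positive mean).
#' @return `values / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0) stop("control set is empty")
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  values / m
}

#' Absolute quantification of samples from measured ratios
#'
#' Inverts the calibration curve for each replicate measurement, applies
#' the dilution factor of the sample:sensor mixing step (default 4/3 for
#' 3:1 mixing), aggregates replicates per sample and attaches a 95%
#' confidence interval. The CI combines, in quadrature, the delta-method
#' variance propagated from the calibration-fit covariance (numeric
#' gradient of the inverse curve with respect to Rmin/Rmax/Kd/p) with the
#' replicate standard error. Samples whose mean concentration falls below
#' `lod` are censored `below_LOD`; samples whose ratios saturate the curve
#' are censored `above_range`.
#'
#' @param fit a `dose_response_fit`.
#' @param samples data.frame with columns `sample_id` and `ratio`
#'   (optionally `replicate`).
#' @param dilution dilution factor applied to inverted concentrations
#'   (>= 1); default 4/3. Either a scalar or a named vector keyed by
#'   `sample_id` (e.g. mixing factor times per-sample pre-dilution).
#' @param lod detection limit in uM used for censoring (default 0).
#' @return data.frame with one row per sample: `sample_id`, `conc_uM`,
#'   `ci_low_uM`, `ci_high_uM`, `censoring`, `dilution_factor`, `n`.
#' @export
quantify_samples <- function(fit, samples, dilution = 4 / 3, lod = 0) {
  stopifnot(inherits(fit, "dose_response_fit"), all(dilution >= 1),
            all(c("sample_id", "ratio") %in% names(samples)))
  out <- lapply(split(samples, samples$sample_id), function(df) {
    dilution <- if (length(dilution) == 1) unname(dilution)
                else unname(dilution[[df$sample_id[1]]])
    n <- nrow(df)
    mean_ratio <- mean(df$ratio)
    inv <- invert_dose_response(fit, mean_ratio)
    if (inv$censoring == "above_range") {
      return(data.frame(sample_id = df$sample_id[1], conc_uM = NA_real_,
                        ci_low_uM = NA_real_, ci_high_uM = NA_real_,
                        censoring = "above_range",
                        dilution_factor = dilution, n = n,
                        stringsAsFactors = FALSE))
    }
    # invert the replicate-mean ratio: the inverse curve is convex near
    # saturation, so averaging before inversion avoids the heavy right
    # tail that per-replicate inversion produces there
    est <- inv$conc_uM * dilution
    var_fit <- inverse_delta_var(fit, mean_ratio) * dilution^2
    slope <- inverse_slope(fit, mean_ratio) * dilution
    var_rep <- if (n > 1) slope^2 * var(df$ratio) / n else 0
    hw <- qnorm(0.975) * sqrt(var_fit + var_rep)
    cens <- if (est < lod) "below_LOD" else "quantified"
    data.frame(sample_id = df$sample_id[1], conc_uM = est,
               ci_low_uM = max(0, est - hw), ci_high_uM = est + hw,
               censoring = cens, dilution_factor = dilution, n = n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## d conc / d ratio of the inverse curve, for replicate-scatter
## propagation.
inverse_slope <- function(fit, R) {
  if (R <= fit$Rmin || R >= fit$Rmax) return(0)
  h <- (fit$Rmax - fit$Rmin) * 1e-7
  (invert_dose_response(fit, R + h)$conc_uM -
     invert_dose_response(fit, R - h)$conc_uM) / (2 * h)
}

## Delta-method variance of the inverted concentration at ratio R,
## propagated from the 4x4 fit covariance by numeric differentiation.
inverse_delta_var <- function(fit, R) {
  if (anyNA(fit$covariance) || all(fit$covariance == 0)) return(0)
  inv1 <- function(Rmin, Rmax, Kd, p, R) {
    if (R <= Rmin || R >= Rmax) return(NA_real_)
    Kd * ((R - Rmin) / (Rmax - R))^(1 / p)
  }
  th <- c(fit$Rmin, fit$Rmax, fit$Kd_uM, fit$hill_p)
  g <- numeric(4)
  for (i in 1:4) {
    h <- max(abs(th[i]), 1e-3) * 1e-5
    up <- dn <- th
    up[i] <- up[i] + h
    dn[i] <- dn[i] - h
    g[i] <- (inv1(up[1], up[2], up[3], up[4], R) -
             inv1(dn[1], dn[2], dn[3], dn[4], R)) / (2 * h)
  }
  if (anyNA(g)) return(0)
  drop(t(g) %*% fit$covariance %*% g)
}

#' Agreement between sensor estimates and a reference method
#'
#' Ordinary least-squares regression of sensor-derived concentrations on
#' the reference-method concentrations (slope 1, intercept 0 and R-squared
#' 1 for perfect agreement), plus the mean relative error and the
#' per-level coefficient of variation.
#'
#' @param estimates numeric vector of sensor-derived concentrations (uM).
#' @param reference numeric vector of the same length (>= 3) of
#'   reference-method concentrations (uM).
#' @param level optional grouping vector (e.g. the nominal spike level)
#'   used for the per-level CV; defaults to `reference`.
#' @return object of class `agreement_stats`: list with `slope`,
#'   `intercept_uM`, `r_squared`, `mean_relative_error_pct`,
#'   `cv_pct_by_level`, `n`.
#' @export
method_agreement <- function(estimates, reference, level = reference) {
  ok <- complete.cases(estimates, reference)
  estimates <- estimates[ok]; reference <- reference[ok]; level <- level[ok]
  if (length(estimates) < 3) stop("need at least 3 paired values")
  if (var(reference) == 0) stop("reference values have zero variance")
  m <- lm(estimates ~ reference)
  msum <- suppressWarnings(summary(m))  # exact agreement warns in summary.lm
  pos <- reference > 0
  mre <- mean(abs(estimates[pos] - reference[pos]) / reference[pos]) * 100
  cv <- tapply(estimates, level, function(x)
    if (length(x) > 1 && mean(x) > 0) 100 * sd(x) / mean(x) else NA_real_)
  out <- list(slope = unname(coef(m)[2]),
              intercept_uM = unname(coef(m)[1]),
              r_squared = msum$r.squared,
              mean_relative_error_pct = mre,
              cv_pct_by_level = cv,
              n = length(estimates))
  class(out) <- "agreement_stats"
  out
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "Method agreement (n = %d): slope %.3f, intercept %.3g uM, R^2 %.4f, MRE %.2f%%\n",
    x$n, x$slope, x$intercept_uM, x$r_squared, x$mean_relative_error_pct))
  invisible(x)
}
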