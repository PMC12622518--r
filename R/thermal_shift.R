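#' Construct a melt curve
#'
#' A `melt_curve` holds one differential-scanning-fluorimetry trace: the
#' dye fluorescence of a protein sample recorded while ramping temperature.
#' Points are sorted by temperature on construction; duplicated
#' temperatures, fewer than 10 points, or temperatures outside 20-100 C
#' are rejected.
#'
#' @param temperature_C numeric vector of temperatures (degrees C).
#' @param fluorescence numeric vector of the same length (arbitrary units).
#' @param sample_id,ligand sample labels.
#' @param ligand_conc_uM ligand concentration (uM), NA for the apo control.
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temperature_C, fluorescence, sample_id = "sample",
                       ligand = "none", ligand_conc_uM = NA_real_) {
  if (length(temperature_C) != length(fluorescence))
    stop("temperature and fluorescence must have the same length")
  if (length(temperature_C) < 10)
    stop_glusense(sprintf("melt curve '%s' has fewer than 10 points", sample_id),
                  "too_short_curve")
  o <- order(temperature_C)
  temperature_C <- temperature_C[o]
  fluorescence <- fluorescence[o]
  if (anyDuplicated(temperature_C))
    stop_glusense(sprintf("duplicate temperatures in melt curve '%s'", sample_id),
                  "duplicate_temperature")
  if (min(temperature_C) < 20 || max(temperature_C) > 100)
    stop("temperatures must lie within [20, 100] C")
  structure(list(sample_id = sample_id, ligand = ligand,
                 ligand_conc_uM = ligand_conc_uM,
                 temperature_C = temperature_C,
                 fluorescence = fluorescence),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("Melt curve '%s' (ligand %s, %s uM): %d points, %.1f-%.1f C\n",
              x$sample_id, x$ligand,
              format(x$ligand_conc_uM), length(x$temperature_C),
              min(x$temperature_C), max(x$temperature_C)))
  invisible(x)
}

## Savitzky-Golay smoothed signal and first derivative of a melt curve,
## on its (assumed near-uniform) temperature grid. The window shrinks to
## the largest odd value below the curve length when necessary.
sg_melt <- function(curve, window, degree = 2) {
  n <- length(curve$temperature_C)
  if (window >= n)
    stop_glusense("smoothing window must be shorter than the curve", "bad_window")
  if (window %% 2 == 0 || window < 5)
    stop_glusense("smoothing window must be odd and >= 5", "bad_window")
  h <- mean(diff(curve$temperature_C))
  smooth <- signal::sgolayfilt(curve$fluorescence, p = degree, n = window)
  deriv <- signal::sgolayfilt(curve$fluorescence, p = degree, n = window,
                              m = 1) / h
  list(temperature_C = curve$temperature_C, smooth = smooth, deriv = deriv)
}

#' First derivative of a melt curve
#'
#' Smooths the fluorescence trace with a Savitzky-Golay polynomial filter
#' (local quadratic by default) and returns the first derivative dF/dT on
#' the curve's temperature grid. The melting transition appears as a
#' positive peak in this trace (SYPRO-Orange convention: fluorescence
#' rises through unfolding).
#'
#' @param curve a [melt_curve()].
#' @param window odd smoothing window length in points (>= 5, shorter than
#'   the curve); default 21.
#' @param degree polynomial degree of the filter (default 2).
#' @return data.frame with columns `temperature_C` and `dFdT`.
#' @export
compute_melt_derivative <- function(curve, window = 21, degree = 2) {
  sg <- sg_melt(curve, window, degree)
  data.frame(temperature_C = sg$temperature_C, dFdT = sg$deriv)
}

#' Melting temperature from the derivative melt curve
#'
#' Tm is located at the maximum of the Savitzky-Golay first derivative of
#' the fluorescence trace, refined by a quadratic fit over the contiguous
#' block of derivative points at or above `peak_frac` of the peak height
#' (vertex of the parabola). The search is restricted to `search_range`
#' and to temperatures at or below the global maximum of the smoothed
#' fluorescence, so that post-transition quenching (falling fluorescence
#' at high temperature) cannot masquerade as a transition. A curve whose
#' derivative is nowhere positive in the search window is reported as
#' having no transition (`Tm_C = NA`, qc flag `"no_transition"`).
#'
#' @param curve a [melt_curve()].
#' @param search_range numeric `c(Tlow, Thigh)` in degrees C; default
#'   `c(30, 90)` to avoid edge artifacts.
#' @param window,degree smoothing parameters, see [compute_melt_derivative()].
#' @param peak_frac fraction of the derivative peak height delimiting the
#'   quadratic refinement region (default 0.5).
#' @return object of class `tm_estimate`: list with `Tm_C`,
#'   `derivative_peak_height`, `qc_flags`.
#' @export
estimate_tm <- function(curve, search_range = c(30, 90), window = 21,
                        degree = 2, peak_frac = 0.5) {
  sg <- sg_melt(curve, window, degree)
  Tv <- sg$temperature_C
  if (search_range[1] < min(Tv) - 1e-9 || search_range[2] > max(Tv) + 1e-9)
    search_range <- c(max(search_range[1], min(Tv)),
                      min(search_range[2], max(Tv)))
  t_fmax <- Tv[which.max(sg$smooth)]
  keep <- Tv >= search_range[1] & Tv <= min(search_range[2], t_fmax)
  qc <- character(0)
  d <- sg$deriv[keep]
  Td <- Tv[keep]
  if (length(d) < 3 || max(d) <= 0) {
    return(structure(list(Tm_C = NA_real_,
                          derivative_peak_height = if (length(d)) max(d) else NA_real_,
                          qc_flags = "no_transition"),
                     class = "tm_estimate"))
  }
  i <- which.max(d)
  if (i == 1 || i == length(d)) qc <- c(qc, "peak_at_boundary")
  sel <- which(d >= peak_frac * d[i])
  runs <- split(sel, cumsum(c(1, diff(sel) != 1)))
  sel <- runs[[which(vapply(runs, function(r) i %in% r, logical(1)))]]
  tm <- Td[i]
  if (length(sel) >= 3) {
    x <- Td[sel] - Td[i]
    y <- d[sel]
    co <- coef(lm(y ~ x + I(x^2)))
    if (is.finite(co[3]) && co[3] < 0) {
      v <- -co[2] / (2 * co[3])
      if (v >= min(x) && v <= max(x)) tm <- Td[i] + v
    }
  }
  structure(list(Tm_C = unname(tm), derivative_peak_height = unname(d[i]),
                 qc_flags = qc),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  if (is.na(x$Tm_C)) cat("Tm estimate: no transition detected\n")
  else cat(sprintf("Tm = %.2f C (derivative peak %.3g a.u./C)\n",
                   x$Tm_C, x$derivative_peak_height))
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Ligand-induced thermal shift
#'
#' `delta_tm` is the difference between the sample Tm and the no-ligand
#' reference Tm. Accepts `tm_estimate` objects or plain numbers; an
#' undefined (no-transition) Tm on either side propagates to `NA`.
#'
#' @param sample_tm,reference_tm `tm_estimate` objects or numeric Tm
#'   values in degrees C.
#' @return the shift in degrees C (NA when either Tm is undefined).
#' @export
delta_tm <- function(sample_tm, reference_tm) {
  s <- if (inherits(sample_tm, "tm_estimate")) sample_tm$Tm_C else sample_tm
  r <- if (inherits(reference_tm, "tm_estimate")) reference_tm$Tm_C else reference_tm
  s - r
}

#' Binder call from a thermal shift
#'
#' A compound is called a binder when its ligand-induced shift strictly
#' exceeds the threshold (default 2 C). When a concentration series of
#' shifts is supplied, the call also reports whether the shift is
#' non-decreasing with concentration, the qualitative dose trend expected
#' of genuine binding.
#'
#' @param delta_Tm_C the shift for the call, in degrees C.
#' @param threshold_C binder threshold (default 2; the call uses a strict
#'   `>` comparison).
#' @param conc_uM,series_delta_Tm_C optional paired vectors describing a
#'   concentration series of shifts.
#' @param trend_tol_C tolerance for the monotone-trend check (default 0.3).
#' @return list with `is_binder` (logical, NA when the shift is undefined)
#'   and `dose_trend` (`"non_decreasing"`, `"non_monotone"` or NA).
#' @export
call_binder <- function(delta_Tm_C, threshold_C = 2,
                        conc_uM = NULL, series_delta_Tm_C = NULL,
                        trend_tol_C = 0.3) {
  is_binder <- if (is.na(delta_Tm_C)) NA else delta_Tm_C > threshold_C
  trend <- NA_character_
  if (!is.null(conc_uM)) {
    stopifnot(length(conc_uM) == length(series_delta_Tm_C))
    o <- order(conc_uM)
    dd <- diff(series_delta_Tm_C[o])
    trend <- if (all(dd >= -trend_tol_C)) "non_decreasing" else "non_monotone"
  }
  list(is_binder = is_binder, dose_trend = trend)
}

#' Thermal-shift screen analysis
#'
#' Runs the full melt-curve workflow on a set of curves: per-curve Tm
#' estimation, shift against the no-ligand reference, and binder calls at
#' the configured threshold. Replicate curves of the same ligand are
#' summarised as mean and sd.
#'
#' @param curves list of [melt_curve()] objects.
#' @param reference_ligand ligand label of the no-ligand control
#'   (default `"none"`).
#' @param threshold_C binder threshold in degrees C (default 2).
#' @param ... passed on to [estimate_tm()].
#' @return data.frame with one row per curve: sample, ligand, Tm,
#'   delta-Tm, binder flag and qc flags.
#' @export
analyze_thermal_shift <- function(curves, reference_ligand = "none",
                                  threshold_C = 2, ...) {
  ests <- lapply(curves, estimate_tm, ...)
  ligs <- vapply(curves, function(x) x$ligand, character(1))
  ref_tms <- vapply(ests[ligs == reference_ligand],
                    function(e) e$Tm_C, numeric(1))
  if (length(ref_tms) == 0)
    stop("no reference (no-ligand) curve found")
  ref <- mean(ref_tms, na.rm = TRUE)
  rows <- Map(function(cv, e) {
    dt <- delta_tm(e, ref)
    data.frame(sample_id = cv$sample_id, ligand = cv$ligand,
               ligand_conc_uM = cv$ligand_conc_uM,
               Tm_C = e$Tm_C, delta_Tm_C = dt,
               is_binder = call_binder(dt, threshold_C)$is_binder,
               qc_flags = paste(e$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }, curves, ests)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
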