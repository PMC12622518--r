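## Natural isotope abundances by nominal mass shift relative to the
## lightest isotope. Values are the IUPAC/CIAAW 2021 representative
## abundances. Deuterium and 17O/18O etc. matter for TBDMS-derivatized
## GC-MS fragments, where Si in particular contributes heavily at +1/+2.
ISOTOPE_ABUNDANCE <- list(
  H  = c(0.999885, 0.000115),
  C  = c(0.9893, 0.0107),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Si = c(0.92223, 0.04685, 0.03092),
  S  = c(0.9499, 0.0075, 0.0425, 0.0001)
)

#' Natural isotope abundance vector of an element
#'
#' Returns the natural abundance of an element's stable isotopes indexed
#' by nominal mass shift (position 1 = lightest isotope, +0). Supported
#' elements are H, C, N, O, Si and S, covering organic metabolites and
#' their silyl derivatives.
#'
#' @param element element symbol, e.g. `"C"`.
#' @return numeric vector of abundances summing to 1.
#' @examples
#' element_isotope_vector("C")  # 12C, 13C
#' @export
element_isotope_vector <- function(element) {
  v <- ISOTOPE_ABUNDANCE[[element]]
  if (is.null(v))
    stop(sprintf("unknown element '%s' (known: %s)", element,
                 paste(names(ISOTOPE_ABUNDANCE), collapse = ", ")))
  v
}

#' Parse an elemental formula
#'
#' Turns a Hill-style formula string such as `"C6H8O7"` into a named
#' vector of atom counts. Named numeric vectors/lists pass through.
#'
#' @param formula formula string or named numeric vector of atom counts.
#' @return named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula)))
    return(formula[formula > 0])
  if (is.list(formula)) return(parse_formula(unlist(formula)))
  stopifnot(is.character(formula), length(formula) == 1)
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(parts, collapse = "") != formula)
    stop(sprintf("cannot parse formula '%s'", formula))
  counts <- integer(0)
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    n <- if (n == "") 1L else as.integer(n)
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + n
  }
  counts[counts > 0]
}

## Discrete convolution of two mass-shift probability vectors.
conv_dist <- function(a, b) {
  if (length(a) == 0) return(b)
  out <- numeric(length(a) + length(b) - 1)
  for (j in seq_along(b)) {
    idx <- seq_along(a) + j - 1
    out[idx] <- out[idx] + a * b[j]
  }
  out
}

## Truncate a distribution to the shortest prefix holding >= 1 - tol mass.
truncate_dist <- function(x, tol = 1e-12) {
  cs <- cumsum(x)
  k <- which(cs >= 1 - tol)[1]
  if (is.na(k)) k <- length(x)
  x[seq_len(k)]
}

#' Natural mass-shift distribution of a molecular formula
#'
#' Convolves the per-atom isotope abundance vectors across every atom of
#' the formula, giving the probability of observing each nominal mass
#' shift (+0, +1, ...) for a molecule of natural isotopic composition.
#' The tail is truncated once the retained probability reaches
#' `1 - tol`.
#'
#' @param formula formula string or named atom-count vector
#'   (see [parse_formula()]); an empty formula yields `1` (no shift).
#' @param tol tail-truncation tolerance (default 1e-12).
#' @param abundances isotope abundance table; override only for testing
#'   limiting cases.
#' @return numeric vector of mass-shift probabilities starting at +0.
#' @examples
#' formula_distribution("C2")  # binomial in the 13C abundance
#' @export
formula_distribution <- function(formula, tol = 1e-12,
                                 abundances = ISOTOPE_ABUNDANCE) {
  counts <- parse_formula(formula)
  dist <- 1
  for (el in names(counts)) {
    v <- abundances[[el]]
    if (is.null(v)) stop(sprintf("unknown element '%s'", el))
    for (i in seq_len(counts[[el]])) dist <- conv_dist(dist, v)
    dist <- truncate_dist(dist, tol)
  }
  dist
}

#' Natural-abundance correction matrix for a labeled fragment
#'
#' Builds the forward convolution operator M mapping a tracer mass
#' distribution vector x (fractions of molecules carrying 0..n tracer
#' 13C labels) to the mass-shift distribution actually observed in the
#' mass spectrometer: `observed = M x`. Column j (j tracer labels) is the
#' convolution of
#' \itemize{
#'   \item the binomial natural 13C distribution over the `n - j`
#'     unlabeled tracer positions,
#'   \item the binomial tracer-purity distribution over the `j` labeled
#'     positions (each labeled position carries 13C with probability
#'     `tracer_purity`),
#'   \item the natural isotope distribution of all remaining atoms of the
#'     fragment (the formula minus the n tracer carbons), including
#'     derivatization atoms such as Si.
#' }
#' Rows beyond shift n are retained up to the truncation tolerance, so
#' each untruncated column sums to 1.
#'
#' @param fragment_formula full elemental formula of the measured fragment
#'   (string or named counts), including derivatization atoms.
#' @param n_tracer_carbons number of carbon positions that can carry the
#'   tracer label (<= the formula's carbon count).
#' @param tracer_purity isotopic purity of the tracer (fraction in
#'   (0.9, 1]); default 0.99.
#' @param tol tail-truncation tolerance.
#' @param abundances isotope abundance table (testing hook).
#' @return object of class `correction_matrix`: list with `matrix`
#'   (rows = observed shifts 0..n+k, columns = tracer labels 0..n),
#'   `formula`, `n_tracer_carbons`, `tracer_purity`.
#' @export
build_correction_matrix <- function(fragment_formula, n_tracer_carbons,
                                    tracer_purity = 0.99, tol = 1e-12,
                                    abundances = ISOTOPE_ABUNDANCE) {
  counts <- parse_formula(fragment_formula)
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  n <- as.integer(n_tracer_carbons)
  if (n > nC)
    stop(sprintf("formula has %d carbons but %d tracer carbons requested",
                 nC, n))
  if (tracer_purity <= 0.9 || tracer_purity > 1)
    stop("tracer purity must lie in (0.9, 1]")
  rest <- counts
  rest[["C"]] <- nC - n
  rest_dist <- formula_distribution(rest[rest > 0], tol, abundances)
  a13 <- abundances[["C"]][2]
  cols <- vector("list", n + 1)
  for (j in 0:n) {
    nat <- dbinom(0:(n - j), n - j, a13)
    pur <- dbinom(0:j, j, tracer_purity)
    col <- conv_dist(conv_dist(nat, pur), rest_dist)
    cols[[j + 1]] <- truncate_dist(col, tol)
  }
  nr <- max(vapply(cols, length, integer(1)))
  M <- vapply(cols, function(cl) c(cl, numeric(nr - length(cl))), numeric(nr))
  dimnames(M) <- list(paste0("m+", 0:(nr - 1)), paste0("x", 0:n))
  structure(list(matrix = M, formula = counts, n_tracer_carbons = n,
                 tracer_purity = tracer_purity),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf(
    "Natural-abundance correction matrix: %d x %d (tracer carbons %d, purity %.3f)\n",
    nrow(x$matrix), ncol(x$matrix), x$n_tracer_carbons, x$tracer_purity))
  invisible(x)
}

#' Mass distribution vector from raw peak areas
#'
#' Normalizes a dense vector of isotopologue peak areas (indexed m+0,
#' m+1, ...) to fractions summing to 1, without natural-abundance
#' correction.
#'
#' @param areas nonnegative numeric vector with positive sum.
#' @param metabolite,replicate optional labels carried on the result.
#' @return object of class `mid_vector`: list with `fractions`,
#'   `metabolite`, `replicate`, `flags`.
#' @export
mdv_from_areas <- function(areas, metabolite = NA_character_,
                           replicate = NA_integer_) {
  if (any(areas < 0)) stop("peak areas must be nonnegative")
  s <- sum(areas)
  if (s <= 0) stop("peak areas sum to zero")
  new_mid(areas / s, metabolite, replicate)
}

new_mid <- function(fractions, metabolite = NA_character_,
                    replicate = NA_integer_, flags = character(0)) {
  structure(list(fractions = fractions, metabolite = metabolite,
                 replicate = replicate, flags = flags),
            class = "mid_vector")
}

#' @export
print.mid_vector <- function(x, ...) {
  cat(sprintf("MID%s: %s\n",
              if (is.na(x$metabolite)) "" else paste0(" (", x$metabolite, ")"),
              paste(sprintf("m+%d %.4f", seq_along(x$fractions) - 1,
                            x$fractions), collapse = ", ")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

mid_fractions <- function(x) {
  if (inherits(x, "mid_vector")) x$fractions else as.numeric(x)
}

#' Correct raw isotopologue areas for natural abundance
#'
#' Removes the contribution of naturally occurring heavy isotopes (and
#' imperfect tracer purity) from measured peak areas by solving the
#' nonnegative least-squares problem `min || M x - raw ||^2, x >= 0`
#' (via [pracma::lsqnonneg()]) and renormalizing x to sum 1. NNLS rather
#' than a direct matrix inverse guarantees physically meaningful
#' (nonnegative) corrected fractions under measurement noise.
#'
#' @param raw_areas dense nonnegative vector of peak areas indexed by
#'   observed mass shift (m+0 first); shorter vectors are zero-padded to
#'   the matrix rows, longer ones truncated with a warning.
#' @param M a [build_correction_matrix()] result.
#' @param metabolite,replicate optional labels carried on the result.
#' @return `mid_vector` of corrected fractions of length
#'   `n_tracer_carbons + 1`; an `ill_conditioned` flag is set when the
#'   matrix condition number exceeds 1e8.
#' @export
correct_mid <- function(raw_areas, M, metabolite = NA_character_,
                        replicate = NA_integer_) {
  stopifnot(inherits(M, "correction_matrix"))
  if (any(raw_areas < 0)) stop("peak areas must be nonnegative")
  if (sum(raw_areas) <= 0) stop("peak areas sum to zero")
  nr <- nrow(M$matrix)
  if (length(raw_areas) < nr) {
    raw_areas <- c(raw_areas, numeric(nr - length(raw_areas)))
  } else if (length(raw_areas) > nr) {
    if (sum(raw_areas[-seq_len(nr)]) > 1e-6 * sum(raw_areas))
      warning("peak areas beyond the correction-matrix mass range were dropped")
    raw_areas <- raw_areas[seq_len(nr)]
  }
  flags <- character(0)
  if (kappa(M$matrix, exact = TRUE) > 1e8) flags <- c(flags, "ill_conditioned")
  x <- pracma::lsqnonneg(M$matrix, raw_areas / sum(raw_areas))$x
  if (sum(x) <= 0) stop("natural-abundance correction returned an all-zero MID")
  new_mid(x / sum(x), metabolite, replicate, flags)
}

#' Two-pathway flux partition from boundary MDV mixing
#'
#' Estimates the fraction of total flux routed through each of two
#' catabolic pathways from the isotopologue signature of a downstream
#' metabolite. The observed (natural-abundance-corrected) mass
#' distribution vector is modeled as a convex mixture of two boundary
#' MDVs: the pure hydroxylation-route signature H (from a strain in which
#' the dehydrogenation route is deleted) and the pure
#' dehydrogenation-route signature D (the converse knockout).
#'
#' Two estimators are available and both are always reported:
#' \itemize{
#'   \item `"full_mdv"` (default primary): the least-squares mixing
#'     fraction `f = <obs - D, H - D> / ||H - D||^2`, the closed-form
#'     minimizer of `||obs - f H - (1-f) D||^2`, clipped to \[0, 1\].
#'   \item `"m5_ratio"`: the one-channel estimator
#'     `f = (obs_k - D_k)/(H_k - D_k)` on the fully-labeled channel
#'     (m+5 for a five-carbon glutarate skeleton), clipped to \[0, 1\].
#' }
#' The two agree exactly whenever H and D differ only in the m+0 and
#' fully-labeled channels. The two reported fractions sum to 1 exactly.
#'
#' @param observed,boundary_H,boundary_D MDVs of equal length
#'   (`mid_vector` objects or plain fraction vectors).
#' @param mode primary estimator, `"full_mdv"` or `"m5_ratio"`.
#' @param m_channel labeled mass shift used by the ratio estimator
#'   (default 5).
#' @return object of class `flux_partition`: list with
#'   `f_hydroxylation`, `f_dehydrogenation`, `residual_norm`, `mode`,
#'   `f_full_mdv`, `f_m5_ratio`, `ci_95` (NA until bootstrapped).
#' @export
fit_flux_partition <- function(observed, boundary_H, boundary_D,
                               mode = c("full_mdv", "m5_ratio"),
                               m_channel = 5) {
  mode <- match.arg(mode)
  obs <- mid_fractions(observed)
  H <- mid_fractions(boundary_H)
  D <- mid_fractions(boundary_D)
  if (length(obs) != length(H) || length(H) != length(D))
    stop("observed and boundary MDVs must have the same length")
  dHD <- H - D
  if (sqrt(sum(dHD^2)) < 1e-9)
    stop_glusense("boundary MDVs are identical; mixing fraction unidentifiable",
                  "unidentifiable")
  f_full <- min(1, max(0, sum((obs - D) * dHD) / sum(dHD^2)))
  k <- m_channel + 1
  f_m5 <- NA_real_
  if (k <= length(obs) && abs(dHD[k]) > 1e-12)
    f_m5 <- min(1, max(0, (obs[k] - D[k]) / dHD[k]))
  f <- if (mode == "full_mdv") f_full else f_m5
  if (is.na(f))
    stop("boundary MDVs do not differ on the requested labeled channel")
  resid <- sqrt(sum((obs - f * H - (1 - f) * D)^2))
  structure(list(f_hydroxylation = f, f_dehydrogenation = 1 - f,
                 residual_norm = resid, mode = mode,
                 f_full_mdv = f_full, f_m5_ratio = f_m5,
                 ci_95 = c(NA_real_, NA_real_)),
            class = "flux_partition")
}

#' @export
print.flux_partition <- function(x, ...) {
  cat(sprintf(
    "Flux partition (%s): hydroxylation %.2f%%, dehydrogenation %.2f%% (residual %.3g)\n",
    x$mode, 100 * x$f_hydroxylation, 100 * x$f_dehydrogenation,
    x$residual_norm))
  if (!anyNA(x$ci_95))
    cat(sprintf("  95%% CI for f_hydroxylation: [%.3f, %.3f]\n",
                x$ci_95[1], x$ci_95[2]))
  invisible(x)
}

#' Bootstrap confidence interval for the flux partition
#'
#' Percentile bootstrap over biological replicates: replicate MDVs are
#' resampled with replacement, averaged, and refit; the 2.5/97.5
#' percentiles of the resampled mixing fractions form the interval.
#' Deterministic for a fixed seed.
#'
#' @param replicate_mdvs list of replicate observed MDVs (>= 3), or a
#'   matrix with one replicate per row.
#' @param boundary_H,boundary_D boundary MDVs, see [fit_flux_partition()].
#' @param mode primary estimator.
#' @param n_boot number of bootstrap draws (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @return a `flux_partition` fitted on the replicate mean, with `ci_95`
#'   filled in.
#' @export
bootstrap_flux_ci <- function(replicate_mdvs, boundary_H, boundary_D,
                              mode = c("full_mdv", "m5_ratio"),
                              n_boot = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (is.matrix(replicate_mdvs))
    replicate_mdvs <- lapply(seq_len(nrow(replicate_mdvs)),
                             function(i) replicate_mdvs[i, ])
  reps <- lapply(replicate_mdvs, mid_fractions)
  if (length(reps) < 3) stop("need at least 3 replicate MDVs")
  if (n_boot < 100) warning("fewer than 100 bootstrap draws")
  mat <- do.call(rbind, reps)
  fit <- fit_flux_partition(colMeans(mat), boundary_H, boundary_D, mode)
  fs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(mat), nrow(mat), replace = TRUE)
      fit_flux_partition(colMeans(mat[idx, , drop = FALSE]),
                         boundary_H, boundary_D, mode)$f_hydroxylation
    }, numeric(1))
  })
  fit$ci_95 <- unname(quantile(fs, c(0.025, 0.975)))
  fit
}
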