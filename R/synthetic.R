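#' Scenario configuration for the synthetic-data generators
#'
#' Bundles every parameter of a synthetic experiment, with defaults set to
#' the study conditions of the glutarate biosensor system: the purified
#' sensor's dose-response truth (Rmin 1, Rmax 7.46 i.e. a 646% maximum
#' ratio change, Kd 60.68 uM, Hill slope 1), an FTS melt transition at
#' 52.3 C sampled on a 0.1 C grid from 25-95 C with 1% amplitude noise, a
#' proton-coupled uptake transporter with Km 23.34 uM probed at one-minute
#' kinetic sampling, and a 50:50 labeled/unlabeled glutarate feed
#' (tracer purity 0.99) split 93.38%/6.62% between the hydroxylation and
#' dehydrogenation catabolic routes. Every generator is a pure function of
#' (config, seed).
#'
#' @param seed integer base seed; each generator derives an independent
#'   stream from (seed, role) so adding one dataset never perturbs
#'   another.
#' @param melt,dose,uptake,labeling,comparison named lists overriding
#'   individual defaults of the corresponding generator block.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, melt = list(), dose = list(),
                            uptake = list(), labeling = list(),
                            comparison = list()) {
  defaults <- list(
    seed = seed,
    melt = list(
      Tm_C = 52.3, amplitude = 1000, transition_width_C = 1.5,
      baseline = 100, quench_rate = 0.02, noise_sd_frac = 0.01,
      grid_step_C = 0.1, T_range_C = c(25, 95)),
    dose = list(
      Rmin = 1, Rmax = 7.46, Kd_uM = 60.68, hill_p = 1,
      concentrations_uM = c(0, 2, 5, 10, 20, 40, 60, 100, 200, 400,
                            1000, 2000),
      replicates = 3, noise_model = "multiplicative", noise_sd = 0.03,
      F488 = 1000),
    uptake = list(
      Km_uM = 23.34, Vmax_uM_per_min = 60,
      substrate_levels_uM = c(5, 10, 20, 40, 80, 120, 200, 400),
      sample_interval_s = 15, duration_s = 60,
      inhibition_pct = c(CCCP = 95, PCMB = 10, iodoacetamide = 10),
      noise_sd = 0.05, conc_cap_uM = Inf),
    labeling = list(
      f_hydroxylation = 0.9338, feed_label_fraction = 0.5,
      tracer_purity = 0.99,
      fragment_formulas = list(L2HG = "C5H8O5", citrate = "C6H8O7"),
      n_tracer_carbons = list(L2HG = 5, citrate = 6),
      boundary_H = c(0.04, 0.02, 0.04, 0.10, 0.20, 0.55, 0.05),
      boundary_D = c(0.20, 0.10, 0.35, 0.25, 0.06, 0.03, 0.01),
      noise_sd = 0.01, replicates = 3, total_area = 1e6),
    comparison = list(
      spike_levels_uM = c(0, 5, 10, 25, 50, 75, 100, 150, 200, 300,
                          400, 500, 600, 750, 1000, 1200, 1400, 1600,
                          1800, 2000),
      replicates = 3, sensor_noise_sd = 0.03, reference_noise_sd = 0.02,
      mixing_ratio = 3))
  cfg <- defaults
  for (blk in c("melt", "dose", "uptake", "labeling", "comparison"))
    cfg[[blk]] <- modifyList(cfg[[blk]], get(blk))
  stopifnot(cfg$melt$transition_width_C > 0,
            cfg$melt$grid_step_C >= 0.05, cfg$melt$grid_step_C <= 1,
            cfg$labeling$f_hydroxylation >= 0,
            cfg$labeling$f_hydroxylation <= 1,
            cfg$labeling$feed_label_fraction >= 0,
            cfg$labeling$feed_label_fraction <= 1)
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate synthetic FTS melt curves
#'
#' Simulates one melt curve per requested condition:
#' `F(T) = baseline + amplitude * logistic((T - Tm)/width) * quench(T)`
#' plus Gaussian noise, where the quench factor
#' `exp(-quench_rate * max(0, T - (Tm + 3 width)))` reproduces the
#' post-transition fluorescence decay of dye-based DSF. The inflection of
#' the noiseless curve sits exactly at the configured Tm.
#'
#' @param cfg a [scenario_config()].
#' @param seed RNG seed (defaults to the scenario seed).
#' @param shifts named numeric vector of programmed thermal shifts in
#'   degrees C; one curve is generated per entry, with the entry named
#'   `"none"` (shift 0) acting as the apo reference.
#' @param replicates curves per condition (default 1).
#' @return list with `curves` (list of [melt_curve()]) and `truth`
#'   (data.frame of programmed Tm per curve).
#' @export
gen_melt_curve <- function(cfg = scenario_config(), seed = cfg$seed,
                           shifts = c(none = 0), replicates = 1) {
  m <- cfg$melt
  Tv <- seq(m$T_range_C[1], m$T_range_C[2], by = m$grid_step_C)
  with_seed(derive_seed(seed, "melt"), {
    curves <- list()
    truth <- list()
    for (lig in names(shifts)) {
      tm <- m$Tm_C + shifts[[lig]]
      for (r in seq_len(replicates)) {
        f <- m$baseline +
          m$amplitude * plogis((Tv - tm) / m$transition_width_C) *
          exp(-m$quench_rate * pmax(0, Tv - (tm + 3 * m$transition_width_C)))
        f <- f + rnorm(length(Tv), 0, m$noise_sd_frac * m$amplitude)
        id <- sprintf("%s_rep%d", lig, r)
        curves[[id]] <- melt_curve(Tv, f, sample_id = id, ligand = lig,
                                   ligand_conc_uM = if (lig == "none") NA else 100)
        truth[[id]] <- data.frame(sample_id = id, ligand = lig,
                                  Tm_true_C = tm,
                                  delta_Tm_true_C = shifts[[lig]],
                                  stringsAsFactors = FALSE)
      }
    }
    list(curves = curves, truth = do.call(rbind, truth))
  })
}

hill_cfg <- function(d, conc) hill_ratio(conc, d$Rmin, d$Rmax, d$Kd_uM, d$hill_p)

## Apply the configured noise model to true ratios.
noise_ratio <- function(r_true, noise_model, noise_sd) {
  if (noise_sd == 0) return(r_true)
  if (noise_model == "multiplicative") r_true * (1 + rnorm(length(r_true), 0, noise_sd))
  else r_true + rnorm(length(r_true), 0, noise_sd)
}

plate_rows <- function(well_id, condition, conc, ratio, F488, replicate,
                       timepoint_s = NA_real_, construct = "sensor") {
  data.frame(
    well_id = rep(well_id, each = 2),
    condition = rep(condition, each = 2),
    analyte_conc_uM = rep(conc, each = 2),
    channel = rep(c("F405", "F488"), length(well_id)),
    value = as.vector(rbind(ratio * F488, rep(F488, length(well_id)))),
    replicate = rep(replicate, each = 2),
    timepoint_s = rep(timepoint_s, each = 2),
    construct = rep(construct, each = 2),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic dose-response calibration plate
#'
#' Simulates dual-channel fluorescence readings for a calibration series:
#' true ratios follow the Hill model at the configured truth parameters,
#' noise is applied to the ratio per the configured noise model, and the
#' two channels are emitted consistently (F488 fixed at its configured
#' level, F405 = ratio x F488).
#'
#' @param cfg a [scenario_config()].
#' @param seed RNG seed (defaults to the scenario seed).
#' @return list with `table` (long-format plate data.frame, two channel
#'   rows per well, readable by [read_plate_measurements()]) and `truth`
#'   (the generating parameters).
#' @export
gen_dose_response <- function(cfg = scenario_config(), seed = cfg$seed) {
  d <- cfg$dose
  with_seed(derive_seed(seed, "dose"), {
    grid <- expand.grid(conc = d$concentrations_uM,
                        rep = seq_len(d$replicates))
    r_true <- hill_cfg(d, grid$conc)
    r_obs <- noise_ratio(r_true, d$noise_model, d$noise_sd)
    wells <- sprintf("W%03d", seq_len(nrow(grid)))
    tab <- plate_rows(wells, "calibration", grid$conc, r_obs, d$F488,
                      grid$rep)
    list(table = tab,
         truth = list(Rmin = d$Rmin, Rmax = d$Rmax, Kd_uM = d$Kd_uM,
                      hill_p = d$hill_p,
                      delta_Rmax = (d$Rmax - d$Rmin) / d$Rmin))
  })
}

#' Generate a pH-series plate with sensor and reference constructs
#'
#' Emulates the pH-stability control experiment: the sensor ratio at a
#' fixed analyte concentration and the unfused reference fluorophore are
#' both scaled by a shared pH-dependent factor, so reference correction
#' should flatten the series while the uncorrected sensor ratio varies
#' with pH.
#'
#' @param cfg a [scenario_config()].
#' @param seed RNG seed.
#' @param pH pH values of the series.
#' @param conc_uM fixed analyte concentration (default 1000 uM).
#' @return list with `table` (plate rows for both constructs; the pH is
#'   stored in `condition`) and `truth` (the shared pH factors).
#' @export
gen_ph_series <- function(cfg = scenario_config(), seed = cfg$seed,
                          pH = seq(6.6, 8.2, by = 0.2), conc_uM = 1000) {
  d <- cfg$dose
  with_seed(derive_seed(seed, "ph"), {
    g <- 0.6 + 0.05 * (pH - 6.6) / 0.2  # shared pH response of the chromophore
    r_sensor <- noise_ratio(hill_cfg(d, rep(conc_uM, length(pH))) * g,
                            d$noise_model, d$noise_sd)
    r_ref <- noise_ratio(g, d$noise_model, d$noise_sd)
    tab <- rbind(
      plate_rows(sprintf("S%02d", seq_along(pH)), sprintf("pH%.1f", pH),
                 conc_uM, r_sensor, d$F488, 1L, construct = "sensor"),
      plate_rows(sprintf("R%02d", seq_along(pH)), sprintf("pH%.1f", pH),
                 conc_uM, r_ref, d$F488, 1L, construct = "reference"))
    list(table = tab, truth = list(pH = pH, factor = g))
  })
}

#' Generate synthetic uptake-assay time courses
#'
#' Simulates sensor-reported intracellular concentration during substrate
#' uptake: the concentration rises at the Michaelis-Menten rate
#' `v = Vmax S/(Km + S)` (constant external substrate over the short
#' assay, optionally capped at `conc_cap_uM`), inhibitor treatments scale
#' the rate by `1 - inhibition/100`, and the concentration is mapped
#' through the sensor's Hill model to noisy ratio readings.
#'
#' @param cfg a [scenario_config()].
#' @param seed RNG seed.
#' @param treatments character vector of conditions to simulate:
#'   `"none"` plus any names of `cfg$uptake$inhibition_pct`.
#' @return list with `table` (time-stamped plate rows; condition encodes
#'   `substrate:treatment`) and `truth` (per-condition true initial rates
#'   and the kinetic constants).
#' @export
gen_uptake_assay <- function(cfg = scenario_config(), seed = cfg$seed,
                             treatments = "none") {
  u <- cfg$uptake
  d <- cfg$dose
  stopifnot(u$duration_s >= 3 * u$sample_interval_s)
  with_seed(derive_seed(seed, "uptake"), {
    times <- seq(0, u$duration_s, by = u$sample_interval_s)
    tabs <- list()
    truth <- list()
    w <- 0
    for (tr in treatments) {
      scale <- if (tr == "none") 1
               else 1 - u$inhibition_pct[[tr]] / 100
      for (S in u$substrate_levels_uM) {
        w <- w + 1
        v <- u$Vmax_uM_per_min * S / (u$Km_uM + S) * scale
        conc <- pmin(v * times / 60, u$conc_cap_uM)
        r_obs <- noise_ratio(hill_cfg(d, conc), "multiplicative", u$noise_sd)
        tabs[[w]] <- plate_rows(
          rep(sprintf("U%03d", w), length(times)),
          sprintf("S%g:%s", S, tr), S, r_obs, d$F488, 1L,
          timepoint_s = times)
        truth[[w]] <- data.frame(substrate_conc_uM = S, treatment = tr,
                                 rate_true_uM_per_min = v,
                                 stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, tabs),
         truth = list(rates = do.call(rbind, truth), Km_uM = u$Km_uM,
                      Vmax_uM_per_min = u$Vmax_uM_per_min))
  })
}

#' Generate a synthetic 13C labeling dataset
#'
#' Simulates the GC-MS isotopologue table of a 50:50 labeled/unlabeled
#' glutarate feeding experiment across three strains: the wild type and
#' the two single-pathway knockouts supplying the boundary signatures.
#' True MDVs: the C5 metabolite of the hydroxylation route inherits the
#' feed distribution (unlabeled fraction at m+0, labeled fraction
#' binomially thinned by tracer purity at m+5); the wild-type citrate
#' fragment is the convex mixture `f H + (1-f) D` of the knockout
#' boundary MDVs. Each true MDV is forward-convolved with the natural
#' isotope distribution of its fragment formula (via the correction
#' matrix), scaled to a total peak area, and perturbed with additive
#' Gaussian noise (clipped at zero).
#'
#' @param cfg a [scenario_config()].
#' @param seed RNG seed.
#' @return list with `table` (long isotopologue data.frame readable by
#'   [read_isotopologue_table()]) and `truth` (true mixing fraction,
#'   boundary and feed MDVs).
#' @export
gen_labeling_dataset <- function(cfg = scenario_config(), seed = cfg$seed) {
  l <- cfg$labeling
  stopifnot(abs(sum(l$boundary_H) - 1) < 1e-9,
            abs(sum(l$boundary_D) - 1) < 1e-9,
            all(l$boundary_H >= 0), all(l$boundary_D >= 0))
  feed <- c(1 - l$feed_label_fraction, numeric(4)) # m+0..m+4
  feed <- c(feed, 0)
  lab <- dbinom(0:5, 5, l$tracer_purity) * l$feed_label_fraction
  feed <- feed + lab
  truths <- list(
    L2HG = list(WT = feed, dCsiD = NULL, dGcdH = feed),
    citrate = list(
      WT = l$f_hydroxylation * l$boundary_H +
        (1 - l$f_hydroxylation) * l$boundary_D,
      dCsiD = l$boundary_D, dGcdH = l$boundary_H))
  with_seed(derive_seed(seed, "labeling"), {
    rows <- list()
    k <- 0
    for (met in names(truths)) {
      M <- build_correction_matrix(l$fragment_formulas[[met]],
                                   l$n_tracer_carbons[[met]],
                                   l$tracer_purity)
      for (strain in names(truths[[met]])) {
        x <- truths[[met]][[strain]]
        if (is.null(x)) next
        mu <- drop(M$matrix %*% x) * l$total_area
        # report the realistic acquisition envelope m+0 .. m+(n+2)
        mu <- mu[seq_len(min(length(mu), l$n_tracer_carbons[[met]] + 3))]
        for (r in seq_len(l$replicates)) {
          areas <- pmax(0, mu + rnorm(length(mu), 0,
                                      l$noise_sd * l$total_area))
          k <- k + 1
          rows[[k]] <- data.frame(
            strain = strain, metabolite = met,
            fragment_formula = l$fragment_formulas[[met]],
            mass_shift = seq_along(areas) - 1,
            peak_area = areas, replicate = r,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(table = do.call(rbind, rows),
         truth = list(f_hydroxylation = l$f_hydroxylation,
                      boundary_H = l$boundary_H, boundary_D = l$boundary_D,
                      feed_mdv = feed))
  })
}

#' Generate a paired sensor/reference-method comparison dataset
#'
#' Emulates a spike-recovery experiment: known glutarate amounts are
#' spiked into a sample matrix and measured in triplicate by the sensor
#' and independently by a reference chromatographic method with its own
#' noise. As in bench practice, each sample is pre-diluted into the
#' sensor's informative range before the 3:1 sample:sensor mixing step
#' (the smallest factor from 1/2/5/10/20/50/100 that brings the expected
#' in-well concentration to about 1.5 Kd or less); the applied factors
#' are reported in `dilutions` and must be folded into the
#' quantification's dilution argument together with the 4/3 mixing
#' factor.
#'
#' @param cfg a [scenario_config()].
#' @param seed RNG seed.
#' @return list with `plate` (sensor plate rows; `condition` carries the
#'   sample id), `dilutions` (data.frame `sample_id`, `predilution`),
#'   `reference` (data.frame `sample_id`, `conc_uM` from the reference
#'   method) and `truth` (the spiked concentrations).
#' @export
gen_method_comparison <- function(cfg = scenario_config(), seed = cfg$seed) {
  cm <- cfg$comparison
  d <- cfg$dose
  mixing <- (cm$mixing_ratio + 1) / cm$mixing_ratio
  steps <- c(1, 2, 5, 10, 20, 50, 100)
  predil <- vapply(cm$spike_levels_uM, function(sp) {
    ok <- steps[sp / mixing / steps <= 1.5 * d$Kd_uM]
    if (length(ok)) min(ok) else max(steps)
  }, numeric(1))
  with_seed(derive_seed(seed, "comparison"), {
    grid <- expand.grid(i = seq_along(cm$spike_levels_uM),
                        rep = seq_len(cm$replicates))
    spike <- cm$spike_levels_uM[grid$i]
    in_well <- spike / (mixing * predil[grid$i])
    r_obs <- noise_ratio(hill_cfg(d, in_well), "multiplicative",
                         cm$sensor_noise_sd)
    ids <- sprintf("spike_%g", spike)
    plate <- plate_rows(sprintf("Q%03d", seq_len(nrow(grid))), ids,
                        NA_real_, r_obs, d$F488, grid$rep)
    ref <- data.frame(
      sample_id = sprintf("spike_%g", cm$spike_levels_uM),
      conc_uM = pmax(0, cm$spike_levels_uM *
                       (1 + rnorm(length(cm$spike_levels_uM), 0,
                                  cm$reference_noise_sd))),
      stringsAsFactors = FALSE)
    list(plate = plate,
         dilutions = data.frame(
           sample_id = sprintf("spike_%g", cm$spike_levels_uM),
           predilution = predil, stringsAsFactors = FALSE),
         reference = ref,
         truth = data.frame(sample_id = sprintf("spike_%g", cm$spike_levels_uM),
                            spike_uM = cm$spike_levels_uM,
                            stringsAsFactors = FALSE))
  })
}
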