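# glusense

Analysis toolkit for ratiometric fluorescent glutarate biosensor
experiments. Genetically encoded sensors built from the CsiR ligand-binding
domain and a circularly permuted yellow fluorescent protein report glutarate
through the ratio of emission at 528 nm under 405 nm and 488 nm excitation
(R = F405/F488). This package implements the quantitative workflows such a
sensor supports, for protein biochemists and metabolic engineers who have
the plate-reader, melt-curve and GC-MS exports but not the analysis code:

* **Thermal-shift screening** — melting temperatures (Tm) from
  differential-scanning-fluorimetry melt curves via smoothed derivative
  analysis, ligand-induced shifts (ΔTm) against the apo control, and binder
  calls at a strict 2 °C threshold.
* **Dose–response calibration and absolute quantification** — the
  four-parameter Hill model

  R(C) = Rmax + (Rmin − Rmax) / (1 + (C/Kd)^p)

  fitted by Levenberg–Marquardt, its exact inverse
  C = Kd·((R − Rmin)/(Rmax − R))^(1/p) for quantification with censoring
  outside [Rmin, Rmax], the dynamic range ΔRmax = (Rmax − Rmin)/Rmin, a
  3σ blank-based limit of detection, reference-fluorophore (pH)
  correction, and agreement statistics against a reference method such as
  HPLC.
* **Transporter kinetics** — sensor ratio time courses inverted to
  intracellular concentration, initial uptake rates by windowed OLS,
  Michaelis–Menten fits (v = Vmax·S/(Km + S)), and threshold-based
  classification of inhibitor panels (e.g. complete suppression by a
  protonophore ⇒ proton-coupled transport).
* **¹³C flux partitioning** — natural-abundance correction of GC-MS
  isotopologue intensities through an explicitly constructed convolution
  matrix inverted by nonnegative least squares, and estimation of the flux
  split between two catabolic routes (glutarate hydroxylation vs
  glutaryl-CoA dehydrogenation) by least-squares mixing of boundary mass
  distribution vectors from single-pathway knockout strains, with a
  bootstrap confidence interval.
* **Synthetic data** — seeded generators for every input format, with truth
  records, so each estimator is covered by parameter-recovery tests.

## Worked example

```r
library(glusense)
sc <- scenario_config(seed = 42)

# 1. calibrate the sensor from a (here: simulated) calibration plate
g <- gen_dose_response(sc)
write.csv(g$table, "plate.csv", row.names = FALSE, quote = FALSE)
meas <- read_plate_measurements("plate.csv")
cal <- fit_dose_response(meas)
cal
#> Ratiometric dose-response fit
#>   Rmin = 0.9835, Rmax = 7.562  (dRmax = 668.8%)
#>   Kd = 63.33 uM, Hill p = 0.974
#>   n = 36 points, residual sd = 0.143

# 2. detection limit and quantification of an unknown (3:1 mixing => 4/3)
estimate_lod(cal, meas$ratio[meas$analyte_conc_uM == 0])
#> [1] 0.7072563
unknown <- data.frame(sample_id = "serum_A",
                      ratio = rep(predict_ratio(cal, 45), 3))
quantify_samples(cal, unknown, dilution = 4/3)
#>   sample_id conc_uM ci_low_uM ci_high_uM  censoring dilution_factor n
#> 1   serum_A      60  56.84949   63.15051 quantified        1.333333 3

# 3. pathway split from a 13C labeling experiment
gl <- gen_labeling_dataset(sc)
M  <- build_correction_matrix("C6H8O7", 6, tracer_purity = 0.99)
cit <- gl$table[gl$table$metabolite == "citrate", ]
mids <- lapply(split(cit, list(cit$strain, cit$replicate), drop = TRUE),
               function(x) correct_mid(x$peak_area, M)$fractions)
strain <- sub("\\..*", "", names(mids))
avg <- function(s) colMeans(do.call(rbind, mids[strain == s]))
fit_flux_partition(avg("WT"), avg("dGcdH"), avg("dCsiD"))
#> Flux partition (full_mdv): hydroxylation 96.68%, dehydrogenation 3.32% (residual 0.0193)
```

The calibration recovers the simulated sensor's constants (Kd 60.68 µM,
ΔRmax 646%) within the noise of a single 36-point plate; a ratio measured
at 45 µM in-well quantifies to 60 µM in the undiluted sample after the
4/3 mixing correction; the flux estimate recovers the programmed 93.38%
hydroxylation share to within replicate scatter for one seed.

A command-line wrapper over the same functions is installed as
`inst/scripts/glusense`, with subcommands `fts`, `calibrate`, `quantify`,
`transport`, `flux` and `simulate`, each taking `--config`, `--in`,
`--out`, `--seed` and `--log-level`. Reports are deterministic for a fixed
config and seed.

See `vignettes/glusense-methods.Rmd` for the models, numerical choices and
known limitations.

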