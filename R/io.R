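#' Default column mapping for plate-reader tables
#'
#' Maps the logical fields of a dual-channel plate measurement to the
#' column names of a delimited export. The defaults match the fixture
#' format written by the synthetic-data generators; instrument exports
#' with different headers are accommodated by overriding entries (in code
#' or through the YAML config of the command-line tools) rather than by
#' guessing.
#'
#' @param ... named overrides, e.g. `value = "RFU"`.
#' @return named list of column names.
#' @export
plate_layout <- function(...) {
  modifyList(list(well_id = "well_id", condition = "condition",
                  analyte_conc_uM = "analyte_conc_uM", channel = "channel",
                  value = "value", replicate = "replicate",
                  timepoint_s = "timepoint_s", construct = "construct",
                  conc_unit = "conc_unit"),
             list(...))
}

read_delim_checked <- function(source, sep = ",") {
  df <- read.csv(source, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (nrow(df) == 0) stop("input table is empty")
  df
}

#' Read dual-channel plate measurements
#'
#' Parses a long-format plate-reader export (one row per well, channel
#' and timepoint; comma-separated by default, UTF-8, `.` decimal) and
#' pairs the two excitation channels into ratiometric measurements with
#' `ratio = F405 / F488`. Concentrations are canonicalized to uM; a
#' `conc_unit` column holding `"mM"` or `"M"` triggers conversion.
#'
#' @param source path or connection to the delimited table.
#' @param layout a [plate_layout()] column mapping.
#' @param sep field separator (`","` default, `"\t"` accepted).
#' @return data.frame of class `ratio_measurements`, one row per
#'   well/timepoint: `well_id`, `condition`, `analyte_conc_uM`,
#'   `replicate`, `timepoint_s`, `construct`, `F405`, `F488`, `ratio`.
#' @export
read_plate_measurements <- function(source, layout = plate_layout(),
                                    sep = ",") {
  df <- read_delim_checked(source, sep)
  for (fld in c("well_id", "channel", "value")) {
    if (!layout[[fld]] %in% names(df))
      stop_glusense(sprintf("missing mandatory column '%s'", layout[[fld]]),
                    "format_error")
  }
  get_col <- function(fld, default) {
    if (layout[[fld]] %in% names(df)) df[[layout[[fld]]]]
    else rep(default, nrow(df))
  }
  value <- df[[layout$value]]
  bad <- which(!is.finite(value) | value <= 0)
  if (length(bad))
    stop_glusense(
      sprintf("nonpositive or missing fluorescence in row(s) %s",
              paste(head(bad + 1, 10), collapse = ", ")),
      "validation_error")
  conc <- get_col("analyte_conc_uM", NA_real_)
  unit <- get_col("conc_unit", "uM")
  conc <- conc * ifelse(unit == "mM", 1e3, ifelse(unit == "M", 1e6, 1))
  long <- data.frame(
    well_id = as.character(df[[layout$well_id]]),
    condition = as.character(get_col("condition", NA_character_)),
    analyte_conc_uM = conc,
    channel = as.character(df[[layout$channel]]),
    value = value,
    replicate = as.integer(get_col("replicate", 1L)),
    timepoint_s = as.numeric(get_col("timepoint_s", NA_real_)),
    construct = as.character(get_col("construct", "sensor")),
    stringsAsFactors = FALSE)
  if (!all(long$channel %in% c("F405", "F488")))
    stop_glusense("channel column must contain only F405/F488",
                  "validation_error")
  key <- paste(long$well_id, long$channel, long$timepoint_s)
  if (anyDuplicated(key))
    stop_glusense("duplicate (well, channel, timepoint) readings",
                  "validation_error")
  f405 <- long[long$channel == "F405", ]
  f488 <- long[long$channel == "F488", ]
  k405 <- paste(f405$well_id, f405$timepoint_s)
  k488 <- paste(f488$well_id, f488$timepoint_s)
  orphans <- c(setdiff(k405, k488), setdiff(k488, k405))
  if (length(orphans))
    stop_glusense(sprintf("unpaired channel readings for: %s",
                          paste(head(orphans, 10), collapse = "; ")),
                  "pairing_error")
  m <- match(k405, k488)
  out <- f405[c("well_id", "condition", "analyte_conc_uM", "replicate",
                "timepoint_s", "construct")]
  out$F405 <- f405$value
  out$F488 <- f488$value[m]
  out$ratio <- out$F405 / out$F488
  out <- out[order(out$well_id, out$timepoint_s), ]
  rownames(out) <- NULL
  class(out) <- c("ratio_measurements", "data.frame")
  out
}

#' Write plate measurements back to the long channel format
#'
#' Inverse of [read_plate_measurements()] for round-tripping fixtures:
#' each measurement is expanded to its two channel rows.
#'
#' @param meas a `ratio_measurements` data.frame.
#' @param path output CSV path.
#' @export
write_plate_measurements <- function(meas, path) {
  n <- nrow(meas)
  long <- data.frame(
    well_id = rep(meas$well_id, each = 2),
    condition = rep(meas$condition, each = 2),
    analyte_conc_uM = rep(meas$analyte_conc_uM, each = 2),
    channel = rep(c("F405", "F488"), n),
    value = as.vector(rbind(meas$F405, meas$F488)),
    replicate = rep(meas$replicate, each = 2),
    timepoint_s = rep(meas$timepoint_s, each = 2),
    construct = rep(meas$construct, each = 2),
    stringsAsFactors = FALSE)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach reference-construct ratios to sensor measurements
#'
#' Joins the mean ratio of `construct == "reference"` wells to the sensor
#' wells sharing the same condition and timepoint, adding a
#' `reference_ratio` column for use with [reference_correct()].
#'
#' @param meas a `ratio_measurements` data.frame containing both
#'   constructs.
#' @return the sensor rows with a `reference_ratio` column.
#' @export
attach_reference <- function(meas) {
  sens <- meas[meas$construct == "sensor", ]
  ref <- meas[meas$construct == "reference", ]
  if (nrow(ref) == 0)
    stop_glusense("no reference-construct wells present", "missing_reference")
  key <- function(df) paste(df$condition, df$timepoint_s)
  ref_mean <- tapply(ref$ratio, key(ref), mean)
  sens$reference_ratio <- unname(ref_mean[key(sens)])
  sens
}

#' Read melt-curve exports
#'
#' Parses a delimited melt-curve table with columns `sample_id`,
#' `ligand`, `ligand_conc_uM`, `temperature_C`, `fluorescence` into one
#' [melt_curve()] per sample, sorted by ascending temperature (row order
#' in the file is irrelevant). Duplicate temperatures within a sample and
#' curves with fewer than 10 points are rejected.
#'
#' @param source path or connection.
#' @param sep field separator.
#' @return named list of [melt_curve()] objects.
#' @export
read_melt_curve_table <- function(source, sep = ",") {
  df <- read_delim_checked(source, sep)
  need <- c("sample_id", "ligand", "ligand_conc_uM", "temperature_C",
            "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_glusense(sprintf("missing mandatory column '%s'", miss[1]),
                  "format_error")
  lapply(split(df, df$sample_id), function(g) {
    melt_curve(g$temperature_C, g$fluorescence,
               sample_id = g$sample_id[1], ligand = g$ligand[1],
               ligand_conc_uM = g$ligand_conc_uM[1])
  })
}

#' Write melt curves to the tabular export format
#'
#' @param curves list of [melt_curve()] objects.
#' @param path output CSV path.
#' @export
write_melt_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, ligand = cv$ligand,
               ligand_conc_uM = cv$ligand_conc_uM,
               temperature_C = cv$temperature_C,
               fluorescence = cv$fluorescence, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GC-MS isotopologue peak-area table
#'
#' Parses a long-format table with columns `strain`, `metabolite`,
#' `fragment_formula`, `mass_shift`, `peak_area` and (optionally)
#' `replicate` into dense per-record area vectors: for each
#' (strain, metabolite, replicate) the areas are placed at their mass
#' shift (m+0 first) and missing shifts are filled with zero, aligned to
#' the maximum shift observed for that metabolite. A missing replicate
#' column is treated as replicate 1 with a warning; a mass shift beyond
#' the fragment's carbon count plus two (the heavy-isotope envelope of a
#' typical derivatized fragment) warns but keeps the row.
#'
#' @param source path or connection.
#' @param sep field separator.
#' @return data.frame of records with list-column `areas`; one row per
#'   (strain, metabolite, replicate).
#' @export
read_isotopologue_table <- function(source, sep = ",") {
  df <- read_delim_checked(source, sep)
  need <- c("strain", "metabolite", "fragment_formula", "mass_shift",
            "peak_area")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_glusense(sprintf("missing mandatory column '%s'", miss[1]),
                  "format_error")
  if (!"replicate" %in% names(df)) {
    warning("no replicate column; treating all rows as replicate 1")
    df$replicate <- 1L
  }
  if (any(df$peak_area < 0))
    stop_glusense("negative peak areas", "validation_error")
  nC <- vapply(df$fragment_formula, function(f) {
    cnt <- parse_formula(f)
    if ("C" %in% names(cnt)) cnt[["C"]] else 0L
  }, numeric(1))
  high <- df$mass_shift > nC + 2
  if (any(high))
    warning(sprintf("%d row(s) have mass shifts beyond carbon count + 2; retained",
                    sum(high)))
  max_shift <- tapply(df$mass_shift, df$metabolite, max)
  groups <- split(df, df[c("strain", "metabolite", "replicate")], drop = TRUE)
  recs <- lapply(groups, function(g) {
    len <- max_shift[[g$metabolite[1]]] + 1
    areas <- numeric(len)
    areas[g$mass_shift + 1] <- g$peak_area
    data.frame(strain = g$strain[1], metabolite = g$metabolite[1],
               fragment_formula = g$fragment_formula[1],
               replicate = g$replicate[1],
               areas = I(list(areas)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write isotopologue records to the long tabular format
#'
#' @param records data.frame as returned by [read_isotopologue_table()]
#'   (with an `areas` list-column), or a long data.frame as produced by
#'   [gen_labeling_dataset()].
#' @param path output CSV path.
#' @export
write_isotopologue_table <- function(records, path) {
  if ("areas" %in% names(records)) {
    rows <- lapply(seq_len(nrow(records)), function(i) {
      a <- records$areas[[i]]
      data.frame(strain = records$strain[i],
                 metabolite = records$metabolite[i],
                 fragment_formula = records$fragment_formula[i],
                 mass_shift = seq_along(a) - 1, peak_area = a,
                 replicate = records$replicate[i], stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rows)
  }
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a result report
#'
#' A `result_report` is the serializable unit of analysis output: a kind
#' label, named parameters each carrying an explicit unit string, free
#' diagnostics, and provenance (configuration digest, seed, package
#' version).
#'
#' @param analysis_kind short label, e.g. `"dose_response_fit"`.
#' @param parameters named list; each element either
#'   `list(value =, unit =)` or a bare number (unit
#'   `"dimensionless"`).
#' @param diagnostics named list of auxiliary values.
#' @param config_digest provenance digest of the configuration (any
#'   string; see [read_config()]).
#' @param seed the seed the analysis was run with.
#' @return object of class `result_report`.
#' @export
result_report <- function(analysis_kind, parameters, diagnostics = list(),
                          config_digest = "unconfigured", seed = NA) {
  parameters <- lapply(parameters, function(p) {
    if (is.list(p)) {
      stopifnot(!is.null(p$value), is.character(p$unit), nzchar(p$unit))
      p
    } else list(value = p, unit = "dimensionless")
  })
  if (!nzchar(analysis_kind) || !nzchar(config_digest))
    stop("analysis kind and provenance fields must be non-empty")
  structure(list(analysis_kind = analysis_kind, parameters = parameters,
                 diagnostics = diagnostics,
                 provenance = list(
                   config_digest = config_digest,
                   seed = seed,
                   software = paste0("glusense ",
                                     as.character(packageVersion("glusense"))))),
            class = "result_report")
}

#' Write result reports as deterministic JSON
#'
#' Serializes one or more [result_report()]s to a human-diffable JSON
#' file. Numbers are written at full double precision (17 significant
#' digits) so that a read-write-read cycle reproduces every value
#' bit-exactly, and serialization is deterministic: the same reports
#' always produce byte-identical files.
#'
#' @param results a `result_report` or list of them (possibly empty).
#' @param dest output path.
#' @return `dest`, invisibly.
#' @export
write_report <- function(results, dest) {
  if (inherits(results, "result_report")) results <- list(results)
  payload <- list(report_format = "glusense/1",
                  n_analyses = length(results),
                  analyses = lapply(results, unclass))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           pretty = 2, null = "null", na = "null")
  con <- file(dest, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(dest)
}

#' Read a result-report file
#'
#' @param source path to a JSON file written by [write_report()].
#' @return list of `result_report` objects.
#' @export
read_report <- function(source) {
  payload <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  lapply(payload$analyses, function(a) structure(a, class = "result_report"))
}

#' Read a YAML analysis configuration
#'
#' Loads a YAML config (column layouts, fit options, thresholds, seeds)
#' and attaches a deterministic digest of its normalized content for
#' provenance tracking.
#'
#' @param path YAML file path.
#' @return named list with attribute `digest`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  digest <- sprintf("%08x", str_hash(yaml::as.yaml(cfg)))
  attr(cfg, "digest") <- digest
  cfg
}

config_digest <- function(cfg) {
  if (!is.null(attr(cfg, "digest"))) attr(cfg, "digest")
  else sprintf("%08x", str_hash(yaml::as.yaml(cfg)))
}
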