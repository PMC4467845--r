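# CSV readers/writers for the survey table schemas, bundled case-study
# data, and the end-to-end pipeline driver.

ACTIVITY_COLS <- c("sample_code", "location", "matrix", "nuclide",
                   "activity_Bq_per_kg", "uncertainty_Bq_per_kg")
METAL_COLS <- c("sample_code", "location", "element",
                "concentration_mg_per_kg")
PEAK_COLS <- c("sample_code", "progeny_nuclide", "energy_keV", "net_counts",
               "net_counts_unc", "background_counts", "live_time_s",
               "sample_mass_kg")

check_schema <- function(df, expected, what) {
  miss <- setdiff(expected, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         "; expected columns: ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  df
}

read_table_csv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "-", "NA"))
}

#' Read a long-format activity-concentration table
#'
#' Empty cells and `"-"` are read as absent measurements (a warning is
#' raised per affected row); unknown nuclide labels and negative
#' activities are errors naming the offending row.
#'
#' @param path CSV with columns `sample_code`, `location`, `matrix`,
#'   `nuclide`, `activity_Bq_per_kg`, `uncertainty_Bq_per_kg`.
#' @return validated data.frame.
#' @export
read_activity_table <- function(path) {
  df <- check_schema(read_table_csv(path, "activity table"), ACTIVITY_COLS,
                     "activity table")
  bad_nuc <- which(!df$nuclide %in% PARENT_CHAINS)
  if (length(bad_nuc)) {
    stop("unknown nuclide label '", df$nuclide[bad_nuc[1]], "' in row ",
         bad_nuc[1], " (expected one of ",
         paste(PARENT_CHAINS, collapse = ", "), ")", call. = FALSE)
  }
  neg <- which(df$activity_Bq_per_kg < 0)
  if (length(neg)) {
    stop("negative activity in row ", neg[1], call. = FALSE)
  }
  absent <- which(is.na(df$activity_Bq_per_kg))
  if (length(absent)) {
    warning(length(absent), " activity value(s) absent (non-detect rows: ",
            paste(utils::head(absent, 5), collapse = ", "), ")", call. = FALSE)
  }
  df
}

#' Read a metal concentration table (empty cell = non-detect)
#' @param path CSV with columns `sample_code`, `location`, `element`,
#'   `concentration_mg_per_kg`.
#' @return validated data.frame with `NA` marking non-detects.
#' @export
read_metal_table <- function(path) {
  df <- check_schema(read_table_csv(path, "metal table"), METAL_COLS,
                     "metal table")
  if (any(df$concentration_mg_per_kg < 0, na.rm = TRUE)) {
    stop("negative metal concentration in row ",
         which(df$concentration_mg_per_kg < 0)[1], call. = FALSE)
  }
  df
}

#' Read a gamma-peak table
#' @param path CSV in the peak-table schema (see [peaks_to_activities()]).
#' @return validated data.frame.
#' @export
read_peak_table <- function(path) {
  check_schema(read_table_csv(path, "peak table"), PEAK_COLS, "peak table")
}

#' Read an efficiency calibration table
#' @param path CSV with columns `energy_keV`, `efficiency`, `rel_unc`.
#' @return validated data.frame.
#' @export
read_efficiency_table <- function(path) {
  check_schema(read_table_csv(path, "efficiency table"),
               c("energy_keV", "efficiency"), "efficiency table")
}

#' Write a table in the package CSV dialect
#'
#' Comma-separated, UTF-8, `.` decimal separator, empty cell for missing;
#' full precision (no rounding), so write/read round-trips are lossless.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
  })
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundled case-study activity survey
#'
#' Activity concentrations (Bq/kg dry weight, with 1-sigma uncertainties)
#' of Ra-226, Th-232 and K-40 in Indian mackerel and seawater replicates
#' from three coastal sampling locations along the Straits of Malacca
#' (Bagan Lalang, Port Klang, Pantai Remis; three replicates each),
#' shipped with the package as the worked case study.
#'
#' @return data.frame in the activity-table schema (54 rows).
#' @export
malacca_activity <- function() {
  read_activity_table(system.file("extdata", "straits_malacca_activity.csv",
                                  package = "seadose", mustWork = TRUE))
}

#' Bundled case-study metal survey
#'
#' Trace-element concentrations (mg/kg dry weight) in Indian mackerel
#' from the same three locations, with non-detects recorded as missing;
#' Bagan Lalang has two analysed fish, the other locations three.
#'
#' @return data.frame in the metal-table schema.
#' @export
malacca_metals <- function() {
  suppressWarnings(
    read_metal_table(system.file("extdata", "straits_malacca_metals.csv",
                                 package = "seadose", mustWork = TRUE))
  )
}

#' Run the full measurement-to-risk pipeline
#'
#' Orchestrates the ingestion chain: activity table (given directly, read
#' from CSV, or quantified from a peak table + efficiency calibration) ->
#' per-sample intake/dose/risk with location and overall means; metal
#' table -> EDI and TDI screen; one-way ANOVA + Tukey across locations.
#' Deterministic for fixed inputs.
#'
#' @param activities activity table data.frame or CSV path (optional when
#'   `peaks` given).
#' @param metals metal table data.frame or CSV path (optional).
#' @param peaks peak table data.frame or CSV path (optional); requires
#'   `efficiency`.
#' @param efficiency efficiency calibration data.frame or CSV path, used
#'   with `peaks`.
#' @param bundle reference bundle from [load_reference_tables()].
#' @param out_dir if non-`NULL`, report tables are written there as CSV
#'   and the report as JSON.
#' @param alpha significance level for the statistics section.
#' @return list of class `risk_report`: `metadata`, `activity`,
#'   `dose_risk`, `dose_risk_means`, `activity_means`, `metals_edi`,
#'   `statistics`, `warnings`.
#' @export
run_pipeline <- function(activities = NULL, metals = NULL, peaks = NULL,
                         efficiency = NULL,
                         bundle = load_reference_tables(),
                         out_dir = NULL, alpha = 0.05) {
  warnings <- character(0)
  if (is.character(activities)) activities <- read_activity_table(activities)
  if (is.character(metals)) metals <- read_metal_table(metals)

  if (!is.null(peaks)) {
    if (is.character(peaks)) peaks <- read_peak_table(peaks)
    if (is.null(efficiency)) {
      stop("quantifying a peak table requires an efficiency calibration",
           call. = FALSE)
    }
    if (is.character(efficiency)) efficiency <- read_efficiency_table(efficiency)
    curve <- fit_efficiency(efficiency,
                            order = min(4, length(unique(efficiency$energy_keV)) - 1))
    acts <- peaks_to_activities(peaks, curve, bundle)
    if (any(acts$below_mda)) {
      warnings <- c(warnings, sprintf(
        "%d activity value(s) below MDA entered the report", sum(acts$below_mda)))
    }
    if (is.null(activities)) {
      # quantified activities: attach location/matrix if derivable from codes
      acts$location <- NA_character_
      acts$matrix <- "fish"
      activities <- data.frame(
        sample_code = acts$sample_code, location = acts$location,
        matrix = acts$matrix, nuclide = acts$nuclide,
        activity_Bq_per_kg = acts$activity_Bq_per_kg,
        uncertainty_Bq_per_kg = acts$uncertainty_Bq_per_kg,
        stringsAsFactors = FALSE
      )
    }
  }
  if (is.null(activities)) stop("no activity input provided", call. = FALSE)

  dr <- dose_risk_table(activities, bundle)
  has_loc <- !any(is.na(dr$location))
  dr_means <- if (has_loc) aggregate_rows(dr, "location") else
    aggregate_rows(dr, "all")
  act_means <- if (has_loc) activity_location_means(activities) else NULL

  metals_edi <- NULL
  if (!is.null(metals)) {
    metals_edi <- edi_table(metals, bundle)
    if (any(metals_edi$flag == "no_tdi")) {
      warnings <- c(warnings, sprintf(
        "no TDI registered for element(s): %s",
        paste(unique(metals_edi$element[metals_edi$flag == "no_tdi"]),
              collapse = ", ")))
    }
    if (any(metals_edi$flag == "exceeds_tdi")) {
      warnings <- c(warnings, sprintf(
        "EDI exceeds TDI for element(s): %s",
        paste(unique(metals_edi$element[metals_edi$flag == "exceeds_tdi"]),
              collapse = ", ")))
    }
  }

  stats_section <- list()
  if (has_loc) {
    stats_section$activity <- significance_report(
      activities[activities$matrix == "fish", ], alpha = alpha)
    if (!is.null(metals)) {
      stats_section$metals <- significance_report(metals, alpha = alpha)
    }
  }

  report <- structure(list(
    metadata = list(
      package_version = as.character(utils::packageVersion("seadose")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      alpha = alpha
    ),
    activity = activities,
    activity_means = act_means,
    dose_risk = dr,
    dose_risk_means = dr_means,
    metals_edi = metals_edi,
    statistics = stats_section,
    warnings = warnings
  ), class = "risk_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a risk report to disk
#'
#' CSV per table plus one JSON report (`report.json`); the JSON carries
#' everything, the CSVs are for spreadsheet use.
#'
#' @param report a `risk_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(report$dose_risk, file.path(out_dir, "dose_risk.csv"))
  write_table_csv(report$dose_risk_means,
                  file.path(out_dir, "dose_risk_means.csv"))
  if (!is.null(report$activity_means)) {
    write_table_csv(report$activity_means,
                    file.path(out_dir, "activity_means.csv"))
  }
  if (!is.null(report$metals_edi)) {
    write_table_csv(report$metals_edi, file.path(out_dir, "metals_edi.csv"))
  }
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", force = TRUE)
  invisible(out_dir)
}

#' @export
print.risk_report <- function(x, ...) {
  cat("seadose risk report\n")
  cat(sprintf("  %d activity rows, %d dose/risk sample rows\n",
              nrow(x$activity), nrow(x$dose_risk)))
  if (!is.null(x$metals_edi)) {
    cat(sprintf("  %d metal EDI rows (%d below TDI)\n", nrow(x$metals_edi),
                sum(x$metals_edi$flag == "below_tdi")))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n"); for (w in x$warnings) cat("   -", w, "\n")
  } else cat("  no warnings\n")
  invisible(x)
}
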