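# Estimated daily intake of heavy metals (EDI = C x W / m) and screening
# against tolerable daily intakes, with non-detect handling.

#' Location-mean metal concentration with non-detect handling
#'
#' Non-detects are excluded from the mean by default: the mean is taken
#' over detected replicates only. Substitution strategies are available
#' for sensitivity analysis.
#'
#' @param concentrations numeric vector of replicate concentrations
#'   (mg/kg dry weight) with `NA` for non-detects.
#' @param nondetect one of `"exclude"` (default), `"zero"` (substitute 0)
#'   or `"half_lod"` (substitute `lod / 2`).
#' @param lod limit of detection (mg/kg), required for `"half_lod"`.
#' @return mean concentration (mg/kg), or `NA` when every replicate is a
#'   non-detect under `"exclude"`.
#' @export
location_mean_concentration <- function(concentrations,
                                        nondetect = c("exclude", "zero",
                                                      "half_lod"),
                                        lod = NULL) {
  nondetect <- match.arg(nondetect)
  if (any(concentrations < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  x <- concentrations
  if (nondetect == "zero") {
    x[is.na(x)] <- 0
  } else if (nondetect == "half_lod") {
    if (is.null(lod)) stop("half_lod substitution needs 'lod'", call. = FALSE)
    x[is.na(x)] <- lod / 2
  } else {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
  }
  mean(x)
}

#' Estimated daily intake of a metal
#'
#' EDI = C_metal x W / m, with C_metal in mg/kg dry weight, W the daily
#' fish consumption in grams and m the adult body mass in kg; the units
#' resolve to micrograms per kg body weight per day.
#'
#' @param mean_concentration mg metal per kg fish (dry weight).
#' @param params `exposure_params` list (`daily_food_mass_g`,
#'   `body_mass_kg`).
#' @return EDI in micrograms per kg body weight per day.
#' @export
estimated_daily_intake <- function(mean_concentration,
                                   params = default_exposure_params()) {
  if (any(mean_concentration < 0, na.rm = TRUE)) {
    stop("mean_concentration must be >= 0", call. = FALSE)
  }
  stop_if_not_positive(params$body_mass_kg, "body_mass_kg")
  mean_concentration * params$daily_food_mass_g / params$body_mass_kg
}

#' Screen EDI rows against the TDI registry
#'
#' Adds the tolerable daily intake, the EDI/TDI ratio and a flag to each
#' row. A ratio of exactly 1 is classified `below_tdi` (the TDI is a
#' tolerable ceiling, inclusive); elements missing from the registry are
#' flagged `no_tdi`.
#'
#' @param edi_rows data.frame with columns `element` and
#'   `edi_ug_per_kg_bw_day`.
#' @param registry TDI registry data.frame (see [default_tdi()]).
#' @return input with `tdi_ug_per_kg_bw_day`, `ratio` and `flag` columns.
#' @export
tdi_screen <- function(edi_rows, registry = default_tdi()) {
  idx <- match(edi_rows$element, registry$element)
  edi_rows$tdi_ug_per_kg_bw_day <- registry$tdi_ug_per_kg_bw_day[idx]
  edi_rows$ratio <- edi_rows$edi_ug_per_kg_bw_day /
    edi_rows$tdi_ug_per_kg_bw_day
  edi_rows$flag <- ifelse(
    is.na(idx), "no_tdi",
    ifelse(edi_rows$ratio <= 1, "below_tdi", "exceeds_tdi")
  )
  edi_rows
}

#' Estimated-daily-intake table from a metal concentration survey
#'
#' Computes the per-location mean concentration (non-detects excluded),
#' the EDI and the TDI screen for every element x location, mirroring the
#' layout of a dietary heavy-metal screening table.
#'
#' @param metals data.frame in the metal-table schema (`sample_code`,
#'   `location`, `element`, `concentration_mg_per_kg`, `NA` = non-detect).
#' @param bundle reference bundle from [load_reference_tables()].
#' @param nondetect non-detect rule passed to
#'   [location_mean_concentration()].
#' @param lod optional limit of detection for `"half_lod"`.
#' @return data.frame with `location`, `element`,
#'   `mean_concentration_mg_per_kg`, `edi_ug_per_kg_bw_day`,
#'   `tdi_ug_per_kg_bw_day`, `ratio`, `flag`. Fully censored
#'   element/location pairs are dropped.
#' @export
edi_table <- function(metals, bundle = load_reference_tables(),
                      nondetect = "exclude", lod = NULL) {
  need <- c("sample_code", "location", "element", "concentration_mg_per_kg")
  miss <- setdiff(need, names(metals))
  if (length(miss)) {
    stop("metal table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  combos <- unique(metals[, c("location", "element")])
  rows <- vector("list", 0)
  for (i in seq_len(nrow(combos))) {
    loc <- combos$location[i]
    el <- combos$element[i]
    conc <- metals$concentration_mg_per_kg[
      metals$location == loc & metals$element == el]
    m <- location_mean_concentration(conc, nondetect = nondetect, lod = lod)
    if (is.na(m)) next  # all replicates non-detect: no EDI
    rows[[length(rows) + 1]] <- data.frame(
      location = loc, element = el,
      mean_concentration_mg_per_kg = m,
      edi_ug_per_kg_bw_day = estimated_daily_intake(m, bundle$exposure),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("every element fully censored", call. = FALSE)
  tdi_screen(do.call(rbind, rows), bundle$tdi)
}
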