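# HPGe peak areas -> parent-chain activity concentrations.
# Activity via A = N / (t * eps(E) * Pgamma * b * m) under secular
# equilibrium, quadrature uncertainty budget, Currie MDA screening.

#' Fit a full-energy-peak efficiency curve
#'
#' Least-squares polynomial of log(efficiency) against log(energy), the
#' standard parameterisation for HPGe efficiency calibrations.
#'
#' @param points data.frame with columns `energy_keV`, `efficiency` and
#'   optionally `rel_unc` (relative uncertainty of each calibration point).
#' @param order polynomial order in log-log space (default 4, capped below
#'   the number of distinct calibration energies).
#' @return object of class `efficiency_curve` holding the coefficients
#'   (ascending powers of log energy), the fit order, the RMS residual in
#'   log space and the calibration energy range.
#' @export
fit_efficiency <- function(points, order = 4) {
  if (!all(c("energy_keV", "efficiency") %in% names(points))) {
    stop("efficiency points need columns 'energy_keV' and 'efficiency'",
         call. = FALSE)
  }
  if (any(points$efficiency <= 0 | points$efficiency >= 1)) {
    stop("calibration efficiencies must lie in (0, 1)", call. = FALSE)
  }
  if (any(points$energy_keV <= 0)) stop("energies must be > 0", call. = FALSE)
  n_distinct <- length(unique(points$energy_keV))
  if (n_distinct < order + 1) {
    stop("need at least order + 1 distinct calibration energies (got ",
         n_distinct, " for order ", order, ")", call. = FALSE)
  }
  x <- log(points$energy_keV)
  y <- log(points$efficiency)
  X <- outer(x, 0:order, `^`)
  fit <- stats::lsfit(X, y, intercept = FALSE)
  coefs <- unname(fit$coefficients)
  res <- sqrt(mean(fit$residuals^2))
  structure(list(
    coefficients = coefs,
    fit_order = order,
    fit_residual = res,
    energy_range_keV = range(points$energy_keV)
  ), class = "efficiency_curve")
}

#' Evaluate an efficiency curve at given energies
#'
#' @param curve an `efficiency_curve` from [fit_efficiency()].
#' @param energy_keV energies at which to evaluate.
#' @param allow_extrapolation evaluate outside the calibration range
#'   instead of erroring; a warning is still raised.
#' @return full-energy-peak efficiencies (fractions).
#' @export
efficiency_at <- function(curve, energy_keV, allow_extrapolation = FALSE) {
  stopifnot(inherits(curve, "efficiency_curve"))
  if (any(energy_keV <= 0)) stop("energy must be > 0", call. = FALSE)
  rng <- curve$energy_range_keV
  outside <- energy_keV < rng[1] | energy_keV > rng[2]
  if (any(outside)) {
    msg <- sprintf("efficiency extrapolated outside calibration range [%.1f, %.1f] keV",
                   rng[1], rng[2])
    if (!allow_extrapolation) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  lx <- log(energy_keV)
  X <- outer(lx, seq_along(curve$coefficients) - 1, `^`)
  exp(drop(X %*% curve$coefficients))
}

#' @export
print.efficiency_curve <- function(x, ...) {
  cat(sprintf("log-log polynomial efficiency curve, order %d\n", x$fit_order))
  cat(sprintf("  calibration range: %.1f-%.1f keV, RMS log residual %.3g\n",
              x$energy_range_keV[1], x$energy_range_keV[2], x$fit_residual))
  invisible(x)
}

#' Combine independent relative uncertainties in quadrature
#'
#' @param relative_components vector of relative (fractional or percent,
#'   units are preserved) uncertainty components, all >= 0.
#' @return square root of the sum of squares; 0 for an empty input.
#' @export
propagate_uncertainty <- function(relative_components) {
  if (length(relative_components) == 0) return(0)
  if (any(relative_components < 0)) {
    stop("uncertainty components must be >= 0", call. = FALSE)
  }
  sqrt(sum(relative_components^2))
}

#' Activity concentration from a single gamma peak
#'
#' A = N / (t * eps * Pgamma * b * m), with relative uncertainty from the
#' quadrature of counting statistics and the systematic budget.
#'
#' @param net_counts net peak area (counts).
#' @param net_counts_unc absolute uncertainty of the net area; defaults to
#'   `sqrt(net_counts)`.
#' @param live_time_s counting live time (s).
#' @param efficiency full-energy-peak efficiency at the line energy.
#' @param intensity gamma emission intensity (photons per decay).
#' @param branching_factor chain-decay branch multiplier (default 1).
#' @param sample_mass_kg dry sample mass (kg).
#' @param budget named vector of systematic relative uncertainty
#'   components (see [default_uncertainty_budget()]).
#' @return list with `value` (Bq/kg), `uncertainty` (Bq/kg, 1 sigma) and
#'   `rel_uncertainty`.
#' @export
line_activity <- function(net_counts, live_time_s, efficiency, intensity,
                          sample_mass_kg, branching_factor = 1,
                          net_counts_unc = sqrt(net_counts),
                          budget = default_uncertainty_budget()) {
  if (net_counts < 0) stop("net_counts must be >= 0", call. = FALSE)
  stop_if_not_positive(live_time_s, "live_time_s")
  stop_if_not_positive(efficiency, "efficiency")
  stop_if_not_positive(intensity, "intensity")
  stop_if_not_positive(branching_factor, "branching_factor")
  stop_if_not_positive(sample_mass_kg, "sample_mass_kg")
  denom <- live_time_s * efficiency * intensity * branching_factor *
    sample_mass_kg
  value <- net_counts / denom
  rel_count <- if (net_counts > 0) net_counts_unc / net_counts else 0
  rel <- propagate_uncertainty(c(rel_count, unname(budget)))
  list(value = value, uncertainty = value * rel, rel_uncertainty = rel)
}

#' Currie minimum detectable activity (95% confidence)
#'
#' MDA = (2.71 + 4.65 sqrt(B)) / (t * eps * Pgamma * m), with B the
#' background (continuum) counts under the peak region.
#'
#' @param background_counts background counts under the peak.
#' @param efficiency full-energy-peak efficiency.
#' @param intensity gamma emission intensity.
#' @param live_time_s counting live time (s).
#' @param sample_mass_kg sample mass (kg).
#' @param branching_factor chain branch multiplier (default 1).
#' @return MDA in Bq/kg.
#' @export
minimum_detectable_activity <- function(background_counts, efficiency,
                                        intensity, live_time_s,
                                        sample_mass_kg,
                                        branching_factor = 1) {
  if (background_counts < 0) stop("background_counts must be >= 0", call. = FALSE)
  stop_if_not_positive(efficiency, "efficiency")
  stop_if_not_positive(intensity, "intensity")
  stop_if_not_positive(live_time_s, "live_time_s")
  stop_if_not_positive(sample_mass_kg, "sample_mass_kg")
  stop_if_not_positive(branching_factor, "branching_factor")
  (2.71 + 4.65 * sqrt(background_counts)) /
    (live_time_s * efficiency * intensity * branching_factor * sample_mass_kg)
}

#' Combine per-line activities into one parent-chain activity
#'
#' Inverse-variance weighted mean across the quantification lines of one
#' chain (plain mean when `weighted = FALSE` or uncertainties are absent).
#' The result always lies between the smallest and largest input value and
#' its uncertainty never exceeds the smallest input uncertainty.
#'
#' @param values per-line activity values (Bq/kg), one chain only.
#' @param uncertainties per-line 1-sigma uncertainties (Bq/kg).
#' @param weighted use 1/sigma^2 weights (default) or a plain mean.
#' @return list with `value` and `uncertainty`.
#' @export
combine_lines <- function(values, uncertainties = NULL, weighted = TRUE) {
  if (length(values) == 0) stop("no line activities to combine", call. = FALSE)
  if (is.null(uncertainties)) weighted <- FALSE
  if (weighted) {
    if (length(uncertainties) != length(values)) {
      stop("values and uncertainties must have equal length", call. = FALSE)
    }
    if (any(uncertainties <= 0)) {
      stop("weighted combination requires positive uncertainties", call. = FALSE)
    }
    w <- 1 / uncertainties^2
    list(value = sum(w * values) / sum(w), uncertainty = sqrt(1 / sum(w)))
  } else {
    unc <- if (is.null(uncertainties)) NA_real_ else
      sqrt(sum(uncertainties^2)) / length(values)
    list(value = mean(values), uncertainty = unc)
  }
}

#' Peak table to parent-chain activity concentrations
#'
#' Runs the whole quantification chain for a table of net peak areas:
#' match each peak to its gamma line, keep primary quantification lines,
#' compute per-line activities with the uncertainty budget, combine lines
#' per parent chain, and screen against the Currie MDA.
#'
#' @param peaks data.frame in the peak-table schema
#'   (`sample_code`, `progeny_nuclide`, `energy_keV`, `net_counts`,
#'   `net_counts_unc`, `background_counts`, `live_time_s`,
#'   `sample_mass_kg`).
#' @param curve an `efficiency_curve`.
#' @param bundle reference bundle (gamma lines + uncertainty budget), see
#'   [load_reference_tables()].
#' @param primary_only quantify from primary-flagged lines only (default).
#' @param allow_extrapolation passed to [efficiency_at()].
#' @return data.frame with one row per sample x parent chain:
#'   `sample_code`, `nuclide`, `activity_Bq_per_kg`,
#'   `uncertainty_Bq_per_kg`, `mda_Bq_per_kg`, `below_mda`, `n_lines`.
#' @export
peaks_to_activities <- function(peaks, curve,
                                bundle = load_reference_tables(),
                                primary_only = TRUE,
                                allow_extrapolation = FALSE) {
  lines <- bundle$gamma_lines
  if (primary_only) lines <- lines[lines$primary_flag, ]
  key <- paste(lines$progeny_nuclide, round(lines$energy_keV, 1))
  pk_key <- paste(peaks$progeny_nuclide, round(peaks$energy_keV, 1))
  idx <- match(pk_key, key)
  used <- !is.na(idx)
  if (!any(used)) stop("no peaks match a quantification line", call. = FALSE)
  peaks <- peaks[used, , drop = FALSE]
  ln <- lines[idx[used], , drop = FALSE]

  eff <- efficiency_at(curve, ln$energy_keV,
                       allow_extrapolation = allow_extrapolation)
  out <- vector("list", 0)
  for (sc in unique(peaks$sample_code)) {
    sel <- peaks$sample_code == sc
    for (ch in unique(ln$parent_chain[sel])) {
      i <- which(sel & ln$parent_chain == ch)
      vals <- unc <- mda <- numeric(length(i))
      for (k in seq_along(i)) {
        j <- i[k]
        la <- line_activity(
          net_counts = peaks$net_counts[j],
          live_time_s = peaks$live_time_s[j],
          efficiency = eff[j],
          intensity = ln$intensity[j],
          sample_mass_kg = peaks$sample_mass_kg[j],
          branching_factor = ln$branching_factor[j],
          net_counts_unc = peaks$net_counts_unc[j],
          budget = bundle$uncertainty_budget
        )
        vals[k] <- la$value
        unc[k] <- la$uncertainty
        mda[k] <- minimum_detectable_activity(
          peaks$background_counts[j], eff[j], ln$intensity[j],
          peaks$live_time_s[j], peaks$sample_mass_kg[j],
          ln$branching_factor[j]
        )
      }
      cmb <- if (all(unc > 0)) combine_lines(vals, unc) else
        combine_lines(vals, weighted = FALSE)
      # chain is detectable if its best line would be
      chain_mda <- min(mda)
      out[[length(out) + 1]] <- data.frame(
        sample_code = sc, nuclide = ch,
        activity_Bq_per_kg = cmb$value,
        uncertainty_Bq_per_kg = cmb$uncertainty,
        mda_Bq_per_kg = chain_mda,
        below_mda = cmb$value < chain_mda,
        n_lines = length(i),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
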