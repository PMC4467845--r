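# Seeded synthetic surveys mirroring the 3-location x 3-replicate fish +
# water activity design, Poisson gamma-peak counts, and metal tables with
# non-detects. One global seed is split into fixed per-module child seeds
# so each table can be regenerated independently yet reproducibly.

SEED_OFFSET <- c(activity = 101L, peaks = 211L, metals = 307L)

with_child_seed <- function(seed, module, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + SEED_OFFSET[[module]]) %% .Machine$integer.max)
  force(code)
}

#' Build a synthetic survey scenario
#'
#' Defaults emulate a three-location coastal survey with three fish and
#' three water replicates per location, true activities centred on the
#' observed location means of the case-study survey, 10% lognormal
#' replicate dispersion, an 86400 s HPGe count per sample with a log-log
#' power-law efficiency curve, and a heavy-metal profile with
#' element-specific detection probabilities.
#'
#' @param locations data.frame with columns `name`, `code`, then
#'   `fish_<chain>` and `water_<chain>` true activities (Bq/kg) for
#'   Ra-226, Th-232, K-40 (tags `Ra226`, `Th232`, `K40`).
#' @param replicates_per_location fish (and water) replicates per location.
#' @param replicate_dispersion relative s.d. of the lognormal replicate
#'   noise (0 = every replicate equals its location truth).
#' @param noise `"lognormal"` (default) or `"normal"` replicate noise.
#' @param metal_profile data.frame `element`, `mean_mg_per_kg`, `rel_sd`,
#'   `detect_probability`.
#' @param metal_replicates fish analysed for metals per location (scalar
#'   or one value per location).
#' @param efficiency_coefficients log-log polynomial coefficients of the
#'   detector efficiency curve (ascending powers of log energy).
#' @param live_time_s counting live time per sample (s).
#' @param sample_mass_range_kg dry-mass range sampled uniformly per fish.
#' @param background_counts expected continuum counts under each peak.
#' @param seed global integer seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(
    locations = default_scenario_locations(),
    replicates_per_location = 3,
    replicate_dispersion = 0.10,
    noise = c("lognormal", "normal"),
    metal_profile = default_metal_profile(),
    metal_replicates = c(2, 3, 3),
    efficiency_coefficients = c(0.416, -0.7),
    live_time_s = 86400,
    sample_mass_range_kg = c(0.12, 0.218),
    background_counts = 400,
    seed = 42L) {
  noise <- match.arg(noise)
  if (replicate_dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (any(metal_profile$detect_probability < 0 |
            metal_profile$detect_probability > 1)) {
    stop("detect_probability must lie in [0, 1]", call. = FALSE)
  }
  truth_cols <- grep("^(fish|water)_", names(locations), value = TRUE)
  if (any(locations[truth_cols] < 0)) {
    stop("true activities must be >= 0", call. = FALSE)
  }
  if (length(metal_replicates) == 1) {
    metal_replicates <- rep(metal_replicates, nrow(locations))
  }
  structure(list(
    locations = locations,
    replicates_per_location = replicates_per_location,
    replicate_dispersion = replicate_dispersion,
    noise = noise,
    metal_profile = metal_profile,
    metal_replicates = metal_replicates,
    efficiency_coefficients = efficiency_coefficients,
    live_time_s = live_time_s,
    sample_mass_range_kg = sample_mass_range_kg,
    background_counts = background_counts,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Default scenario locations (case-study location means)
#' @return data.frame consumed by [scenario_config()].
#' @export
default_scenario_locations <- function() {
  data.frame(
    name = c("Bagan Lalang", "Port Klang", "Pantai Remis"),
    code = c("Bl", "Kl", "Re"),
    fish_Ra226 = c(7.83, 6.48, 4.05),
    fish_Th232 = c(6.21, 3.71, 1.93),
    fish_K40 = c(359.2, 398.9, 288.1),
    water_Ra226 = c(1.05, 1.23, 1.18),
    water_Th232 = c(0.28, 0.35, 0.27),
    water_K40 = c(16.4, 14.8, 19.9),
    stringsAsFactors = FALSE
  )
}

#' Default heavy-metal generation profile
#'
#' Means near the observed survey averages; detection probabilities match
#' the observed detected fractions (e.g. Hg and Pb mostly censored).
#'
#' @return data.frame consumed by [scenario_config()].
#' @export
default_metal_profile <- function() {
  data.frame(
    element = c("Al", "Cr", "Mn", "Co", "Cu", "As", "Hg", "Pb"),
    mean_mg_per_kg = c(3.9, 0.037, 1.04, 0.0023, 0.113, 0.54, 0.025, 0.02),
    rel_sd = c(0.25, 0.45, 0.55, 0.50, 0.45, 0.35, 0.80, 0.50),
    detect_probability = c(1, 0.875, 1, 0.625, 1, 1, 0.375, 0.125),
    stringsAsFactors = FALSE
  )
}

# lognormal draw with arithmetic mean `mu` and relative s.d. `cv`
rlnorm_mean_cv <- function(n, mu, cv) {
  if (cv == 0 || mu == 0) return(rep(mu, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
}

draw_replicates <- function(n, mu, cv, noise) {
  if (noise == "lognormal") {
    rlnorm_mean_cv(n, mu, cv)
  } else {
    pmax(stats::rnorm(n, mu, cv * mu), 0)
  }
}

#' Generate a synthetic activity-concentration survey
#'
#' Replicate fish and water activities drawn around the location truths
#' with the configured dispersion; per-sample relative uncertainties are
#' assigned from the measurement budget (counting statistics between 0.5%
#' and 10%, plus efficiency, mass and intensity components in
#' quadrature). Deterministic for a fixed seed.
#'
#' @param config a `scenario_config`.
#' @return data.frame in the activity-table schema, with attribute
#'   `"truth"` holding the generating location means.
#' @export
generate_activity_dataset <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  with_child_seed(config$seed, "activity", {
    loc <- config$locations
    nrep <- config$replicates_per_location
    rows <- vector("list", 0)
    for (i in seq_len(nrow(loc))) {
      for (mat in c("fish", "water")) {
        prefix <- if (mat == "fish") "Fi" else "Wa"
        for (r in seq_len(nrep)) {
          code <- sprintf("%s_%s-%d", prefix, loc$code[i], r)
          for (ch in PARENT_CHAINS) {
            truth <- loc[[paste0(mat, "_", chain_tag(ch))]][i]
            val <- draw_replicates(1, truth, config$replicate_dispersion,
                                   config$noise)
            rel_count <- stats::runif(1, 0.005, 0.10)
            rel <- propagate_uncertainty(
              c(rel_count, unname(default_uncertainty_budget())))
            rows[[length(rows) + 1]] <- data.frame(
              sample_code = code, location = loc$name[i], matrix = mat,
              nuclide = ch, activity_Bq_per_kg = val,
              uncertainty_Bq_per_kg = val * rel,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- loc
    out
  })
}

#' Generate a synthetic gamma-peak table
#'
#' Draws replicate fish activities (same child activity stream as
#' [generate_activity_dataset()]), then for every primary quantification
#' line computes expected counts activity x t x eff(E) x Pgamma x branch
#' x mass, draws the gross peak area as Poisson(expected + background)
#' and reports the background-subtracted net area (floored at zero).
#'
#' @param config a `scenario_config`.
#' @param bundle reference bundle supplying the gamma-line table.
#' @return data.frame in the peak-table schema with attribute
#'   `"true_activities"` (the generated per-sample fish activities).
#' @export
generate_peak_table <- function(config = scenario_config(),
                                bundle = load_reference_tables()) {
  stopifnot(inherits(config, "scenario_config"))
  acts <- generate_activity_dataset(config)
  fish <- acts[acts$matrix == "fish", ]
  lines <- bundle$gamma_lines[bundle$gamma_lines$primary_flag, ]
  eff <- exp(drop(outer(log(lines$energy_keV),
                        seq_along(config$efficiency_coefficients) - 1,
                        `^`) %*% config$efficiency_coefficients))
  if (any(eff <= 0 | eff >= 1)) {
    stop("efficiency curve must give efficiencies in (0, 1) at all primary lines",
         call. = FALSE)
  }
  with_child_seed(config$seed, "peaks", {
    rows <- vector("list", 0)
    for (sc in unique(fish$sample_code)) {
      mass <- stats::runif(1, config$sample_mass_range_kg[1],
                           config$sample_mass_range_kg[2])
      sub <- fish[fish$sample_code == sc, ]
      for (j in seq_len(nrow(lines))) {
        a <- sub$activity_Bq_per_kg[sub$nuclide == lines$parent_chain[j]]
        expected <- a * config$live_time_s * eff[j] * lines$intensity[j] *
          lines$branching_factor[j] * mass
        bkg <- config$background_counts
        gross <- stats::rpois(1, expected + bkg)
        net <- max(gross - bkg, 0)
        rows[[length(rows) + 1]] <- data.frame(
          sample_code = sc,
          progeny_nuclide = lines$progeny_nuclide[j],
          energy_keV = lines$energy_keV[j],
          net_counts = net,
          net_counts_unc = sqrt(gross + bkg),
          background_counts = bkg,
          live_time_s = config$live_time_s,
          sample_mass_kg = mass,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "true_activities") <- fish
    out
  })
}

#' Generate a synthetic metal concentration table
#'
#' Lognormal concentrations around the profile means; each record is
#' independently censored (non-detect, `NA`) with probability
#' 1 - detect_probability. Deterministic for a fixed seed.
#'
#' @param config a `scenario_config`.
#' @return data.frame in the metal-table schema.
#' @export
generate_metal_dataset <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  with_child_seed(config$seed, "metals", {
    loc <- config$locations
    prof <- config$metal_profile
    rows <- vector("list", 0)
    for (i in seq_len(nrow(loc))) {
      for (r in seq_len(config$metal_replicates[i])) {
        code <- sprintf("Fi_%s-%d", loc$code[i], r)
        for (j in seq_len(nrow(prof))) {
          detected <- stats::runif(1) < prof$detect_probability[j]
          conc <- if (detected) {
            rlnorm_mean_cv(1, prof$mean_mg_per_kg[j], prof$rel_sd[j])
          } else NA_real_
          rows[[length(rows) + 1]] <- data.frame(
            sample_code = code, location = loc$name[i],
            element = prof$element[j],
            concentration_mg_per_kg = conc,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}
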