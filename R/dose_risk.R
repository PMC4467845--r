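# Daily radionuclide intake, committed annual effective dose and lifetime
# cancer risk from activity concentrations in fish, with location and
# overall aggregation.

#' Daily intake of radioactivity from fish consumption
#'
#' D_int = A_s x A_if / 365, where A_if is the per-capita annual fish
#' consumption (kg/y), itself the annual production x kg per short ton x
#' consumed fraction / population (see [derive_per_capita_intake()]).
#'
#' @param activity activity concentration A_s (Bq/kg dry weight).
#' @param params `exposure_params` list.
#' @return daily intake (Bq/day).
#' @export
daily_intake <- function(activity, params = default_exposure_params()) {
  if (any(activity < 0)) stop("activity must be >= 0", call. = FALSE)
  activity * params$per_capita_intake_kg_per_y / params$days_per_year
}

#' Committed annual effective dose from one radionuclide
#'
#' D_eff = A_s x A_if x D_cf, converted to microsievert per year.
#'
#' @param activity activity concentration (Bq/kg dry weight).
#' @param params `exposure_params` list.
#' @param dcf ingestion dose conversion factor (Sv/Bq) for the chain;
#'   either a single value or a named vector plus `chain`.
#' @param chain parent chain name used to index `dcf` when it is named.
#' @return committed effective dose (microSv/y).
#' @export
annual_effective_dose <- function(activity, params = default_exposure_params(),
                                  dcf = default_dose_coefficients(),
                                  chain = NULL) {
  if (any(activity < 0)) stop("activity must be >= 0", call. = FALSE)
  if (!is.null(chain)) {
    if (!chain %in% names(dcf)) {
      stop("no dose coefficient for chain ", chain, call. = FALSE)
    }
    dcf <- dcf[[chain]]
  }
  if (length(dcf) != 1) {
    stop("supply a single dose coefficient or a 'chain' to select one",
         call. = FALSE)
  }
  activity * params$per_capita_intake_kg_per_y * dcf * 1e6
}

#' Total committed effective dose across radionuclides
#'
#' Sum of the per-chain committed doses. The consumed fraction is already
#' embedded in the per-capita intake and is not applied again.
#'
#' @param per_chain_doses named numeric vector of per-chain doses
#'   (microSv/y).
#' @return total committed effective dose (microSv/y).
#' @export
total_effective_dose <- function(per_chain_doses) {
  if (length(per_chain_doses) == 0) {
    stop("no per-chain doses to sum", call. = FALSE)
  }
  sum(per_chain_doses)
}

#' Lifetime cancer risk from ingested radioactivity
#'
#' LCR = annual intake (Bq/y) x lifespan (y) x mortality risk coefficient
#' (per Bq), with the annual intake taken as the daily intake x 365.
#'
#' @param daily_intake_Bq daily intake (Bq/day).
#' @param params `exposure_params` list.
#' @param rc mortality risk coefficient (per Bq); single value or named
#'   vector plus `chain`.
#' @param chain parent chain name used to index `rc` when it is named.
#' @return dimensionless lifetime mortality risk.
#' @export
lifetime_cancer_risk <- function(daily_intake_Bq,
                                 params = default_exposure_params(),
                                 rc = default_risk_coefficients(),
                                 chain = NULL) {
  if (any(daily_intake_Bq < 0)) stop("daily intake must be >= 0", call. = FALSE)
  if (!is.null(chain)) {
    if (!chain %in% names(rc)) {
      stop("no risk coefficient for chain ", chain, call. = FALSE)
    }
    rc <- rc[[chain]]
  }
  if (length(rc) != 1) {
    stop("supply a single risk coefficient or a 'chain' to select one",
         call. = FALSE)
  }
  daily_intake_Bq * params$days_per_year * params$lifespan_y * rc
}

#' Per-sample intake, dose and risk table
#'
#' Applies the full ingestion chain to every fish sample of a long-format
#' activity table: per-chain daily intake, per-chain committed effective
#' dose, total dose, and per-chain lifetime cancer risk. Water samples are
#' carried in the input but excluded from dose and risk computation.
#'
#' @param activities data.frame in the activity-table schema
#'   (`sample_code`, `location`, `matrix`, `nuclide`,
#'   `activity_Bq_per_kg`, `uncertainty_Bq_per_kg`).
#' @param bundle reference bundle from [load_reference_tables()].
#' @return data.frame with one row per fish sample: `sample_code`,
#'   `location`, then `daily_intake_<chain>_Bq_per_day`,
#'   `dose_<chain>_uSv_per_y`, `total_dose_uSv_per_y`, `lcr_<chain>`.
#' @export
dose_risk_table <- function(activities, bundle = load_reference_tables()) {
  fish <- activities[activities$matrix == "fish" &
                       !is.na(activities$activity_Bq_per_kg), , drop = FALSE]
  if (nrow(fish) == 0) stop("no fish activity rows in input", call. = FALSE)
  chains <- intersect(PARENT_CHAINS, unique(fish$nuclide))
  unknown <- setdiff(unique(fish$nuclide), PARENT_CHAINS)
  if (length(unknown)) {
    stop("unknown nuclide label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- bundle$exposure
  codes <- unique(fish$sample_code)
  rows <- lapply(codes, function(sc) {
    sub <- fish[fish$sample_code == sc, ]
    row <- data.frame(sample_code = sc, location = sub$location[1],
                      stringsAsFactors = FALSE)
    doses <- numeric(0)
    for (ch in chains) {
      a <- sub$activity_Bq_per_kg[sub$nuclide == ch]
      if (length(a) != 1) {
        stop("sample ", sc, " must have exactly one ", ch, " activity",
             call. = FALSE)
      }
      din <- daily_intake(a, params)
      dose <- annual_effective_dose(a, params, bundle$dose_coefficients,
                                    chain = ch)
      lcr <- lifetime_cancer_risk(din, params, bundle$risk_coefficients,
                                  chain = ch)
      doses[ch] <- dose
      row[[paste0("daily_intake_", chain_tag(ch), "_Bq_per_day")]] <- din
      row[[paste0("dose_", chain_tag(ch), "_uSv_per_y")]] <- dose
      row[[paste0("lcr_", chain_tag(ch))]] <- lcr
    }
    row$total_dose_uSv_per_y <- total_effective_dose(doses)
    row
  })
  out <- do.call(rbind, rows)
  # stable column order: intakes, doses, total, risks
  first <- c("sample_code", "location")
  din_cols <- grep("^daily_intake_", names(out), value = TRUE)
  dose_cols <- grep("^dose_", names(out), value = TRUE)
  lcr_cols <- grep("^lcr_", names(out), value = TRUE)
  out[, c(first, din_cols, dose_cols, "total_dose_uSv_per_y", lcr_cols)]
}

chain_tag <- function(chain) gsub("-", "", chain)

#' Column means by location and overall
#'
#' Reproduces the "Mean" and "Over all mean" rows of the survey tables:
#' arithmetic means of every numeric column per group, and across all
#' rows. Uncertainty columns, when present, are averaged the same way.
#'
#' @param rows data.frame with a grouping column and numeric columns.
#' @param group_key name of the grouping column (default `"location"`),
#'   or `"all"` for the overall mean only.
#' @return data.frame of group means; the overall mean row has group label
#'   `"overall"`.
#' @export
aggregate_rows <- function(rows, group_key = "location") {
  num <- vapply(rows, is.numeric, logical(1))
  if (!any(num)) stop("no numeric columns to aggregate", call. = FALSE)
  if (nrow(rows) == 0) stop("empty input", call. = FALSE)
  overall <- data.frame(group = "overall",
                        t(colMeans(rows[, num, drop = FALSE])),
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (identical(group_key, "all")) {
    names(overall)[1] <- "group"
    return(overall)
  }
  if (!group_key %in% names(rows)) {
    stop("grouping column '", group_key, "' not found", call. = FALSE)
  }
  groups <- unique(rows[[group_key]])
  per <- lapply(groups, function(g) {
    sub <- rows[rows[[group_key]] == g, num, drop = FALSE]
    data.frame(group = g, t(colMeans(sub)), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- rbind(do.call(rbind, per), overall)
  names(out)[1] <- group_key
  out
}

#' Location-mean activity concentrations
#'
#' @param activities long-format activity table.
#' @param matrix_type `"fish"` or `"water"`.
#' @return data.frame of per-location and overall mean activity and mean
#'   uncertainty per nuclide.
#' @export
activity_location_means <- function(activities, matrix_type = "fish") {
  sub <- activities[activities$matrix == matrix_type &
                      !is.na(activities$activity_Bq_per_kg), , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for matrix ", matrix_type, call. = FALSE)
  out <- vector("list", 0)
  for (nuc in unique(sub$nuclide)) {
    s2 <- sub[sub$nuclide == nuc, ]
    m <- aggregate_rows(
      s2[, c("location", "activity_Bq_per_kg", "uncertainty_Bq_per_kg")],
      "location"
    )
    m$nuclide <- nuc
    out[[length(out) + 1]] <- m
  }
  res <- do.call(rbind, out)
  res[, c("location", "nuclide", "activity_Bq_per_kg",
          "uncertainty_Bq_per_kg")]
}
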