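# Printed reference values from the case-study survey report, plus the
# comparator used for printed-table reproduction: a computed value matches
# a printed one when half-up rounding to the printed precision recovers it,
# or (fallback, for the few cells the report itself rounded inconsistently)
# when it agrees within 0.5% relative.

expect_matches_printed <- function(actual, printed, digits = NULL,
                                   sig = NULL, rel_tol = 0.005) {
  act <- quasi_label(rlang::enquo(actual))
  rounded <- if (!is.null(sig)) signif_half_up(actual, sig) else
    round_half_up(actual, digits)
  ok <- (abs(rounded - printed) <= 1e-6 * abs(printed)) |
    (abs(actual - printed) <= rel_tol * abs(printed))
  expect(
    all(ok),
    sprintf("%s (= %s) does not reproduce printed value(s) %s",
            act$lab, paste(signif(actual[!ok], 6), collapse = ", "),
            paste(printed[!ok], collapse = ", "))
  )
  invisible(actual)
}

# intake/dose/risk table as printed: 9 samples + 3 location means
printed_dose_risk <- function() {
  df <- read.csv(text = "
sample_code,din_Ra226,din_Th232,din_K40,dose_Ra226,dose_Th232,dose_K40,total,lcr_Ra226,lcr_Th232,lcr_K40
Fi_Bl-1,1.01,0.79,50.33,103.4,66.07,113.9,283.4,2.5e-4,4.9e-5,7.6e-4
Fi_Bl-2,1.06,0.81,48.58,108.3,68.14,109.9,286.4,2.6e-4,5.1e-5,7.3e-4
Fi_Bl-3,0.98,0.82,41.04,100.1,68.79,92.87,261.7,2.4e-4,5.1e-5,6.2e-4
Fi_Kl-1,0.82,0.49,48.25,83.88,40.88,109.2,234.0,2.0e-4,3.0e-5,7.3e-4
Fi_Kl-2,0.87,0.49,57.45,89.19,41.32,130.0,260.5,2.1e-4,3.1e-5,8.6e-4
Fi_Kl-3,0.83,0.46,49.69,84.94,39.03,112.5,236.4,2.0e-4,2.9e-5,7.5e-4
Fi_Re-1,0.57,0.21,34.89,58.00,17.66,78.96,154.6,1.4e-4,1.3e-5,5.3e-4
Fi_Re-2,0.49,0.25,38.84,50.04,20.93,87.90,158.9,1.2e-4,1.6e-5,5.8e-4
Fi_Re-3,0.52,0.29,38.52,53.35,24.53,87.16,165.0,1.3e-4,1.8e-5,5.8e-4
", stringsAsFactors = FALSE)
  df
}

printed_dose_risk_means <- function() {
  read.csv(text = "
location,din_Ra226,din_Th232,din_K40,dose_Ra226,dose_Th232,dose_K40,total,lcr_Ra226,lcr_Th232,lcr_K40
Bagan Lalang,1.02,0.81,46.65,103.9,67.67,105.6,277.2,2.5e-4,5.0e-5,7.0e-4
Port Klang,0.84,0.48,51.80,86.00,40.41,117.2,243.6,2.1e-4,3.0e-5,7.8e-4
Pantai Remis,0.53,0.25,37.42,53.80,21.04,84.67,159.5,1.3e-4,1.6e-5,5.6e-4
", stringsAsFactors = FALSE)
}

# EDI table as printed (micrograms per kg body weight per day)
printed_edi <- function() {
  read.csv(text = "
location,element,edi
Port Klang,Al,6.8671
Port Klang,Cr,0.0671
Port Klang,Mn,1.5735
Port Klang,Co,0.0050
Port Klang,Cu,0.1322
Port Klang,As,1.3900
Port Klang,Hg,0.0458
Pantai Remis,Al,9.0059
Pantai Remis,Cr,0.0958
Pantai Remis,Mn,3.4184
Pantai Remis,Co,0.0051
Pantai Remis,Cu,0.1322
Pantai Remis,As,0.9896
Bagan Lalang,Al,5.785
Bagan Lalang,Cr,0.0201
Bagan Lalang,Mn,0.8119
Bagan Lalang,Co,0.0013
Bagan Lalang,Cu,0.3672
Bagan Lalang,As,0.6035
Bagan Lalang,Pb,0.0371
", stringsAsFactors = FALSE)
}

# printed precision of effective-dose cells: 1 decimal at >= 100, else 2
dose_digits <- function(printed) ifelse(abs(printed) >= 100, 1, 2)

# split a long activity table into location-keyed value lists per nuclide
activity_groups <- function(activities, nuclide, matrix_type = "fish") {
  sub <- activities[activities$matrix == matrix_type &
                      activities$nuclide == nuclide, ]
  split(sub$activity_Bq_per_kg, sub$location)
}
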