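params <- default_exposure_params()
dcf <- default_dose_coefficients()
rc <- default_risk_coefficients()

test_that("daily intake reproduces the printed per-sample values", {
  expect_equal(round_half_up(daily_intake(7.79, params), 2), 1.01)
  expect_equal(round_half_up(daily_intake(4.37, params), 2), 0.57)
  expect_equal(daily_intake(0, params), 0)
  expect_error(daily_intake(-1, params), ">= 0")
})

test_that("annual effective dose reproduces the printed values", {
  expect_equal(round_half_up(
    annual_effective_dose(7.79, params, dcf, chain = "Ra-226"), 1), 103.4)
  expect_equal(round_half_up(
    annual_effective_dose(387.6, params, dcf, chain = "K-40"), 1), 113.9)
  expect_equal(annual_effective_dose(0, params, dcf, chain = "Th-232"), 0)
  expect_error(annual_effective_dose(1, params, dcf, chain = "Cs-137"),
               "Cs-137")
})

test_that("total dose is the plain sum of per-chain doses", {
  d2 <- vapply(PARENT_CHAINS, function(ch)
    annual_effective_dose(c("Ra-226" = 8.16, "Th-232" = 6.25,
                            "K-40" = 374.1)[[ch]], params, dcf, chain = ch),
    numeric(1))
  expect_equal(round_half_up(total_effective_dose(d2), 1), 286.4)

  d1 <- vapply(PARENT_CHAINS, function(ch)
    annual_effective_dose(c("Ra-226" = 7.79, "Th-232" = 6.06,
                            "K-40" = 387.6)[[ch]], params, dcf, chain = ch),
    numeric(1))
  expect_equal(round_half_up(total_effective_dose(d1), 1), 283.4)

  expect_equal(total_effective_dose(42.5), 42.5)
  expect_error(total_effective_dose(numeric(0)), "no per-chain")
})

test_that("lifetime cancer risk reproduces the printed values", {
  din_ra <- daily_intake(7.79, params)
  expect_equal(signif_half_up(
    lifetime_cancer_risk(din_ra, params, rc, chain = "Ra-226"), 2), 2.5e-4)
  din_th <- daily_intake(6.06, params)
  expect_equal(signif_half_up(
    lifetime_cancer_risk(din_th, params, rc, chain = "Th-232"), 2), 4.9e-5)
  expect_equal(lifetime_cancer_risk(0, params, rc, chain = "K-40"), 0)
  expect_error(lifetime_cancer_risk(1, params, rc, chain = "U-238"), "U-238")
})

test_that("the intake-dose-risk chain obeys its algebraic identities", {
  set.seed(13)
  for (i in 1:25) {
    a <- runif(1, 0, 500)
    b <- runif(1, 0, 500)
    ch <- sample(PARENT_CHAINS, 1)
    # linearity in activity
    expect_equal(daily_intake(a + b, params),
                 daily_intake(a, params) + daily_intake(b, params))
    expect_equal(annual_effective_dose(a + b, params, dcf, chain = ch),
                 annual_effective_dose(a, params, dcf, chain = ch) +
                   annual_effective_dose(b, params, dcf, chain = ch))
    # LCR(A) = D_int(A) x 365 x 70 x R_c, exactly
    expect_equal(lifetime_cancer_risk(daily_intake(a, params), params, rc,
                                      chain = ch),
                 daily_intake(a, params) * 365 * 70 * rc[[ch]])
    # dose / intake is a per-chain constant: 365 x D_cf x 1e6
    if (a > 0) {
      expect_equal(annual_effective_dose(a, params, dcf, chain = ch) /
                     daily_intake(a, params),
                   365 * dcf[[ch]] * 1e6, tolerance = 1e-9)
    }
  }
})

test_that("location aggregation reproduces the printed activity means", {
  act <- malacca_activity()
  means <- activity_location_means(act, "fish")
  ra <- means[means$nuclide == "Ra-226", ]
  expect_equal(round_half_up(
    ra$activity_Bq_per_kg[ra$location == "Bagan Lalang"], 2), 7.83)
  th <- means[means$nuclide == "Th-232", ]
  expect_equal(round_half_up(
    th$activity_Bq_per_kg[th$location == "Pantai Remis"], 2), 1.93)
  # identical replicates aggregate to themselves
  df <- data.frame(location = "X", v = c(4.2, 4.2, 4.2))
  expect_equal(aggregate_rows(df, "location")$v, c(4.2, 4.2))
  expect_error(aggregate_rows(df[0, ], "location"), "empty")
})

test_that("the full dose/risk table reproduces every printed cell", {
  b <- load_reference_tables()
  dr <- dose_risk_table(malacca_activity(), b)
  exp_rows <- printed_dose_risk()
  dr <- dr[match(exp_rows$sample_code, dr$sample_code), ]

  for (ch in c("Ra226", "Th232", "K40")) {
    expect_matches_printed(dr[[paste0("daily_intake_", ch, "_Bq_per_day")]],
                           exp_rows[[paste0("din_", ch)]], digits = 2)
    d_print <- exp_rows[[paste0("dose_", ch)]]
    d_act <- dr[[paste0("dose_", ch, "_uSv_per_y")]]
    for (i in seq_along(d_print)) {
      expect_matches_printed(d_act[i], d_print[i],
                             digits = dose_digits(d_print[i]))
    }
    expect_matches_printed(dr[[paste0("lcr_", ch)]],
                           exp_rows[[paste0("lcr_", ch)]], sig = 2)
  }
  expect_matches_printed(dr$total_dose_uSv_per_y, exp_rows$total, digits = 1)
  # total is the sum of the per-chain doses
  expect_equal(dr$total_dose_uSv_per_y,
               dr$dose_Ra226_uSv_per_y + dr$dose_Th232_uSv_per_y +
                 dr$dose_K40_uSv_per_y, tolerance = 1e-9)
})

test_that("location means of the dose/risk table reproduce the printed means", {
  b <- load_reference_tables()
  dr <- dose_risk_table(malacca_activity(), b)
  m <- aggregate_rows(dr, "location")
  exp_m <- printed_dose_risk_means()
  m <- m[match(exp_m$location, m$location), ]
  for (ch in c("Ra226", "Th232", "K40")) {
    expect_matches_printed(m[[paste0("daily_intake_", ch, "_Bq_per_day")]],
                           exp_m[[paste0("din_", ch)]], digits = 2)
    d_print <- exp_m[[paste0("dose_", ch)]]
    d_act <- m[[paste0("dose_", ch, "_uSv_per_y")]]
    for (i in seq_along(d_print)) {
      expect_matches_printed(d_act[i], d_print[i],
                             digits = dose_digits(d_print[i]))
    }
    expect_matches_printed(m[[paste0("lcr_", ch)]],
                           exp_m[[paste0("lcr_", ch)]], sig = 2)
  }
  expect_matches_printed(m$total_dose_uSv_per_y, exp_m$total, digits = 1)
})

test_that("water samples are carried but excluded from dose computation", {
  act <- malacca_activity()
  dr <- dose_risk_table(act, load_reference_tables())
  expect_equal(nrow(dr), 9)
  expect_false(any(grepl("^Wa_", dr$sample_code)))
})
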