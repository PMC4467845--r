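make_powerlaw_points <- function(coefs, energies) {
  X <- outer(log(energies), seq_along(coefs) - 1, `^`)
  data.frame(energy_keV = energies, efficiency = exp(drop(X %*% coefs)))
}

test_that("efficiency fit recovers an exact log-log polynomial", {
  coefs <- c(2.0, -1.1, 0.05)  # order 2 in log-log space
  pts <- make_powerlaw_points(coefs, c(120, 300, 600, 900, 1460))
  curve <- fit_efficiency(pts, order = 2)
  expect_equal(curve$coefficients, coefs, tolerance = 1e-9)
  expect_lt(curve$fit_residual, 1e-9)
  expect_equal(efficiency_at(curve, 450), exp(sum(coefs * log(450)^(0:2))),
               tolerance = 1e-9)
})

test_that("order-0 fit on constant efficiencies is the constant", {
  pts <- data.frame(energy_keV = c(100, 500, 1000), efficiency = 0.05)
  curve <- fit_efficiency(pts, order = 0)
  expect_equal(efficiency_at(curve, c(150, 800)), c(0.05, 0.05))
})

test_that("noisy fit agrees with an independent normal-equations solve", {
  set.seed(11)
  energies <- c(122, 245, 412, 662, 1001, 1408)
  coefs <- c(1.5, -0.9)
  pts <- make_powerlaw_points(coefs, energies)
  pts$efficiency <- pts$efficiency * exp(rnorm(6, 0, 0.02))
  curve <- fit_efficiency(pts, order = 2)
  # brute-force oracle: solve the normal equations directly
  X <- outer(log(pts$energy_keV), 0:2, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% log(pts$efficiency))
  expect_equal(curve$coefficients, drop(beta), tolerance = 1e-9)
})

test_that("efficiency fit rejects bad input and flags extrapolation", {
  pts <- data.frame(energy_keV = c(100, 500), efficiency = c(0.05, 0.02))
  expect_error(fit_efficiency(pts, order = 2), "order \\+ 1")
  expect_error(fit_efficiency(data.frame(energy_keV = c(1, 2, 3),
                                         efficiency = c(0.1, -0.1, 0.2)),
                              order = 1), "\\(0, 1\\)")
  curve <- fit_efficiency(pts, order = 1)
  expect_error(efficiency_at(curve, 1400), "extrapolat")
  expect_warning(efficiency_at(curve, 1400, allow_extrapolation = TRUE),
                 "extrapolat")
})

test_that("line activity follows A = N / (t e Pg b m)", {
  # empty peak
  expect_equal(line_activity(0, 86400, 0.05, 0.356, 0.2)$value, 0)
  # hand-evaluated reference case
  a <- line_activity(8640, 86400, 0.05, 0.356, 0.2)
  expect_equal(a$value, 28.09, tolerance = 5e-4)
  # inverse-linear in mass, linear in counts
  a2 <- line_activity(8640, 86400, 0.05, 0.356, 0.4)
  expect_equal(a2$value, a$value / 2)
  a3 <- line_activity(2 * 8640, 86400, 0.05, 0.356, 0.2,
                      net_counts_unc = sqrt(2 * 8640))
  expect_equal(a3$value, 2 * a$value)
  # inverse-linear in each remaining denominator factor
  expect_equal(line_activity(8640, 2 * 86400, 0.05, 0.356, 0.2)$value,
               a$value / 2)
  expect_equal(line_activity(8640, 86400, 0.10, 0.356, 0.2)$value,
               a$value / 2)
  expect_equal(line_activity(8640, 86400, 0.05, 0.712, 0.2)$value,
               a$value / 2)
  expect_equal(line_activity(8640, 86400, 0.05, 0.356, 0.2,
                             branching_factor = 0.5)$value, 2 * a$value)
  expect_error(line_activity(8640, 0, 0.05, 0.356, 0.2), "live_time")
  expect_error(line_activity(8640, 86400, 0.05, 0.356, 0), "mass")
})

test_that("Currie MDA matches hand evaluation and is monotone in background", {
  expect_equal(minimum_detectable_activity(0, 0.05, 1, 86400, 0.2),
               2.71 / 864, tolerance = 1e-12)
  expect_equal(minimum_detectable_activity(10000, 0.05, 1, 86400, 0.2),
               (2.71 + 465) / 864, tolerance = 1e-12)
  b_grid <- seq(0, 5000, by = 250)
  mda <- vapply(b_grid, minimum_detectable_activity, numeric(1),
                efficiency = 0.05, intensity = 1, live_time_s = 86400,
                sample_mass_kg = 0.2)
  expect_true(all(diff(mda) >= 0))
  expect_error(minimum_detectable_activity(10, 0, 1, 86400, 0.2), "efficiency")
})

test_that("quadrature combination reproduces the published budget range", {
  # worst case: 10% counting + 4% efficiency + 1.5% mass + 1% intensity
  expect_equal(round_half_up(propagate_uncertainty(c(10, 4, 1.5, 1)), 1), 10.9)
  # best case: 0.5% counting statistics
  expect_equal(round_half_up(propagate_uncertainty(c(0.5, 4, 1.5, 1)), 1), 4.4)
  expect_equal(propagate_uncertainty(0.073), 0.073)
  expect_equal(propagate_uncertainty(numeric(0)), 0)
  expect_error(propagate_uncertainty(c(0.1, -0.2)), ">= 0")
})

test_that("quadrature lies between max component and the arithmetic sum", {
  set.seed(3)
  for (i in 1:50) {
    comps <- runif(sample(1:6, 1), 0, 0.2)
    q <- propagate_uncertainty(comps)
    expect_gte(q, max(comps))
    expect_lte(q, sum(comps) + 1e-12)
  }
})

test_that("line combination is an inverse-variance weighted mean", {
  one <- combine_lines(7.79, 0.46)
  expect_equal(one$value, 7.79)
  expect_equal(one$uncertainty, 0.46)

  two <- combine_lines(c(10, 12), c(1, 2))
  expect_equal(two$value, 10.4)
  expect_equal(two$uncertainty, 0.894, tolerance = 5e-4)

  same <- combine_lines(c(5.5, 5.5), c(0.2, 1.7))
  expect_equal(same$value, 5.5)

  expect_error(combine_lines(numeric(0)), "no line")
  expect_error(combine_lines(c(1, 2), c(0.1)), "equal length")
  expect_error(combine_lines(c(1, 2), c(0.1, 0)), "positive")
})

test_that("combined value is bounded by inputs, uncertainty by the smallest", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    v <- runif(n, 1, 400)
    u <- runif(n, 0.01, 30)
    cmb <- combine_lines(v, u)
    expect_gte(cmb$value, min(v))
    expect_lte(cmb$value, max(v))
    expect_lte(cmb$uncertainty, min(u))
  }
})

test_that("a peak table quantifies to chain activities with MDA screening", {
  cfg <- scenario_config(replicate_dispersion = 0, seed = 77)
  bundle <- load_reference_tables()
  peaks <- generate_peak_table(cfg, bundle)
  pts <- make_powerlaw_points(cfg$efficiency_coefficients,
                              c(150, 238.6, 352, 609, 911, 1461))
  curve <- fit_efficiency(pts, order = 1)
  acts <- peaks_to_activities(peaks, curve, bundle)
  expect_equal(nrow(acts), 9 * 3)  # 9 fish x 3 chains
  expect_true(all(acts$activity_Bq_per_kg >= 0))
  expect_equal(acts$n_lines[acts$nuclide == "Th-232"], rep(3, 9))
  expect_false(any(acts$below_mda))  # activities well above detection
  truth <- attr(peaks, "true_activities")
  for (i in seq_len(nrow(acts))) {
    tr <- truth$activity_Bq_per_kg[
      truth$sample_code == acts$sample_code[i] &
        truth$nuclide == acts$nuclide[i]]
    expect_lt(abs(acts$activity_Bq_per_kg[i] - tr),
              4 * acts$uncertainty_Bq_per_kg[i])
  }
})
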