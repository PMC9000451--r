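test_that("blank-corrected inhibition rate matches hand evaluation", {
  expect_equal(inhibition_rate(A = 0.10, a = 0.90, B = 0.10, b = 0.90), 0)
  expect_equal(inhibition_rate(A = 0.10, a = 0.90, B = 0.12, b = 0.12), 100)
  # (1 - 0.40/0.80) * 100
  expect_equal(inhibition_rate(A = 0.10, a = 0.90, B = 0.12, b = 0.52), 50)
  expect_error(inhibition_rate(A = 0.9, a = 0.9, B = 0.1, b = 0.1),
               "degenerate control")
})

test_that("rate is decreasing in b and invariant to a common offset", {
  b <- seq(0.12, 0.9, by = 0.02)
  r <- inhibition_rate(0.10, 0.90, 0.12, b)
  expect_true(all(diff(r) < 0))
  r0 <- inhibition_rate(0.10, 0.90, 0.12, 0.40)
  r_shift <- inhibition_rate(0.10 + 0.3, 0.90 + 0.3, 0.12 + 0.3,
                             0.40 + 0.3)
  expect_equal(r_shift, r0)
})

test_that("aggregation averages replicates and clamps raw excursions", {
  dr <- aggregate_dose_response(plate_from_rates(1.0, c(50, 50, 50)))
  expect_equal(dr$mean_inhibition_pct, 50)
  expect_equal(dr$sd_pct, 0)

  dr2 <- aggregate_dose_response(plate_from_rates(1.0, c(40, 50, 60)))
  expect_equal(dr2$mean_inhibition_pct, 50)
  expect_equal(dr2$sd_pct, 10)
  expect_equal(dr2$n_rep, 3L)

  # a raw -3% replicate is clamped to 0 before averaging
  dr3 <- aggregate_dose_response(plate_from_rates(1.0, c(-3, 10, 20)))
  expect_equal(dr3$mean_inhibition_pct, 10)
})

test_that("probit fit recovers the designed IC50 from noiseless data", {
  for (ic50_true in c(1.80, 3.03)) {
    tr <- default_truth(IC50 = ic50_true)
    dr <- aggregate_dose_response(
      generate_plate_assay(noiseless_design(), tr))
    fit <- fit_ic50(dr)
    expect_lt(rel_err(fit$ic50, ic50_true), 1e-6)
    expect_equal(fit$slope, tr$probit_slope, tolerance = 1e-9)
    expect_true(fit$ci95[1] < fit$ic50 && fit$ic50 < fit$ci95[2] ||
                  all(abs(fit$ci95 - fit$ic50) < 1e-6))
  }
})

test_that("two symmetric doses put IC50 at the log-space midpoint", {
  dr <- data.frame(conc_mg_ml = c(1, 4),
                   mean_inhibition_pct = c(25, 75),
                   sd_pct = c(NA, NA), n_rep = c(1L, 1L))
  expect_warning(fit <- fit_ic50(dr), "fewer than 3")
  expect_equal(fit$ic50, 2.0, tolerance = 1e-9)
})

test_that("fitted IC50 scales with the concentration axis", {
  tr <- default_truth()
  dr <- aggregate_dose_response(generate_plate_assay(noiseless_design(),
                                                     tr))
  f1 <- fit_ic50(dr)
  dr_scaled <- dr
  dr_scaled$conc_mg_ml <- dr$conc_mg_ml * 7
  f7 <- fit_ic50(dr_scaled)
  expect_equal(f7$ic50, 7 * f1$ic50, tolerance = 1e-9)
})

test_that("degenerate dose-response inputs are refused or flagged", {
  dr1 <- data.frame(conc_mg_ml = c(0, 1), mean_inhibition_pct = c(0, 40),
                    sd_pct = NA, n_rep = 1L)
  expect_error(fit_ic50(dr1), "insufficient data")

  # every dose below 50%: extrapolation is flagged
  dr2 <- data.frame(conc_mg_ml = c(0.2, 0.4, 0.8),
                    mean_inhibition_pct = c(5, 10, 20),
                    sd_pct = NA, n_rep = 1L)
  expect_warning(fit <- fit_ic50(dr2), "one side of 50")
  expect_true(fit$extrapolated)
})
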