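test_that("design and truth validators reject unphysical inputs", {
  expect_error(assay_design(substrate_concs = c(0.4, 0.2)),
               "strictly increasing")
  expect_error(assay_design(substrate_concs = c(0, 0.4)),
               "strictly positive")
  expect_error(assay_design(replicates = 0), "positive integer")
  expect_error(assay_design(noise_sd = -0.1), ">= 0")
  expect_error(ground_truth(Km = -1), "strictly positive")
  expect_error(ground_truth(Ksv_by_T = c(1e4, 2e4)), "named")
})

test_that("competitive rate law evaluates as in the closed form", {
  # v = 5.46 * 0.25 / (0.25 * (1 + 0.88/0.88) + 0.25) = 1.82
  expect_equal(competitive_velocity(S = 0.25, I = 0.88, Km = 0.25,
                                    Vmax = 5.46, Ki = 0.88), 1.82)
  # no inhibitor: plain Michaelis-Menten
  expect_equal(competitive_velocity(1, 0, 0.25, 5.46, 0.88),
               5.46 * 1 / 1.25)
})

test_that("noiseless plate wells reproduce the designed inhibition", {
  d <- noiseless_design(inhibitor_concs = c(0, 0.4, 1.0, 1.8, 4.0))
  tr <- default_truth()  # IC50 = 1.8
  dr <- aggregate_dose_response(generate_plate_assay(d, tr))
  expect_equal(dr$mean_inhibition_pct[dr$conc_mg_ml == 0], 0)
  expect_equal(dr$mean_inhibition_pct[dr$conc_mg_ml == 1.8], 50)
  designed <- 100 * inhibition_fraction(tr, dr$conc_mg_ml)
  expect_equal(dr$mean_inhibition_pct, designed, tolerance = 1e-12)
  expect_equal(dr$sd_pct[dr$conc_mg_ml > 0], rep(0, 4))
})

test_that("generation is deterministic in (design, truth, seed)", {
  tr <- default_truth()
  a1 <- generate_plate_assay(noisy_design(seed = 11), tr)
  a2 <- generate_plate_assay(noisy_design(seed = 11), tr)
  a3 <- generate_plate_assay(noisy_design(seed = 12), tr)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))

  t1 <- generate_titration(noisy_design(seed = 11), tr, 293)
  t2 <- generate_titration(noisy_design(seed = 11), tr, 293)
  expect_identical(t1, t2)
})

test_that("noiseless titration obeys Stern-Volmer to machine precision", {
  d <- noiseless_design()
  tr <- default_truth()
  ser <- generate_titration(d, tr, temperature = 293)
  pk <- peak_reduce(ser)
  F0 <- attr(pk, "F0")
  expect_equal(F0 / pk$F, 1 + tr$Ksv_by_T[["293"]] * pk$Q_mol_per_l,
               tolerance = 1e-12)
  # ratio 20 at 5e-6 mol/L enzyme gives [Q] = 1e-4; with Ksv = 6.03e4,
  # F0/F = 1 + 6.03 = 7.03
  expect_equal(F0 / pk$F[pk$Q_mol_per_l == 1e-4], 7.03,
               tolerance = 1e-12)
  # red shift: 0.1 nm per unit ratio, max ratio 20 -> +2 nm
  expect_equal(attr(pk, "peak_shift_nm"), 2)
})

test_that("titration generation requires the zero-ratio reference", {
  d <- noiseless_design(molar_ratios = c(1, 2, 4))
  expect_error(generate_titration(d, default_truth(), 293),
               "F0")
})

test_that("estimator spread shrinks as replicates increase", {
  tr <- default_truth()
  est <- function(reps) {
    vapply(1:30, function(i) {
      d <- assay_design(noise_sd = 0.05, replicates = reps,
                        seed = 100L + i)
      fit_ic50(aggregate_dose_response(generate_plate_assay(d, tr)))$ic50
    }, numeric(1))
  }
  expect_lt(sd(est(12L)), sd(est(2L)))
})
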