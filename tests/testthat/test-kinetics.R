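# build a velocity series from an arbitrary rate law v(S, I)
vs_from_law <- function(S, I, vfun, enzyme = 5) {
  g <- expand.grid(substrate_conc_mg_ml = S, inhibitor_conc_mg_ml = I)
  g$enzyme_conc_mg_ml <- enzyme
  g$velocity_per_min <- vfun(g$substrate_conc_mg_ml,
                             g$inhibitor_conc_mg_ml)
  velocity_series(g)
}

test_that("type plot recovers proportional velocity-vs-enzyme lines", {
  E <- c(5, 10, 15, 20)
  k <- c(1.0, 0.5, 0.25)   # slope halves per dose
  g <- do.call(rbind, lapply(seq_along(k), function(i) {
    data.frame(substrate_conc_mg_ml = 1.0, enzyme_conc_mg_ml = E,
               inhibitor_conc_mg_ml = i - 1,
               velocity_per_min = k[i] * E)
  }))
  tp <- fit_type_plot(velocity_series(g))
  expect_equal(tp$slope, k, tolerance = 1e-12)
  expect_equal(tp$intercept, rep(0, 3), tolerance = 1e-12)
  expect_error(
    fit_type_plot(velocity_series(g[g$enzyme_conc_mg_ml < 15, ])),
    "insufficient data")
})

test_that("reversibility verdicts follow the line geometry", {
  expect_equal(classify_reversibility(
    type_plot(c(0, 1, 2), slope = c(1.0, 0.7, 0.5),
              intercept = c(0, 0, 0))), "reversible")
  expect_equal(classify_reversibility(
    type_plot(c(0, 1, 2), slope = c(1, 1, 1),
              intercept = c(0, -0.2, -0.4))), "irreversible")
  expect_equal(classify_reversibility(
    type_plot(c(0, 1, 2), slope = c(1.0, 1.2, 0.8),
              intercept = c(0, 0, 0))), "indeterminate")
  expect_error(classify_reversibility(
    type_plot(0, slope = 1, intercept = 0)), ">= 2")
})

test_that("generated reversible and irreversible patterns classify", {
  d <- noiseless_design()
  tr <- default_truth()
  tp_rev <- fit_type_plot(generate_velocity_series(d, tr, kind = "enzyme"))
  expect_equal(classify_reversibility(tp_rev), "reversible")
  tp_irr <- fit_type_plot(
    generate_velocity_series(d, tr, kind = "enzyme", reversible = FALSE))
  expect_equal(classify_reversibility(tp_irr), "irreversible")
})

test_that("Lineweaver-Burk recovers competitive kinetics exactly", {
  tr <- default_truth()  # Km 0.25, Vmax 5.46, Ki 0.88
  d <- noiseless_design(inhibitor_concs = c(0, 0.88, 1.76))
  lb <- lineweaver_burk(generate_velocity_series(d, tr))
  expect_lt(rel_err(lb$Vmax, 5.46), 1e-9)
  expect_lt(rel_err(lb$Km, 0.25), 1e-9)
  # [I] = Ki doubles the apparent Km: 0.25 * (1 + 1) = 0.50
  expect_lt(rel_err(lb$Km_app_by_I[["0.88"]], 0.50), 1e-9)
  expect_lt(rel_err(lb$Ki, 0.88), 1e-9)
  expect_equal(lb$verdict, "competitive")
  # Vmax constant across doses on noiseless competitive data
  expect_lt(diff(range(lb$Vmax_by_I)) / mean(lb$Vmax_by_I), 1e-9)
})

test_that("competitive signature holds for any Ki", {
  for (Ki in c(0.3, 0.88, 3.8)) {
    tr <- default_truth(Ki = Ki)
    d <- noiseless_design()
    lb <- lineweaver_burk(generate_velocity_series(d, tr))
    I <- as.numeric(names(lb$Km_app_by_I))
    expect_equal(unname(lb$Km_app_by_I / lb$Km - 1), I / Ki,
                 tolerance = 1e-3)
    expect_equal(lb$verdict, "competitive")
  }
})

test_that("noncompetitive and uncompetitive patterns are labelled", {
  S <- seq(0.4, 1.6, by = 0.2)
  I <- c(0, 1, 2)
  noncomp <- vs_from_law(S, I, function(S, I) {
    (5.46 / (1 + I / 1.5)) * S / (0.25 + S)
  })
  expect_equal(lineweaver_burk(noncomp)$verdict, "noncompetitive")

  uncomp <- vs_from_law(S, I, function(S, I) {
    f <- 1 + I / 1.5
    (5.46 / f) * S / (0.25 / f + S)
  })
  expect_equal(lineweaver_burk(uncomp)$verdict, "uncompetitive")

  mixed <- vs_from_law(S, I, function(S, I) {
    (5.46 / (1 + I / 2)) * S / (0.25 * (1 + I / 0.5) + S)
  })
  expect_equal(lineweaver_burk(mixed)$verdict, "mixed")
})

test_that("zero velocities are excluded with a warning", {
  S <- seq(0.4, 1.6, by = 0.2)
  vs <- vs_from_law(S, 0, function(S, I) 5.46 * S / (0.25 + S))
  vs$velocity_per_min[1] <- 0
  expect_warning(lb <- lineweaver_burk(vs), "zero-velocity")
  expect_lt(rel_err(lb$Vmax, 5.46), 1e-9)
})

test_that("reciprocal fit agrees with the nonlinear oracle when noiseless", {
  tr <- default_truth()
  vs <- generate_velocity_series(noiseless_design(), tr)
  lb <- lineweaver_burk(vs)
  mm <- michaelis_menten_fit(vs)
  expect_lt(rel_err(lb$Vmax, mm$Vmax), 1e-6)
  expect_lt(rel_err(lb$Km, mm$Km), 1e-6)
  expect_lt(max(rel_err(lb$Km_app_by_I, mm$Km_app_by_I)), 1e-6)
})
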