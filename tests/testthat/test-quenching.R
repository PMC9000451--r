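sv_points <- function(Ksv, Q, F0 = 1000) {
  data.frame(Q_mol_per_l = Q, F = F0 / (1 + Ksv * Q))
}

test_that("peak reduction extracts maxima, ties to the red side", {
  d <- noiseless_design()
  tr <- default_truth(red_shift_per_ratio = 1e-9)  # effectively no shift
  pk <- peak_reduce(generate_titration(d, tr, 293))
  expect_equal(attr(pk, "peak_shift_nm"), 0)
  expect_equal(pk$peak_lambda_nm, rep(340, nrow(pk)))

  # uniform intensity scaling leaves the reduction's shape invariant
  ser <- generate_titration(d, default_truth(), 293)
  ser2 <- ser
  ser2$spectra$intensity <- ser$spectra$intensity * 37
  pk1 <- peak_reduce(ser)
  pk2 <- peak_reduce(ser2)
  expect_equal(pk2$F, 37 * pk1$F)
  expect_equal(pk2$peak_lambda_nm, pk1$peak_lambda_nm)
  expect_equal(attr(pk2, "F0") / pk2$F, attr(pk1, "F0") / pk1$F)

  # a tied argmax resolves to the longer wavelength
  flat_top <- data.frame(Q_mol_per_l = rep(c(0, 1e-5), each = 3),
                         wavelength_nm = rep(c(339, 340, 341), 2),
                         intensity = c(1, 5, 5, 1, 4, 4))
  ts <- titration_series(flat_top, 293, 5e-6)
  expect_equal(peak_reduce(ts)$peak_lambda_nm, c(341, 341))
})

test_that("flat spectra are rejected as peakless", {
  sp <- data.frame(Q_mol_per_l = rep(c(0, 1e-5), each = 3),
                   wavelength_nm = rep(300:302, 2),
                   intensity = c(2, 2, 2, 1, 1, 1))
  expect_error(peak_reduce(titration_series(sp, 293, 5e-6)), "flat spectrum")
})

test_that("Stern-Volmer fit recovers Ksv and enforces Kq = Ksv/tau0", {
  Q <- c(0, 0.5, 1, 2, 4, 5, 10, 20) * 5e-6
  fit <- stern_volmer_fit(sv_points(6.03e4, Q), F0 = 1000, tau0 = 1e-8)
  expect_lt(rel_err(fit$Ksv, 6.03e4), 1e-9)
  expect_identical(fit$Kq * fit$tau0, fit$Ksv)
  expect_equal(fit$free_fit$intercept, 1, tolerance = 1e-6)

  # no quenching: constant F gives Ksv = 0
  none <- data.frame(Q_mol_per_l = Q, F = 1000)
  expect_equal(stern_volmer_fit(none, F0 = 1000)$Ksv, 0)
  expect_error(stern_volmer_fit(sv_points(1e4, Q[1:3]), F0 = 1000),
               "insufficient")
})

test_that("double-log fit reads Ka off the intercept in base 10", {
  Q <- 10^seq(-6, -4, by = 0.5)
  pts <- sv_points(1e5, Q)  # (F0-F)/F = 1e5 * Q, i.e. n = 1
  dl <- double_log_fit(pts, F0 = 1000)
  expect_equal(log10(dl$Ka), 5, tolerance = 1e-9)
  expect_equal(dl$n_sites, 1, tolerance = 1e-9)

  # single-site noiseless quenching: Ka from the double-log plot equals
  # the Stern-Volmer constant
  d <- noiseless_design()
  pk <- peak_reduce(generate_titration(d, default_truth(), 293))
  sv <- stern_volmer_fit(pk)
  dl2 <- double_log_fit(pk)
  expect_lt(rel_err(dl2$Ka, sv$Ksv), 1e-6)
  expect_lt(abs(dl2$n_sites - 1), 1e-6)
})

test_that("sub-linear binding stoichiometry is recovered", {
  tr <- default_truth(Ka_by_T = c("293" = 7.14), n_sites = 0.34)
  ser <- generate_titration(noiseless_design(), tr, 293,
                            model = "double_log")
  dl <- double_log_fit(peak_reduce(ser))
  expect_lt(rel_err(dl$Ka, 7.14), 1e-6)
  expect_lt(rel_err(dl$n_sites, 0.34), 1e-6)
  expect_lt(dl$n_sites, 1)
})

test_that("points without quenching signal are excluded with a warning", {
  Q <- c(0, 1e-6, 2e-6, 1e-5, 2e-5, 1e-4)
  pts <- sv_points(6e4, Q)
  pts$F[2] <- 1001  # above F0
  expect_warning(dl <- double_log_fit(pts, F0 = 1000), "F >= F0")
  expect_equal(dl$n_points, 4L)
})

test_that("mechanism classification separates static, dynamic, conflict", {
  fits <- function(ksv, tau0 = 1e-8) {
    lapply(ksv, function(k) list(Ksv = k, Kq = k / tau0))
  }
  # Ksv falls with temperature and Kq ~ 1e12 >> 2e10: static
  static <- setNames(fits(c(0.58e4, 0.44e4)), c("293", "303"))
  expect_equal(classify_mechanism(static), "static")
  # Kq = 1e9 <= ceiling and Ksv rises: dynamic
  dynamic <- setNames(fits(c(10, 12), tau0 = 1e-2), c("293", "303"))
  expect_equal(classify_mechanism(dynamic), "dynamic")
  # conflicting diagnostics: high Kq but Ksv rising
  conflict <- setNames(fits(c(0.44e4, 0.58e4)), c("293", "303"))
  expect_equal(classify_mechanism(conflict), "indeterminate")
})

test_that("full quenching analysis labels generated static data static", {
  d <- noiseless_design()
  tr <- default_truth()
  qf <- analyze_quenching(list(generate_titration(d, tr, 293),
                               generate_titration(d, tr, 303)))
  expect_equal(qf$mechanism, "static")
  expect_equal(qf$by_T[["293"]]$peak_shift_nm, 2)
  expect_lt(rel_err(qf$by_T[["303"]]$Ksv, 4.19e4), 1e-9)
})
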