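#' Fluorescence titration series
#'
#' Emission spectra (300-400 nm, excitation 280 nm) of the enzyme at a
#' fixed molar concentration, titrated with increasing quencher. The
#' zero-quencher spectrum is the F0 reference.
#'
#' @param spectra Data frame with columns `Q_mol_per_l`, `wavelength_nm`,
#'   `intensity` (long format, one spectrum per quencher concentration).
#' @param temperature Temperature, K.
#' @param enzyme_molar_conc Enzyme molar concentration, mol/L.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(spectra, temperature, enzyme_molar_conc) {
  req <- c("Q_mol_per_l", "wavelength_nm", "intensity")
  miss <- setdiff(req, names(spectra))
  if (length(miss)) {
    stop("titration spectra are missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!any(spectra$Q_mol_per_l == 0)) {
    stop("titration series must contain the zero-quencher reference ",
         "(F0 undefined without it)", call. = FALSE)
  }
  if (any(spectra$intensity < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  grids <- lapply(split(spectra$wavelength_nm, spectra$Q_mol_per_l),
                  sort)
  if (length(unique(grids)) != 1) {
    stop("all spectra must share an identical wavelength grid",
         call. = FALSE)
  }
  structure(
    list(temperature = as.numeric(temperature),
         enzyme_molar_conc = as.numeric(enzyme_molar_conc),
         spectra = spectra),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  qs <- sort(unique(x$spectra$Q_mol_per_l))
  cat(sprintf("Titration series at %g K (%d spectra, [E] = %g mol/L)\n",
              x$temperature, length(qs), x$enzyme_molar_conc))
  cat("  [Q] (mol/L):", paste(signif(qs, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Reduce titration spectra to peak observables
#'
#' For each quencher concentration, extracts the maximum emission
#' intensity F and the wavelength at that maximum. Argmax ties resolve to
#' the longer wavelength so a red shift is never under-reported. The peak
#' shift is `peak_lambda(Q_max) - peak_lambda(0)` (positive = red shift).
#'
#' @param series A [titration_series()].
#' @return Data frame with columns `Q_mol_per_l`, `F`, `peak_lambda_nm`,
#'   ordered by Q, with attributes `F0` (intensity at Q = 0) and
#'   `peak_shift_nm`.
#' @export
peak_reduce <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  rows <- lapply(split(series$spectra, series$spectra$Q_mol_per_l),
                 function(sp) {
    if (max(sp$intensity) == min(sp$intensity)) {
      stop("flat spectrum (no peak) at Q = ", sp$Q_mol_per_l[1],
           " mol/L", call. = FALSE)
    }
    top <- sp$intensity == max(sp$intensity)
    data.frame(Q_mol_per_l = sp$Q_mol_per_l[1],
               F = max(sp$intensity),
               peak_lambda_nm = max(sp$wavelength_nm[top]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$Q_mol_per_l), ]
  rownames(out) <- NULL
  attr(out, "F0") <- out$F[out$Q_mol_per_l == 0]
  attr(out, "peak_shift_nm") <-
    out$peak_lambda_nm[nrow(out)] - out$peak_lambda_nm[out$Q_mol_per_l == 0]
  out
}

#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer relation `F0/F = 1 + Ksv * [Q]`. The primary fit
#' constrains the intercept to 1 (the relation has no free intercept), so
#' `Ksv` is the through-origin least-squares slope of `F0/F - 1` on
#' `[Q]`; a free-intercept regression is reported alongside as a QC
#' diagnostic. The bimolecular quenching constant is `Kq = Ksv / tau0`.
#'
#' @param points Data frame with columns `Q_mol_per_l` and `F` (e.g. from
#'   [peak_reduce()]); >= 3 nonzero-Q points required.
#' @param F0 Unquenched intensity. Defaults to the `F0` attribute of
#'   `points` when present.
#' @param tau0 Unquenched fluorophore lifetime, s.
#' @return List with `Ksv` (L/mol), `Kq` (L/(mol s)), `tau0`, `r2`
#'   (of the constrained fit), and `free_fit` (intercept, slope, r2 of
#'   the diagnostic regression).
#' @export
stern_volmer_fit <- function(points, F0 = attr(points, "F0"),
                             tau0 = 1e-8) {
  stopifnot(is.data.frame(points), !is.null(F0), tau0 > 0)
  pts <- points[points$Q_mol_per_l > 0, ]
  if (nrow(pts) < 3) {
    stop("insufficient data: need >= 3 nonzero-quencher points",
         call. = FALSE)
  }
  if (any(pts$F <= 0)) stop("intensities must be > 0", call. = FALSE)
  y <- F0 / pts$F - 1
  q <- pts$Q_mol_per_l
  Ksv <- sum(q * y) / sum(q^2)
  if (Ksv < 0) {
    warning("negative Stern-Volmer slope: no quenching detected",
            call. = FALSE)
  }
  ss_res <- sum((y - Ksv * q)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  free <- lm(I(F0 / pts$F) ~ q)
  list(Ksv = Ksv,
       Kq = Ksv / tau0,
       tau0 = tau0,
       r2 = r2,
       free_fit = list(intercept = coef(free)[[1]],
                       slope = coef(free)[[2]],
                       r2 = suppressWarnings(summary(free))$r.squared))
}

#' Double-logarithmic binding fit
#'
#' Fits `log10((F0 - F)/F) = log10(Ka) + n * log10([Q])`, giving the
#' apparent binding constant `Ka = 10^intercept` and the number of
#' binding sites `n = slope`. Logs are base 10 throughout; a natural-log
#' slip would shift Ka by factors of e. Points with `F >= F0` carry no
#' binding signal and are excluded with a warning.
#'
#' @param points Data frame with columns `Q_mol_per_l` and `F`.
#' @param F0 Unquenched intensity (defaults to the `F0` attribute).
#' @return List with `Ka` (L/mol), `n_sites`, `r2`, `n_points`.
#' @export
double_log_fit <- function(points, F0 = attr(points, "F0")) {
  stopifnot(is.data.frame(points), !is.null(F0))
  pts <- points[points$Q_mol_per_l > 0, ]
  keep <- pts$F > 0 & pts$F < F0
  if (any(!keep)) {
    warning("excluding ", sum(!keep),
            " point(s) with F >= F0 (no quenching signal)",
            call. = FALSE)
    pts <- pts[keep, ]
  }
  if (nrow(pts) < 3) {
    stop("insufficient data: need >= 3 points with 0 < F < F0",
         call. = FALSE)
  }
  y <- log10((F0 - pts$F) / pts$F)
  x <- log10(pts$Q_mol_per_l)
  fit <- lm(y ~ x)
  list(Ka = 10^coef(fit)[[1]],
       n_sites = coef(fit)[[2]],
       r2 = suppressWarnings(summary(fit))$r.squared,
       n_points = nrow(pts))
}

#' Classify the quenching mechanism
#'
#' Static quenching (ground-state complex formation) requires the
#' bimolecular quenching constant to exceed the diffusion-controlled
#' ceiling of dynamic quenching, `Kq > 2.0e10 L/(mol s)`, at every
#' temperature, and — when two or more temperatures are available — the
#' Stern-Volmer constant to strictly decrease with temperature (a complex
#' dissociates on heating). Dynamic quenching shows the opposite pattern
#' (`Kq` at or below the ceiling, Ksv rising with temperature).
#' Conflicting diagnostics return `"indeterminate"`, never a guess.
#'
#' @param fits_by_T Named list of [stern_volmer_fit()] results (or any
#'   lists with `Ksv` and `Kq`), names being temperatures in K.
#' @param kq_ceiling Diffusion-limited maximum of the dynamic quenching
#'   rate constant, L/(mol s).
#' @return One of `"static"`, `"dynamic"`, `"indeterminate"`.
#' @export
classify_mechanism <- function(fits_by_T, kq_ceiling = 2.0e10) {
  stopifnot(length(fits_by_T) >= 1)
  temps <- as.numeric(names(fits_by_T))
  if (any(is.na(temps))) {
    stop("'fits_by_T' must be named by temperature in K", call. = FALSE)
  }
  ord <- order(temps)
  ksv <- vapply(fits_by_T, function(f) f$Ksv, numeric(1))[ord]
  kq <- vapply(fits_by_T, function(f) f$Kq, numeric(1))[ord]
  if (any(ksv <= 0)) return("indeterminate")
  ksv_decreasing <- length(ksv) < 2 || all(diff(ksv) < 0)
  ksv_increasing <- length(ksv) < 2 || all(diff(ksv) > 0)
  if (all(kq > kq_ceiling) && ksv_decreasing) return("static")
  if (all(kq <= kq_ceiling) && ksv_increasing) return("dynamic")
  "indeterminate"
}

#' Full quenching analysis across temperatures
#'
#' Runs [peak_reduce()], [stern_volmer_fit()] and [double_log_fit()] on
#' each temperature's titration series and classifies the mechanism from
#' the ensemble.
#'
#' @param series_list List of [titration_series()] objects (one per
#'   temperature).
#' @param tau0 Unquenched fluorophore lifetime, s.
#' @return Object of class `quench_fit`: list with `by_T` (per
#'   temperature: Ksv, Kq, Ka, n_sites, r2s, peak_shift_nm) and
#'   `mechanism`.
#' @export
analyze_quenching <- function(series_list, tau0 = 1e-8) {
  stopifnot(length(series_list) >= 1)
  by_T <- lapply(series_list, function(s) {
    stopifnot(inherits(s, "titration_series"))
    pk <- peak_reduce(s)
    sv <- stern_volmer_fit(pk, tau0 = tau0)
    dl <- double_log_fit(pk)
    list(temperature = s$temperature,
         Ksv = sv$Ksv, Kq = sv$Kq, tau0 = tau0,
         Ka = dl$Ka, n_sites = dl$n_sites,
         r2_sv = sv$r2, r2_loglog = dl$r2,
         peak_shift_nm = attr(pk, "peak_shift_nm"),
         free_fit = sv$free_fit)
  })
  names(by_T) <- vapply(by_T, function(f) as.character(f$temperature),
                        character(1))
  structure(
    list(by_T = by_T, mechanism = classify_mechanism(by_T)),
    class = "quench_fit"
  )
}

#' @export
print.quench_fit <- function(x, ...) {
  cat("Fluorescence quenching analysis\n")
  for (f in x$by_T) {
    cat(sprintf(
      "  %g K: Ksv %.4g L/mol  Kq %.4g L/(mol s)  Ka %.4g L/mol  n %.3g  shift %+g nm\n",
      f$temperature, f$Ksv, f$Kq, f$Ka, f$n_sites, f$peak_shift_nm))
  }
  cat("  mechanism:", x$mechanism, "\n")
  invisible(x)
}
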