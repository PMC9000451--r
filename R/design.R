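#' Assay design for synthetic lipase-inhibition experiments
#'
#' Bundles the experimental grids and noise model from which the synthetic
#' generators produce data. The defaults reproduce a typical
#' anthocyanin-versus-pancreatic-lipase study design: inhibitor doses 0-4
#' mg/mL, p-nitrophenyl laurate substrate 0.4-1.6 mg/mL, lipase 5-20 mg/mL,
#' quencher:enzyme molar ratios 0-20:1 at 5e-6 mol/L enzyme, and two
#' temperatures (293 K, 303 K).
#'
#' @param inhibitor_concs Inhibitor doses, mg/mL. May start at 0 (the
#'   uninhibited anchor); otherwise strictly positive and strictly
#'   increasing.
#' @param substrate_concs Substrate doses, mg/mL; strictly positive,
#'   strictly increasing.
#' @param enzyme_concs Enzyme doses, mg/mL; strictly positive, strictly
#'   increasing.
#' @param molar_ratios Quencher:enzyme molar ratios (dimensionless). Must
#'   include 0, the fluorescence reference.
#' @param enzyme_molar_conc Enzyme molar concentration in the titration,
#'   mol/L.
#' @param temperatures Temperatures, K.
#' @param replicates Wells per condition (>= 1).
#' @param noise_sd Relative SD of the multiplicative Gaussian measurement
#'   noise (0 = noiseless).
#' @param seed Integer seed; generation is deterministic given
#'   (design, truth, seed).
#' @return An object of class `assay_design`.
#' @export
#' @examples
#' d <- assay_design(noise_sd = 0.02, seed = 7)
#' d
assay_design <- function(inhibitor_concs = c(0, 0.4, 0.6, 0.8, 1.0, 1.5, 2.0, 4.0),
                         substrate_concs = seq(0.4, 1.6, by = 0.2),
                         enzyme_concs = c(5, 10, 15, 20),
                         molar_ratios = c(0, 0.5, 1, 2, 4, 5, 10, 20),
                         enzyme_molar_conc = 5e-6,
                         temperatures = c(293, 303),
                         replicates = 3L,
                         noise_sd = 0,
                         seed = 1L) {
  check_conc_grid(inhibitor_concs, "inhibitor_concs", allow_leading_zero = TRUE)
  check_conc_grid(substrate_concs, "substrate_concs")
  check_conc_grid(enzyme_concs, "enzyme_concs")
  check_conc_grid(molar_ratios, "molar_ratios", allow_leading_zero = TRUE)
  stopifnot(is.numeric(enzyme_molar_conc), enzyme_molar_conc > 0)
  stopifnot(is.numeric(temperatures), all(temperatures > 0))
  if (!is.numeric(replicates) || replicates < 1) {
    stop("'replicates' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be >= 0", call. = FALSE)
  }
  structure(
    list(
      inhibitor_concs = as.numeric(inhibitor_concs),
      substrate_concs = as.numeric(substrate_concs),
      enzyme_concs = as.numeric(enzyme_concs),
      molar_ratios = as.numeric(molar_ratios),
      enzyme_molar_conc = enzyme_molar_conc,
      temperatures = as.numeric(temperatures),
      replicates = as.integer(replicates),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "assay_design"
  )
}

check_conc_grid <- function(x, name, allow_leading_zero = FALSE) {
  if (!is.numeric(x) || length(x) < 1) {
    stop(sprintf("'%s' must be a numeric vector", name), call. = FALSE)
  }
  body <- if (allow_leading_zero && x[1] == 0) x[-1] else x
  if (length(body) && any(body <= 0)) {
    stop(sprintf("'%s' must be strictly positive (a leading 0 is %s)",
                 name, if (allow_leading_zero) "allowed" else "not allowed"),
         call. = FALSE)
  }
  if (is.unsorted(x, strictly = TRUE)) {
    stop(sprintf("'%s' must be strictly increasing", name), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Assay design\n")
  cat("  inhibitor (mg/mL): ", paste(x$inhibitor_concs, collapse = ", "), "\n")
  cat("  substrate (mg/mL): ", paste(x$substrate_concs, collapse = ", "), "\n")
  cat("  enzyme (mg/mL):    ", paste(x$enzyme_concs, collapse = ", "), "\n")
  cat("  molar ratios:      ", paste(x$molar_ratios, collapse = ", "), "\n")
  cat("  enzyme conc (mol/L):", format(x$enzyme_molar_conc), "\n")
  cat("  temperatures (K):  ", paste(x$temperatures, collapse = ", "), "\n")
  cat(sprintf("  replicates: %d   noise_sd: %g   seed: %d\n",
              x$replicates, x$noise_sd, x$seed))
  invisible(x)
}

#' Ground-truth parameters for the synthetic generators
#'
#' The kinetic, dose-response, quenching and binding parameters that the
#' synthetic data are generated from, and that the fitting routines are
#' expected to recover. Defaults are of the magnitude reported for
#' anthocyanin inhibition of pancreatic lipase (Vmax ~5.5 min^-1,
#' Km ~0.25 mg/mL, Ksv ~6e4 L/mol, fluorophore lifetime 1e-8 s).
#'
#' @param Km Michaelis constant, mg/mL.
#' @param Vmax Maximum velocity, 1/min.
#' @param Ki Competitive inhibition constant, mg/mL.
#' @param IC50 Half-maximal inhibitory concentration, mg/mL.
#' @param probit_slope Slope of the probit dose-response curve, probit
#'   units per log10(mg/mL).
#' @param Ksv_by_T Named numeric: Stern-Volmer constant (L/mol) per
#'   temperature (names are temperatures in K).
#' @param Ka_by_T Named numeric: apparent binding constant (L/mol) per
#'   temperature.
#' @param n_sites Number of binding sites (double-log slope).
#' @param tau0 Unquenched fluorophore lifetime, s (default 1e-8).
#' @param peak_lambda Emission peak centre at zero quencher, nm.
#' @param red_shift_per_ratio Red shift of the peak centre per unit
#'   quencher:enzyme molar ratio, nm.
#' @return An object of class `ground_truth`.
#' @export
#' @examples
#' tr <- ground_truth()
#' tr$Ksv_by_T
ground_truth <- function(Km = 0.25,
                         Vmax = 5.46,
                         Ki = 0.88,
                         IC50 = 1.80,
                         probit_slope = 2.0,
                         Ksv_by_T = c("293" = 6.03e4, "303" = 4.19e4),
                         Ka_by_T = c("293" = 15.53e4, "303" = 9.69e4),
                         n_sites = 1.0,
                         tau0 = 1e-8,
                         peak_lambda = 340,
                         red_shift_per_ratio = 0.1) {
  pos <- c(Km = Km, Vmax = Vmax, Ki = Ki, IC50 = IC50,
           probit_slope = probit_slope, n_sites = n_sites, tau0 = tau0,
           peak_lambda = peak_lambda)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    stop("ground-truth parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(Ksv_by_T)) || is.null(names(Ka_by_T))) {
    stop("'Ksv_by_T' and 'Ka_by_T' must be named by temperature (K)",
         call. = FALSE)
  }
  if (any(Ksv_by_T <= 0) || any(Ka_by_T <= 0)) {
    stop("binding constants must be strictly positive", call. = FALSE)
  }
  structure(
    list(Km = Km, Vmax = Vmax, Ki = Ki, IC50 = IC50,
         probit_slope = probit_slope, Ksv_by_T = Ksv_by_T,
         Ka_by_T = Ka_by_T, n_sites = n_sites, tau0 = tau0,
         peak_lambda = peak_lambda,
         red_shift_per_ratio = red_shift_per_ratio),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth\n")
  cat(sprintf("  Km %.4g mg/mL   Vmax %.4g /min   Ki %.4g mg/mL\n",
              x$Km, x$Vmax, x$Ki))
  cat(sprintf("  IC50 %.4g mg/mL  probit slope %.4g\n",
              x$IC50, x$probit_slope))
  cat("  Ksv (L/mol):", paste(sprintf("%s K = %.4g", names(x$Ksv_by_T),
                                      x$Ksv_by_T), collapse = ", "), "\n")
  cat("  Ka  (L/mol):", paste(sprintf("%s K = %.4g", names(x$Ka_by_T),
                                      x$Ka_by_T), collapse = ", "), "\n")
  cat(sprintf("  n %.3g   tau0 %.3g s   peak %.4g nm (+%.3g nm/ratio)\n",
              x$n_sites, x$tau0, x$peak_lambda, x$red_shift_per_ratio))
  invisible(x)
}

#' Competitive-inhibition velocity law
#'
#' Michaelis-Menten rate in the presence of a competitive inhibitor:
#' `v = Vmax * S / (Km * (1 + I/Ki) + S)`. The apparent Michaelis constant
#' is `Km * (1 + I/Ki)` while Vmax is unchanged — the signature used to
#' call an inhibitor competitive.
#'
#' @param S Substrate concentration, mg/mL.
#' @param I Inhibitor concentration, mg/mL.
#' @param Km,Vmax,Ki Kinetic parameters (mg/mL, 1/min, mg/mL).
#' @return Velocity, 1/min. Vectorised over `S` and `I`.
#' @export
#' @examples
#' competitive_velocity(S = 0.25, I = 0.88, Km = 0.25, Vmax = 5.46, Ki = 0.88)
competitive_velocity <- function(S, I, Km, Vmax, Ki) {
  stopifnot(Km > 0, Vmax > 0, Ki > 0, all(S > 0), all(I >= 0))
  Vmax * S / (Km * (1 + I / Ki) + S)
}

#' Probit dose-response inhibition fraction
#'
#' Forward model for the designed inhibition fraction: a probit
#' (inverse-normal) curve in log10 concentration centred at IC50,
#' `p = pnorm(slope * (log10(I) - log10(IC50)))`, with p = 0 at zero dose.
#' Matches the probit regression used for IC50 estimation, so
#' generation and fitting are self-consistent.
#'
#' @param truth A [ground_truth()] object.
#' @param conc Inhibitor concentration(s), mg/mL (0 allowed).
#' @return Inhibition fraction in `[0, 1]`.
#' @export
inhibition_fraction <- function(truth, conc) {
  stopifnot(inherits(truth, "ground_truth"), all(conc >= 0))
  ifelse(conc <= 0, 0,
         pnorm(truth$probit_slope * (log10(conc) - log10(truth$IC50))))
}
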