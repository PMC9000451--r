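# gas constant, J/(mol K); all energies computed in J internally and
# converted to kJ at the reporting boundary only
GAS_CONSTANT <- 8.314
KJ <- 1000

#' Gibbs free energy of binding
#'
#' `dG = -R T ln(K)`, reported in kJ/mol.
#'
#' @param K Binding constant, L/mol (> 0).
#' @param T_K Temperature, K.
#' @param R Gas constant, J/(mol K).
#' @return Gibbs energy, kJ/mol. Vectorised.
#' @export
#' @examples
#' gibbs(7.14, 293)      # -4.79
#' gibbs(9.69e4, 303)    # -28.92
gibbs <- function(K, T_K, R = GAS_CONSTANT) {
  if (any(K <= 0)) stop("binding constant K must be > 0", call. = FALSE)
  if (any(T_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  -R * T_K * log(K) / KJ
}

#' Van't Hoff binding enthalpy from two temperatures
#'
#' `dH = R * ln(Ka2/Ka1) / (1/T1 - 1/T2)`, in kJ/mol, under the usual
#' assumption that dH is constant over the temperature interval.
#'
#' @param Ka1,Ka2 Binding constants (L/mol) at `T1` and `T2`.
#' @param T1,T2 Temperatures, K (must differ).
#' @param R Gas constant, J/(mol K).
#' @return Enthalpy change, kJ/mol.
#' @export
#' @examples
#' vant_hoff_enthalpy(7.14, 3.15, 293, 303)  # about -60.4
vant_hoff_enthalpy <- function(Ka1, Ka2, T1, T2, R = GAS_CONSTANT) {
  stopifnot(Ka1 > 0, Ka2 > 0, T1 > 0, T2 > 0)
  if (T1 == T2) {
    stop("T1 and T2 must differ (van't Hoff slope undefined)",
         call. = FALSE)
  }
  R * log(Ka2 / Ka1) / (1 / T1 - 1 / T2) / KJ
}

#' Binding entropy change
#'
#' `dS = (dH - dG) / T`, with dH and dG in kJ/mol and dS reported in
#' J/(mol K).
#'
#' @param dH Enthalpy change, kJ/mol.
#' @param dG Gibbs energy change, kJ/mol.
#' @param T_K Temperature, K.
#' @return Entropy change, J/(mol K). Vectorised.
#' @export
#' @examples
#' entropy_change(-60.37, -4.79, 293)  # about -189.7
entropy_change <- function(dH, dG, T_K) {
  if (any(T_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  (dH - dG) * KJ / T_K
}

#' Classify the dominant intermolecular forces
#'
#' The classical sign-pattern rubric for protein-ligand binding:
#' * `dH < 0` and `dS < 0` — hydrogen bonds and van der Waals forces
#'   (`"hbond_vdw"`);
#' * `dH > 0` and `dS > 0` — hydrophobic interactions (`"hydrophobic"`);
#' * `dH ~ 0` and `dS > 0` — electrostatic interactions
#'   (`"electrostatic"`);
#' * any other pattern — `"indeterminate"`.
#'
#' The near-zero bands give the `~ 0` branch an explicit width.
#'
#' @param dH Enthalpy change, kJ/mol.
#' @param dS Entropy change, J/(mol K).
#' @param tol_dH Half-width of the "dH is zero" band, kJ/mol.
#' @param tol_dS Half-width of the "dS is zero" band, J/(mol K).
#' @return One of `"hbond_vdw"`, `"hydrophobic"`, `"electrostatic"`,
#'   `"indeterminate"`.
#' @export
#' @examples
#' classify_forces(-60.37, -189.70)  # hbond_vdw
classify_forces <- function(dH, dS, tol_dH = 1, tol_dS = 5) {
  stopifnot(tol_dH > 0, tol_dS > 0)
  if (dH < -tol_dH && dS < -tol_dS) return("hbond_vdw")
  if (dH > tol_dH && dS > tol_dS) return("hydrophobic")
  if (abs(dH) <= tol_dH && dS > tol_dS) return("electrostatic")
  "indeterminate"
}

#' Binding thermodynamics from temperature-dependent binding constants
#'
#' Computes dG at every temperature, the van't Hoff dH (pairwise for
#' more than two temperatures, with a warning, then averaged), dS at
#' every temperature, the force classification and spontaneity.
#'
#' @param Ka_by_T Named numeric vector of binding constants (L/mol),
#'   names being temperatures in K; at least two temperatures.
#' @param R Gas constant, J/(mol K).
#' @param tol_dH,tol_dS Near-zero bands passed to [classify_forces()].
#' @return Object of class `thermo_result`: list with `dG_by_T`
#'   (kJ/mol), `dH` (kJ/mol), `dS_by_T` (J/(mol K)), `forces`,
#'   `spontaneous`.
#' @export
#' @examples
#' thermo_analysis(c("293" = 7.14, "303" = 3.15))
thermo_analysis <- function(Ka_by_T, R = GAS_CONSTANT, tol_dH = 1,
                            tol_dS = 5) {
  temps <- as.numeric(names(Ka_by_T))
  if (any(is.na(temps)) || length(temps) < 2) {
    stop("'Ka_by_T' must be named by >= 2 temperatures in K",
         call. = FALSE)
  }
  ord <- order(temps)
  temps <- temps[ord]
  Ka <- as.numeric(Ka_by_T)[ord]
  dG <- setNames(gibbs(Ka, temps, R), temps)
  if (length(temps) > 2) {
    warning("more than two temperatures: van't Hoff dH fitted pairwise ",
            "on consecutive temperatures and averaged", call. = FALSE)
  }
  pair_dH <- vapply(seq_len(length(temps) - 1), function(i) {
    vant_hoff_enthalpy(Ka[i], Ka[i + 1], temps[i], temps[i + 1], R)
  }, numeric(1))
  dH <- mean(pair_dH)
  dS <- setNames(entropy_change(dH, dG, temps), temps)
  structure(
    list(Ka_by_T = setNames(Ka, temps),
         dG_by_T = dG, dH = dH, dS_by_T = dS,
         forces = classify_forces(dH, mean(dS), tol_dH, tol_dS),
         spontaneous = all(dG < 0)),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("Binding thermodynamics (van't Hoff)\n")
  cat(sprintf("  dH: %.2f kJ/mol\n", x$dH))
  for (tK in names(x$dG_by_T)) {
    cat(sprintf("  %s K: dG %.2f kJ/mol   dS %.2f J/(mol K)\n",
                tK, x$dG_by_T[[tK]], x$dS_by_T[[tK]]))
  }
  cat("  forces:", x$forces,
      if (x$spontaneous) "(spontaneous binding)" else "(non-spontaneous)",
      "\n")
  invisible(x)
}

#' Cross-check printed binding constants against printed Gibbs energies
#'
#' Recomputes `dG = -R T ln(Ka)` for each row of a binding table and
#' flags rows whose printed dG disagrees beyond `tol`. Published tables
#' sometimes carry transposed sample labels between the binding-constant
#' and thermodynamics tables; this check surfaces such inconsistencies
#' instead of silently propagating them.
#'
#' @param binding Data frame with columns `sample`, `T_K`,
#'   `Ka_L_per_mol` and `dG_kJ_mol` (the printed value).
#' @param tol Absolute mismatch tolerance, kJ/mol.
#' @param R Gas constant, J/(mol K).
#' @return Character vector of flags (empty when consistent); the
#'   annotated table (with `dG_recomputed_kJ_mol` and `consistent`) is
#'   attached as attribute `"table"`.
#' @export
check_binding_consistency <- function(binding, tol = 0.5,
                                      R = GAS_CONSTANT) {
  req <- c("sample", "T_K", "Ka_L_per_mol", "dG_kJ_mol")
  miss <- setdiff(req, names(binding))
  if (length(miss)) {
    stop("binding table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  binding$dG_recomputed_kJ_mol <- gibbs(binding$Ka_L_per_mol,
                                        binding$T_K, R)
  binding$consistent <-
    abs(binding$dG_recomputed_kJ_mol - binding$dG_kJ_mol) <= tol
  flags <- character(0)
  for (i in which(!binding$consistent)) {
    flags <- c(flags, sprintf(
      "dG/Ka mismatch for sample '%s' at %g K: printed dG %.2f kJ/mol but -RT ln(Ka = %.4g) = %.2f kJ/mol",
      binding$sample[i], binding$T_K[i], binding$dG_kJ_mol[i],
      binding$Ka_L_per_mol[i], binding$dG_recomputed_kJ_mol[i]))
  }
  attr(flags, "table") <- binding
  flags
}
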