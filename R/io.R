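# CSV dialect: comma-separated, UTF-8, mandatory header, decimal point.
# Column names carry explicit unit suffixes (_mg_ml, _mol_per_l) so
# mg/mL-vs-mol/L confusion cannot be committed silently.
read_assay_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(basename(path), " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a plate-assay CSV
#'
#' Long format: `sample_id, inhibitor_conc_mg_ml, replicate, role,
#' absorbance` with role in `{A, a, B, b}`.
#'
#' @param path CSV path.
#' @return A [plate_assay()].
#' @export
read_plate_csv <- function(path) {
  plate_assay(read_assay_csv(path, c("sample_id", "inhibitor_conc_mg_ml",
                                     "replicate", "role", "absorbance")))
}

#' Read a velocity-series CSV
#'
#' Columns: `substrate_conc_mg_ml, enzyme_conc_mg_ml,
#' inhibitor_conc_mg_ml, velocity_per_min`.
#'
#' @param path CSV path.
#' @return A [velocity_series()].
#' @export
read_kinetics_csv <- function(path) {
  velocity_series(read_assay_csv(path, c("substrate_conc_mg_ml",
                                         "enzyme_conc_mg_ml",
                                         "inhibitor_conc_mg_ml",
                                         "velocity_per_min")))
}

#' Read titration spectra via a manifest
#'
#' The manifest CSV maps per-point spectrum files (two columns:
#' `wavelength_nm, intensity`) to quencher concentration and
#' temperature: columns `file, Q_mol_per_l, temperature_K,
#' enzyme_molar_conc_mol_per_l`. File paths are resolved relative to the
#' manifest's directory.
#'
#' @param manifest_path Manifest CSV path.
#' @return Named list of [titration_series()], one per temperature
#'   (names are temperatures in K).
#' @export
read_titration_manifest <- function(manifest_path) {
  man <- read_assay_csv(manifest_path,
                        c("file", "Q_mol_per_l", "temperature_K",
                          "enzyme_molar_conc_mol_per_l"))
  base <- dirname(manifest_path)
  out <- lapply(split(man, man$temperature_K), function(m) {
    specs <- lapply(seq_len(nrow(m)), function(i) {
      sp <- read_assay_csv(file.path(base, m$file[i]),
                           c("wavelength_nm", "intensity"))
      sp$Q_mol_per_l <- m$Q_mol_per_l[i]
      sp
    })
    titration_series(do.call(rbind, specs),
                     temperature = m$temperature_K[1],
                     enzyme_molar_conc = m$enzyme_molar_conc_mol_per_l[1])
  })
  names(out) <- vapply(out, function(s) as.character(s$temperature),
                       character(1))
  out
}

#' Read a binding-constant table
#'
#' Columns: `sample, T_K, Ka_L_per_mol`, optionally `dG_kJ_mol` (printed
#' Gibbs energies, enabling the dG/Ka consistency cross-check).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_binding_csv <- function(path) {
  read_assay_csv(path, c("sample", "T_K", "Ka_L_per_mol"))
}
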