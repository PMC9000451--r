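# multiplicative Gaussian measurement noise, truncated at zero:
# plate readers and fluorometers have signal-proportional error and
# negative signals are unphysical
apply_noise <- function(x, noise_sd) {
  if (noise_sd == 0) return(x)
  pmax(x * (1 + rnorm(length(x), mean = 0, sd = noise_sd)), 0)
}

#' Generate a synthetic endpoint plate assay
#'
#' Forward model for the chromogenic endpoint assay: the blank-corrected
#' uninhibited signal is a fixed window `a - A`, and the sample signal is
#' that window scaled by `1 - p(I)`, where `p(I)` is the probit
#' dose-response [inhibition_fraction()] of the ground truth. The sample
#' blank `B` includes a small inhibitor self-absorbance term. Applying
#' the blank-correction formula to the noiseless wells therefore
#' recovers the designed inhibition fraction exactly; multiplicative
#' noise is applied per well.
#'
#' @param design An [assay_design()].
#' @param truth A [ground_truth()].
#' @param sample_id Sample label written into the table.
#' @return A [plate_assay()] (long format).
#' @export
#' @examples
#' pa <- generate_plate_assay(assay_design(noise_sd = 0), ground_truth())
#' aggregate_dose_response(pa)
generate_plate_assay <- function(design, truth, sample_id = "sample_1") {
  stopifnot(inherits(design, "assay_design"),
            inherits(truth, "ground_truth"))
  if (any(design$substrate_concs <= 0) || any(design$enzyme_concs <= 0)) {
    stop("invalid design: enzyme and substrate concentrations must be ",
         "positive", call. = FALSE)
  }
  blank <- 0.10        # buffer + substrate background absorbance
  signal0 <- 0.80      # blank-corrected uninhibited signal window
  inh_abs <- 0.005     # inhibitor self-absorbance per mg/mL
  withr::with_seed(design$seed, {
    rows <- list()
    for (conc in design$inhibitor_concs) {
      p <- inhibition_fraction(truth, conc)
      for (rep in seq_len(design$replicates)) {
        ab <- c(A = blank,
                a = blank + signal0,
                B = blank + inh_abs * conc,
                b = blank + inh_abs * conc + signal0 * (1 - p))
        ab <- apply_noise(ab, design$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id,
          inhibitor_conc_mg_ml = conc,
          replicate = rep,
          role = names(ab),
          absorbance = unname(ab))
      }
    }
    plate_assay(do.call(rbind, rows))
  })
}

#' Generate a synthetic velocity series
#'
#' Two layouts:
#' * `kind = "substrate"` — initial velocity over the substrate grid for
#'   each inhibitor dose, from the competitive rate law
#'   `V = Vmax S / (Km (1 + I/Ki) + S)`; the input for Lineweaver-Burk
#'   analysis.
#' * `kind = "enzyme"` — velocity over the enzyme grid at fixed
#'   substrate for each dose; the input for the reversibility type plot.
#'   With `reversible = TRUE` velocity is proportional to enzyme
#'   concentration with a dose-dependent slope (lines through the
#'   origin); with `reversible = FALSE` the inhibitor inactivates a
#'   fixed amount of enzyme per mg/mL dose, producing parallel lines
#'   with negative intercepts.
#'
#' Each grid point is measured `design$replicates` times with
#' independent noise, mirroring the triplicate wells of the endpoint
#' assay.
#'
#' @param design An [assay_design()].
#' @param truth A [ground_truth()].
#' @param kind `"substrate"` or `"enzyme"`.
#' @param substrate_conc Fixed substrate concentration for the enzyme
#'   layout, mg/mL.
#' @param reversible Logical; enzyme-layout mechanism (see above).
#' @param inactivation_mg_per_mg Enzyme inactivated (mg/mL) per mg/mL
#'   inhibitor in the irreversible model.
#' @return A [velocity_series()].
#' @export
generate_velocity_series <- function(design, truth,
                                     kind = c("substrate", "enzyme"),
                                     substrate_conc = 1.0,
                                     reversible = TRUE,
                                     inactivation_mg_per_mg = 1.0) {
  stopifnot(inherits(design, "assay_design"),
            inherits(truth, "ground_truth"))
  kind <- match.arg(kind)
  withr::with_seed(design$seed + 1L, {
    reps <- design$replicates
    if (kind == "substrate") {
      grid <- expand.grid(S = rep(design$substrate_concs, reps),
                          I = design$inhibitor_concs)
      v <- competitive_velocity(grid$S, grid$I, truth$Km, truth$Vmax,
                                truth$Ki)
      out <- data.frame(substrate_conc_mg_ml = grid$S,
                        enzyme_conc_mg_ml = design$enzyme_concs[1],
                        inhibitor_conc_mg_ml = grid$I,
                        velocity_per_min = apply_noise(v, design$noise_sd))
    } else {
      grid <- expand.grid(E = rep(design$enzyme_concs, reps),
                          I = design$inhibitor_concs)
      e_ref <- max(design$enzyme_concs)
      if (reversible) {
        v_at_ref <- competitive_velocity(substrate_conc, grid$I,
                                         truth$Km, truth$Vmax, truth$Ki)
        v <- v_at_ref * grid$E / e_ref
      } else {
        slope0 <- competitive_velocity(substrate_conc, 0, truth$Km,
                                       truth$Vmax, truth$Ki) / e_ref
        v <- pmax(0, slope0 * (grid$E - inactivation_mg_per_mg * grid$I))
      }
      out <- data.frame(substrate_conc_mg_ml = substrate_conc,
                        enzyme_conc_mg_ml = grid$E,
                        inhibitor_conc_mg_ml = grid$I,
                        velocity_per_min = apply_noise(v, design$noise_sd))
    }
    velocity_series(out)
  })
}

#' Generate a synthetic fluorescence titration
#'
#' Emits one Gaussian emission band (sd 18 nm) per quencher
#' concentration on the 300-400 nm grid (1 nm steps). The band amplitude
#' follows the quenching model: `F = F0 / (1 + Ksv [Q])`
#' (`model = "stern_volmer"`, the static single-site default) or
#' `F = F0 / (1 + Ka [Q]^n)` (`model = "double_log"`, for fractional
#' binding stoichiometries). The band centre red-shifts by
#' `red_shift_per_ratio` nm per unit molar ratio and is snapped to the
#' wavelength grid so the grid maximum equals the model amplitude
#' exactly. Quencher molarity is `[Q] = ratio * enzyme_molar_conc`.
#'
#' @param design An [assay_design()] whose `molar_ratios` include 0.
#' @param truth A [ground_truth()] with `Ksv_by_T`/`Ka_by_T` entries for
#'   `temperature`.
#' @param temperature Temperature, K.
#' @param model Quenching forward model (see above).
#' @return A [titration_series()].
#' @export
generate_titration <- function(design, truth, temperature = 293,
                               model = c("stern_volmer", "double_log")) {
  stopifnot(inherits(design, "assay_design"),
            inherits(truth, "ground_truth"))
  model <- match.arg(model)
  if (!any(design$molar_ratios == 0)) {
    stop("molar_ratios must include 0: the zero-quencher spectrum ",
         "defines F0", call. = FALSE)
  }
  tkey <- as.character(temperature)
  if (model == "stern_volmer" && !tkey %in% names(truth$Ksv_by_T)) {
    stop("no ground-truth Ksv at ", temperature, " K", call. = FALSE)
  }
  if (model == "double_log" && !tkey %in% names(truth$Ka_by_T)) {
    stop("no ground-truth Ka at ", temperature, " K", call. = FALSE)
  }
  wl <- seq(300, 400, by = 1)
  F0 <- 1000
  band_sd <- 18
  withr::with_seed(design$seed + 2L + round(temperature), {
    specs <- lapply(design$molar_ratios, function(ratio) {
      Q <- ratio * design$enzyme_molar_conc
      amp <- switch(model,
        stern_volmer = F0 / (1 + truth$Ksv_by_T[[tkey]] * Q),
        double_log = if (Q == 0) F0 else
          F0 / (1 + truth$Ka_by_T[[tkey]] * Q^truth$n_sites))
      centre <- round(truth$peak_lambda + truth$red_shift_per_ratio * ratio)
      inten <- amp * exp(-(wl - centre)^2 / (2 * band_sd^2))
      data.frame(Q_mol_per_l = Q, wavelength_nm = wl,
                 intensity = apply_noise(inten, design$noise_sd))
    })
    titration_series(do.call(rbind, specs), temperature,
                     design$enzyme_molar_conc)
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates every pipeline input from one (design, truth) pair and
#' writes it in the CSV dialects the readers consume: the plate table,
#' the substrate- and enzyme-layout kinetics tables, one spectrum CSV
#' per titration point plus a manifest, and the ground truth as JSON.
#'
#' @param dir Output directory (created if needed).
#' @param design An [assay_design()].
#' @param truth A [ground_truth()].
#' @return Invisibly, a named list of the written paths, directly usable
#'   as [run_config()] arguments (`plate`, `kinetics`, `type_plot`,
#'   `quench_manifest`, `truth`).
#' @export
write_synthetic_fixtures <- function(dir, design, truth) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spectra"), showWarnings = FALSE)
  paths <- list(
    plate = file.path(dir, "plate.csv"),
    kinetics = file.path(dir, "kinetics_substrate.csv"),
    type_plot = file.path(dir, "kinetics_enzyme.csv"),
    quench_manifest = file.path(dir, "spectra", "manifest.csv"),
    truth = file.path(dir, "truth.json"))

  write.csv(generate_plate_assay(design, truth), paths$plate,
            row.names = FALSE)
  write.csv(generate_velocity_series(design, truth, kind = "substrate"),
            paths$kinetics, row.names = FALSE)
  write.csv(generate_velocity_series(design, truth, kind = "enzyme"),
            paths$type_plot, row.names = FALSE)

  manifest <- list()
  for (temp in design$temperatures) {
    ser <- generate_titration(design, truth, temperature = temp)
    for (Q in sort(unique(ser$spectra$Q_mol_per_l))) {
      fn <- sprintf("spectrum_T%g_Q%g.csv", temp, Q)
      sp <- ser$spectra[ser$spectra$Q_mol_per_l == Q,
                        c("wavelength_nm", "intensity")]
      write.csv(sp, file.path(dir, "spectra", fn), row.names = FALSE)
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = fn, Q_mol_per_l = Q, temperature_K = temp,
        enzyme_molar_conc_mol_per_l = design$enzyme_molar_conc)
    }
  }
  write.csv(do.call(rbind, manifest), paths$quench_manifest,
            row.names = FALSE)
  jsonlite::write_json(unclass(truth), paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
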