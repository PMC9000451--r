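#' Pipeline run configuration
#'
#' Collects input paths and tolerances for [run_pipeline()]. Any stage
#' input may be `NULL`; the corresponding stage is skipped and flagged.
#'
#' @param plate Plate-assay CSV path (inhibition / IC50 stage).
#' @param kinetics Substrate-layout velocity CSV (Lineweaver-Burk stage).
#' @param type_plot Enzyme-layout velocity CSV (reversibility stage).
#' @param quench_manifest Titration manifest CSV (quenching stage).
#' @param binding Binding-constant CSV; when it carries a `dG_kJ_mol`
#'   column the dG/Ka consistency cross-check runs on it. When no
#'   quenching input is present it also feeds the thermodynamics stage.
#' @param tau0 Fluorophore lifetime, s.
#' @param vmax_tol Relative Vmax-constancy tolerance (kinetics verdict).
#' @param intercept_tol Relative intercept-zero tolerance (reversibility).
#' @param clamp_margin Probit clamp margins, percent.
#' @param force_tol_dH,force_tol_dS Near-zero bands for the force
#'   classification (kJ/mol, J/(mol K)).
#' @param consistency_tol dG/Ka mismatch tolerance, kJ/mol.
#' @return Object of class `run_config`.
#' @export
run_config <- function(plate = NULL, kinetics = NULL, type_plot = NULL,
                       quench_manifest = NULL, binding = NULL,
                       tau0 = 1e-8, vmax_tol = 0.05,
                       intercept_tol = 0.05,
                       clamp_margin = c(0.5, 99.5),
                       force_tol_dH = 1, force_tol_dS = 5,
                       consistency_tol = 0.5) {
  for (p in c(plate, kinetics, type_plot, quench_manifest, binding)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  stopifnot(tau0 > 0, vmax_tol > 0, intercept_tol > 0,
            force_tol_dH > 0, force_tol_dS > 0, consistency_tol > 0)
  structure(
    list(plate = plate, kinetics = kinetics, type_plot = type_plot,
         quench_manifest = quench_manifest, binding = binding,
         tau0 = tau0, vmax_tol = vmax_tol, intercept_tol = intercept_tol,
         clamp_margin = clamp_margin, force_tol_dH = force_tol_dH,
         force_tol_dS = force_tol_dS, consistency_tol = consistency_tol),
    class = "run_config"
  )
}

#' Run the full characterisation pipeline
#'
#' Chains inhibition -> kinetics -> quenching -> thermodynamics on
#' whichever inputs the configuration provides. A stage whose input is
#' missing, or whose preconditions fail, is skipped and recorded in
#' `consistency_flags`; the other stages still run. The thermodynamics
#' stage consumes the double-log binding constants from the quenching
#' stage (or, failing that, a binding CSV), and the dG/Ka cross-check
#' runs whenever a binding table with printed dG values is supplied.
#'
#' @param cfg A [run_config()].
#' @return Object of class `study_report` with elements `ic50_table`
#'   (per sample: IC50, CI, R^2), `kinetic_table` (Vmax, Km, Ki,
#'   verdict, reversibility), `quench_table` (per temperature: Ksv, Kq,
#'   Ka, n, peak shift; plus the mechanism), `thermo_table` (dH, per
#'   temperature dG and dS, forces, spontaneity), `consistency_flags`
#'   (character, possibly empty, never absent) and `parameters` (the
#'   tolerances used).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  flags <- character(0)
  note <- function(msg) flags <<- c(flags, msg)

  ic50_table <- NULL
  if (is.null(cfg$plate)) {
    note("inhibition inputs missing: stage skipped")
  } else {
    ic50_table <- tryCatch({
      assay <- read_plate_csv(cfg$plate)
      rows <- lapply(split(assay, assay$sample_id), function(sub) {
        class(sub) <- class(assay)
        dr <- aggregate_dose_response(sub)
        fit <- suppressWarnings(fit_ic50(dr, cfg$clamp_margin))
        data.frame(sample = sub$sample_id[1],
                   ic50_mg_ml = fit$ic50,
                   ci95_low_mg_ml = fit$ci95[1],
                   ci95_high_mg_ml = fit$ci95[2],
                   probit_slope = fit$slope, r2 = fit$r2,
                   extrapolated = fit$extrapolated)
      })
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    }, error = function(e) {
      note(paste("inhibition stage failed:", conditionMessage(e)))
      NULL
    })
  }

  kinetic_table <- NULL
  if (is.null(cfg$kinetics)) {
    note("kinetics inputs missing: stage skipped")
  } else {
    kinetic_table <- tryCatch({
      vs <- read_kinetics_csv(cfg$kinetics)
      lb <- lineweaver_burk(vs, vmax_tol = cfg$vmax_tol)
      mm <- michaelis_menten_fit(vs)
      if (!is.null(cfg$type_plot)) {
        tp <- fit_type_plot(read_kinetics_csv(cfg$type_plot))
        lb$reversibility <- classify_reversibility(tp, cfg$intercept_tol)
      }
      list(Vmax_per_min = lb$Vmax, Km_mg_ml = lb$Km, Ki_mg_ml = lb$Ki,
           Km_app_by_I_mg_ml = as.list(lb$Km_app_by_I),
           Vmax_mm_per_min = mm$Vmax, Km_mm_mg_ml = mm$Km,
           verdict = lb$verdict, reversibility = lb$reversibility)
    }, error = function(e) {
      note(paste("kinetics stage failed:", conditionMessage(e)))
      NULL
    })
  }

  quench_table <- NULL
  Ka_by_T <- NULL
  if (is.null(cfg$quench_manifest)) {
    note("quenching inputs missing: stage skipped")
  } else {
    quench_table <- tryCatch({
      series <- read_titration_manifest(cfg$quench_manifest)
      qf <- analyze_quenching(series, tau0 = cfg$tau0)
      Ka_by_T <- vapply(qf$by_T, function(f) f$Ka, numeric(1))
      rows <- lapply(qf$by_T, function(f) {
        data.frame(T_K = f$temperature,
                   Ksv_L_per_mol = f$Ksv, Kq_L_per_mol_s = f$Kq,
                   Ka_L_per_mol = f$Ka, n_sites = f$n_sites,
                   peak_shift_nm = f$peak_shift_nm,
                   r2_sv = f$r2_sv, r2_loglog = f$r2_loglog)
      })
      tab <- do.call(rbind, rows)
      rownames(tab) <- NULL
      list(by_T = tab, mechanism = qf$mechanism)
    }, error = function(e) {
      note(paste("quenching stage failed:", conditionMessage(e)))
      NULL
    })
  }

  binding_tab <- if (!is.null(cfg$binding)) read_binding_csv(cfg$binding)
  if (is.null(Ka_by_T) && !is.null(binding_tab)) {
    samples <- unique(binding_tab$sample)
    if (length(samples) == 1) {
      Ka_by_T <- setNames(binding_tab$Ka_L_per_mol,
                          binding_tab$T_K)
    } else {
      # thermodynamics below runs per sample
      Ka_by_T <- NULL
    }
  }

  thermo_table <- NULL
  if (!is.null(cfg$binding) && length(unique(binding_tab$sample)) > 1) {
    thermo_table <- tryCatch({
      lapply(split(binding_tab, binding_tab$sample), function(b) {
        format_thermo(thermo_analysis(setNames(b$Ka_L_per_mol, b$T_K),
                                      tol_dH = cfg$force_tol_dH,
                                      tol_dS = cfg$force_tol_dS))
      })
    }, error = function(e) {
      note(paste("thermodynamics stage failed:", conditionMessage(e)))
      NULL
    })
  } else if (!is.null(Ka_by_T) && length(Ka_by_T) >= 2) {
    thermo_table <- tryCatch({
      format_thermo(thermo_analysis(Ka_by_T, tol_dH = cfg$force_tol_dH,
                                    tol_dS = cfg$force_tol_dS))
    }, error = function(e) {
      note(paste("thermodynamics stage failed:", conditionMessage(e)))
      NULL
    })
  } else {
    note("thermodynamics inputs missing: stage skipped")
  }

  if (!is.null(binding_tab) && "dG_kJ_mol" %in% names(binding_tab)) {
    flags <- c(flags,
               check_binding_consistency(binding_tab,
                                         tol = cfg$consistency_tol))
  }

  structure(
    list(ic50_table = ic50_table,
         kinetic_table = kinetic_table,
         quench_table = quench_table,
         thermo_table = thermo_table,
         consistency_flags = as.character(flags),
         parameters = list(tau0_s = cfg$tau0, vmax_tol = cfg$vmax_tol,
                           intercept_tol = cfg$intercept_tol,
                           clamp_margin_pct = cfg$clamp_margin,
                           force_tol_dH_kJ_mol = cfg$force_tol_dH,
                           force_tol_dS_J_mol_K = cfg$force_tol_dS,
                           consistency_tol_kJ_mol = cfg$consistency_tol)),
    class = "study_report"
  )
}

format_thermo <- function(th) {
  list(dH_kJ_mol = th$dH,
       by_T = data.frame(T_K = as.numeric(names(th$dG_by_T)),
                         dG_kJ_mol = unname(th$dG_by_T),
                         dS_J_mol_K = unname(th$dS_by_T)),
       forces = th$forces,
       spontaneous = th$spontaneous)
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Lipase inhibitor characterisation report ==\n")
  if (!is.null(x$ic50_table)) {
    cat("\nIC50 (probit regression):\n")
    print(x$ic50_table, digits = 4)
  }
  if (!is.null(x$kinetic_table)) {
    k <- x$kinetic_table
    cat(sprintf("\nKinetics: Vmax %.4g /min  Km %.4g mg/mL  Ki %.4g mg/mL  [%s%s]\n",
                k$Vmax_per_min, k$Km_mg_ml, k$Ki_mg_ml, k$verdict,
                if (is.na(k$reversibility)) "" else
                  paste0(", ", k$reversibility)))
  }
  if (!is.null(x$quench_table)) {
    cat("\nQuenching (mechanism:", x$quench_table$mechanism, "):\n")
    print(x$quench_table$by_T, digits = 4)
  }
  if (!is.null(x$thermo_table)) {
    cat("\nThermodynamics:\n")
    th <- x$thermo_table
    if (!is.null(th$dH_kJ_mol)) th <- list(sample = th)
    for (nm in names(th)) {
      t1 <- th[[nm]]
      cat(sprintf("  %s: dH %.2f kJ/mol, forces %s\n", nm, t1$dH_kJ_mol,
                  t1$forces))
      print(t1$by_T, digits = 6)
    }
  }
  if (length(x$consistency_flags)) {
    cat("\nFlags:\n")
    for (fl in x$consistency_flags) cat("  -", fl, "\n")
  } else {
    cat("\nFlags: none\n")
  }
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' Floats are serialised at fixed precision (10 significant digits) so
#' re-running on identical inputs yields byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = 10, null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a study report against the shipped schema
#'
#' Checks the report (or a JSON file written by [write_report()])
#' against the JSON schema in `inst/extdata/report-schema.json`:
#' required keys present, types as declared (skipped stages may be
#' null).
#'
#' @param report A `study_report`, or a path to a report JSON file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  obj <- if (is.character(report)) {
    jsonlite::read_json(report, simplifyVector = FALSE)
  } else {
    jsonlite::parse_json(jsonlite::toJSON(unclass(report),
                                          auto_unbox = TRUE,
                                          null = "null", digits = 10))
  }
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "enzybind"))
  for (key in schema$required) {
    if (!key %in% names(obj)) {
      stop("report is missing required key '", key, "'", call. = FALSE)
    }
  }
  for (key in names(schema$properties)) {
    if (!key %in% names(obj) || is.null(obj[[key]])) next
    want <- schema$properties[[key]]$type
    ok <- switch(want,
                 array = is.list(obj[[key]]) || is.vector(obj[[key]]),
                 object = is.list(obj[[key]]),
                 TRUE)
    if (!ok) {
      stop("report key '", key, "' is not of schema type '", want, "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
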