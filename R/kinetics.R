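#' Velocity series container
#'
#' Initial-velocity measurements over substrate, enzyme and inhibitor
#' grids. Velocities are absorbance-rate based (1/min); no molar
#' conversion via the p-nitrophenol extinction coefficient is attempted.
#'
#' @param df Data frame with columns `substrate_conc_mg_ml`,
#'   `enzyme_conc_mg_ml`, `inhibitor_conc_mg_ml`, `velocity_per_min`.
#' @return The validated data frame with class `velocity_series`.
#' @export
velocity_series <- function(df) {
  req <- c("substrate_conc_mg_ml", "enzyme_conc_mg_ml",
           "inhibitor_conc_mg_ml", "velocity_per_min")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("velocity series is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$velocity_per_min < 0)) {
    stop("velocities must be >= 0", call. = FALSE)
  }
  class(df) <- unique(c("velocity_series", class(df)))
  df
}

#' Inhibition-type plot: velocity versus enzyme concentration
#'
#' Fits one least-squares line of velocity on enzyme concentration per
#' inhibitor dose (at fixed substrate). The geometry of this family of
#' lines diagnoses reversibility: lines through the origin whose slope
#' falls with dose indicate a reversible inhibitor; parallel lines
#' displaced downward indicate irreversible enzyme inactivation.
#'
#' @param vs A [velocity_series()] with >= 3 enzyme concentrations per
#'   inhibitor dose and a single substrate concentration.
#' @return Object of class `type_plot`: a data frame with one row per
#'   dose (`inhibitor_conc_mg_ml`, `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `r2`), carrying the enzyme range as an attribute.
#' @export
fit_type_plot <- function(vs) {
  stopifnot(inherits(vs, "velocity_series"))
  if (length(unique(vs$substrate_conc_mg_ml)) != 1) {
    stop("type plot requires a single fixed substrate concentration",
         call. = FALSE)
  }
  rows <- lapply(split(vs, vs$inhibitor_conc_mg_ml), function(g) {
    if (length(unique(g$enzyme_conc_mg_ml)) < 3) {
      stop("insufficient data: need >= 3 enzyme concentrations per dose",
           call. = FALSE)
    }
    fit <- lm(velocity_per_min ~ enzyme_conc_mg_ml, data = g)
    s <- suppressWarnings(summary(fit))$coefficients
    data.frame(inhibitor_conc_mg_ml = g$inhibitor_conc_mg_ml[1],
               slope = s["enzyme_conc_mg_ml", "Estimate"],
               slope_se = s["enzyme_conc_mg_ml", "Std. Error"],
               intercept = s["(Intercept)", "Estimate"],
               intercept_se = s["(Intercept)", "Std. Error"],
               r2 = suppressWarnings(summary(fit))$r.squared)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$inhibitor_conc_mg_ml), ]
  rownames(out) <- NULL
  attr(out, "enzyme_range") <- range(vs$enzyme_conc_mg_ml)
  class(out) <- c("type_plot", "data.frame")
  out
}

#' Construct a type plot from known line parameters
#'
#' Convenience constructor for diagnostics already summarised as lines
#' (one per inhibitor dose).
#'
#' @param inhibitor_conc_mg_ml Dose per line, mg/mL.
#' @param slope,intercept Line parameters (velocity per enzyme mg/mL;
#'   velocity units).
#' @param enzyme_range Length-2 enzyme-concentration range the lines were
#'   fitted over (sets the scale for the intercept-zero test).
#' @return A `type_plot` object.
#' @export
type_plot <- function(inhibitor_conc_mg_ml, slope, intercept,
                      enzyme_range = c(5, 20)) {
  out <- data.frame(inhibitor_conc_mg_ml = inhibitor_conc_mg_ml,
                    slope = slope, slope_se = NA_real_,
                    intercept = intercept, intercept_se = NA_real_,
                    r2 = NA_real_)
  out <- out[order(out$inhibitor_conc_mg_ml), ]
  rownames(out) <- NULL
  attr(out, "enzyme_range") <- enzyme_range
  class(out) <- c("type_plot", "data.frame")
  out
}

#' Classify inhibitor reversibility from the type plot
#'
#' Reversible if every line passes through the origin (intercept within
#' `tol` of zero, on the scale of the largest fitted velocity) and the
#' slopes strictly decrease with dose; otherwise irreversible (the
#' parallel-lines-with-negative-intercept pattern of enzyme
#' inactivation). Non-monotone slopes give an explicit `"indeterminate"`.
#'
#' @param tp A [fit_type_plot()] or [type_plot()] result with >= 2 doses.
#' @param tol Relative tolerance for "intercept is zero" and for calling
#'   a slope change real.
#' @return One of `"reversible"`, `"irreversible"`, `"indeterminate"`.
#' @export
classify_reversibility <- function(tp, tol = 0.05) {
  stopifnot(inherits(tp, "type_plot"))
  if (nrow(tp) < 2) {
    stop("need >= 2 inhibitor doses to classify reversibility",
         call. = FALSE)
  }
  e_max <- max(attr(tp, "enzyme_range"))
  v_scale <- max(abs(tp$slope * e_max + tp$intercept))
  s_scale <- max(abs(tp$slope))
  d <- diff(tp$slope)
  if (any(d > tol * s_scale)) return("indeterminate")
  # a real dose effect: overall decline beyond tol, no step increasing
  slopes_decreasing <- (tp$slope[1] - tp$slope[nrow(tp)]) > tol * s_scale
  intercepts_zero <- all(abs(tp$intercept) <= tol * v_scale)
  if (intercepts_zero && slopes_decreasing) "reversible" else "irreversible"
}

#' Lineweaver-Burk double-reciprocal analysis
#'
#' Per inhibitor dose, fits `1/V` on `1/[S]` by unweighted least squares.
#' Vmax is taken as the inverse of the mean 1/V-axis intercept across
#' doses (competitive inhibition predicts a shared intercept), apparent
#' Km per dose as `slope * Vmax`, and Ki from the linear relation
#' `Km_app = Km * (1 + [I]/Ki)` fitted across doses. The verdict follows
#' the classical pattern:
#' * apparent Km rises with dose, Vmax unchanged — **competitive**;
#' * Vmax falls, Km unchanged — **noncompetitive**;
#' * Km and Vmax fall by the same factor (parallel reciprocal lines) —
#'   **uncompetitive**;
#' * anything else (both move, inconsistently) — **mixed**, never a
#'   silent competitive call.
#'
#' Zero velocities are excluded with a warning (their reciprocal is
#' undefined).
#'
#' @param vs A [velocity_series()] with >= 4 substrate concentrations per
#'   dose.
#' @param vmax_tol Relative tolerance on Vmax (and Km) constancy used by
#'   the verdict.
#' @return Object of class `kinetic_fit`: list with `Km` (mg/mL), `Vmax`
#'   (1/min), `Km_app_by_I`, `Vmax_by_I`, `Ki` (mg/mL), `verdict`,
#'   `reversibility` (filled in by the pipeline from the type plot,
#'   otherwise `NA`), and `r2_by_line`.
#' @export
lineweaver_burk <- function(vs, vmax_tol = 0.05) {
  stopifnot(inherits(vs, "velocity_series"))
  if (any(vs$velocity_per_min == 0)) {
    warning("excluding ", sum(vs$velocity_per_min == 0),
            " zero-velocity point(s) from the reciprocal fit",
            call. = FALSE)
    vs <- vs[vs$velocity_per_min > 0, ]
  }
  per_dose <- lapply(split(vs, vs$inhibitor_conc_mg_ml), function(g) {
    if (length(unique(g$substrate_conc_mg_ml)) < 4) {
      stop("insufficient data: need >= 4 substrate concentrations per ",
           "inhibitor dose", call. = FALSE)
    }
    inv_v <- 1 / g$velocity_per_min
    inv_s <- 1 / g$substrate_conc_mg_ml
    fit <- lm(inv_v ~ inv_s)
    c(I = g$inhibitor_conc_mg_ml[1],
      slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
      r2 = suppressWarnings(summary(fit))$r.squared)
  })
  lines <- as.data.frame(do.call(rbind, per_dose))
  lines <- lines[order(lines$I), ]
  if (any(lines$intercept <= 0)) {
    stop("non-positive 1/V-axis intercept; Lineweaver-Burk fit is ",
         "degenerate", call. = FALSE)
  }
  Vmax <- 1 / mean(lines$intercept)
  Vmax_by_I <- setNames(1 / lines$intercept, lines$I)
  # per-dose Km_app uses each line's own intercept (slope/intercept =
  # slope * Vmax_dose); with a shared intercept this equals slope * Vmax,
  # and it stays meaningful when the intercepts differ (non-competitive
  # patterns)
  Km_app <- setNames(lines$slope / lines$intercept, lines$I)

  verdict <- lb_verdict(lines$I, Km_app, Vmax_by_I, lines$slope, vmax_tol)

  has_zero <- any(lines$I == 0)
  Ki <- NA_real_
  Km <- if (has_zero) Km_app[[as.character(0)]] else NA_real_
  if (length(unique(lines$I)) >= 2 && any(lines$I > 0)) {
    kfit <- lm(Km_app ~ I, data = data.frame(I = lines$I, Km_app = Km_app))
    b <- coef(kfit)
    if (!has_zero) Km <- b[[1]]
    if (b[[2]] > 0 && b[[1]] > 0) Ki <- b[[1]] / b[[2]]
  }

  structure(
    list(Km = Km, Vmax = Vmax,
         Km_app_by_I = Km_app, Vmax_by_I = Vmax_by_I,
         Ki = Ki, verdict = verdict,
         reversibility = NA_character_,
         r2_by_line = setNames(lines$r2, lines$I),
         lines = lines, vmax_tol = vmax_tol),
    class = "kinetic_fit"
  )
}

# classical Lineweaver-Burk pattern matching. "Change across [I]" is
# the dose-attributable trend — the fitted linear change of each
# quantity over the dose range, relative to its mean — so per-dose
# estimation noise averages out instead of being read as a pattern.
lb_verdict <- function(I, Km_app, Vmax_by_I, slopes, tol) {
  if (length(I) < 2 || all(I == I[1])) return(NA_character_)
  trend <- function(y) {
    b <- coef(lm(y ~ I))[[2]]
    b * (max(I) - min(I)) / mean(y)
  }
  d_vmax <- trend(Vmax_by_I)
  d_km <- trend(Km_app)
  d_slope <- trend(slopes)
  vmax_const <- abs(d_vmax) < tol
  km_const <- abs(d_km) < tol
  slopes_const <- abs(d_slope) < tol
  if (vmax_const && d_km > tol) {
    "competitive"
  } else if (d_vmax < -tol && km_const) {
    "noncompetitive"
  } else if (d_vmax < -tol && d_km < -tol && slopes_const) {
    "uncompetitive"
  } else {
    "mixed"
  }
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Lineweaver-Burk kinetic fit\n")
  cat(sprintf("  Vmax: %.4g /min   Km: %.4g mg/mL   Ki: %.4g mg/mL\n",
              x$Vmax, x$Km, x$Ki))
  cat("  verdict:", x$verdict,
      if (!is.na(x$reversibility)) paste0("(", x$reversibility, ")") else "",
      "\n")
  cat("  apparent Km by dose (mg/mL):\n")
  print(round(x$Km_app_by_I, 4))
  invisible(x)
}

#' Direct nonlinear Michaelis-Menten fit
#'
#' Fits `V = Vmax * S / (Km_app + S)` per inhibitor dose by
#' Levenberg-Marquardt nonlinear least squares, with self-starting
#' initial values (`Vmax` from the largest observed velocity, `Km` from
#' the substrate concentration nearest half-maximal velocity). This is
#' the recommended estimator; the reciprocal-space fit is kept for parity
#' with the classical plots, and on noiseless data the two agree to
#' machine precision.
#'
#' @param vs A [velocity_series()].
#' @return List with `Km_app_by_I`, `Vmax_by_I`, and pooled `Vmax`
#'   (mean across doses) and `Km` (apparent Km at zero dose when present).
#' @export
michaelis_menten_fit <- function(vs) {
  stopifnot(inherits(vs, "velocity_series"))
  vs <- vs[vs$velocity_per_min > 0, ]
  per_dose <- lapply(split(vs, vs$inhibitor_conc_mg_ml), function(g) {
    vmax0 <- max(g$velocity_per_min) * 1.5
    km0 <- g$substrate_conc_mg_ml[
      which.min(abs(g$velocity_per_min - vmax0 / 3))]
    fit <- minpack.lm::nlsLM(
      velocity_per_min ~ Vmax * substrate_conc_mg_ml /
        (Km + substrate_conc_mg_ml),
      data = g, start = list(Vmax = vmax0, Km = km0),
      lower = c(Vmax = 1e-12, Km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    c(I = g$inhibitor_conc_mg_ml[1], coef(fit))
  })
  est <- as.data.frame(do.call(rbind, per_dose))
  est <- est[order(est$I), ]
  Km_app <- setNames(est$Km, est$I)
  Vmax_by_I <- setNames(est$Vmax, est$I)
  list(Km_app_by_I = Km_app,
       Vmax_by_I = Vmax_by_I,
       Vmax = mean(est$Vmax),
       Km = if (any(est$I == 0)) Km_app[[as.character(0)]] else NA_real_)
}
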