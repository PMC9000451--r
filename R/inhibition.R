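#' Plate assay container
#'
#' Long-format endpoint absorbances from a chromogenic microplate assay.
#' Each (inhibitor dose, replicate) group carries four wells, following the
#' standard blank layout:
#' * `A` — control blank (buffer, no enzyme, no inhibitor),
#' * `a` — uninhibited reaction (enzyme, no inhibitor),
#' * `B` — sample blank (inhibitor, no enzyme),
#' * `b` — sample (enzyme + inhibitor).
#'
#' @param df A data frame with columns `sample_id`,
#'   `inhibitor_conc_mg_ml`, `replicate`, `role` (one of `A`, `a`, `B`,
#'   `b`) and `absorbance`.
#' @return The validated data frame with class `plate_assay`.
#' @export
plate_assay <- function(df) {
  req <- c("sample_id", "inhibitor_conc_mg_ml", "replicate", "role",
           "absorbance")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("plate assay is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$role %in% c("A", "a", "B", "b"))) {
    stop("'role' must be one of A, a, B, b", call. = FALSE)
  }
  if (any(df$absorbance < 0)) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  wide <- plate_to_wide(df)
  if (any(wide$a - wide$A <= 0)) {
    stop("degenerate control: every group needs a > A ",
         "(positive uninhibited signal)", call. = FALSE)
  }
  class(df) <- unique(c("plate_assay", class(df)))
  df
}

# one row per (sample, dose, replicate) with columns A, a, B, b
plate_to_wide <- function(df) {
  key <- interaction(df$sample_id, df$inhibitor_conc_mg_ml, df$replicate,
                     drop = TRUE)
  groups <- split(df, key)
  rows <- lapply(groups, function(g) {
    if (anyDuplicated(g$role) || nrow(g) != 4L) {
      stop("each (sample, dose, replicate) group needs exactly one well ",
           "per role A, a, B, b", call. = FALSE)
    }
    ab <- setNames(g$absorbance, g$role)
    data.frame(sample_id = g$sample_id[1],
               inhibitor_conc_mg_ml = g$inhibitor_conc_mg_ml[1],
               replicate = g$replicate[1],
               A = ab[["A"]], a = ab[["a"]], B = ab[["B"]], b = ab[["b"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$inhibitor_conc_mg_ml, out$replicate), ]
}

#' Blank-corrected inhibition rate
#'
#' Percent inhibition from the four well absorbances:
#' `100 * (1 - (b - B) / (a - A))`, where `a - A` is the blank-corrected
#' uninhibited signal and `b - B` the blank-corrected signal in the
#' presence of inhibitor. Raw noisy rates may fall outside `[0, 100]`;
#' clamping is an aggregation policy, not done here.
#'
#' @param A Control-blank absorbance.
#' @param a Uninhibited-reaction absorbance.
#' @param B Sample-blank absorbance (no enzyme).
#' @param b Sample absorbance.
#' @return Inhibition rate in percent. Vectorised.
#' @export
#' @examples
#' inhibition_rate(A = 0.10, a = 0.90, B = 0.12, b = 0.52)  # 50
inhibition_rate <- function(A, a, B, b) {
  if (any(a - A <= 0)) {
    stop("degenerate control: a - A must be > 0 ",
         "(the uninhibited reaction produced no signal)", call. = FALSE)
  }
  100 * (1 - (b - B) / (a - A))
}

#' Aggregate a plate assay into a dose-response table
#'
#' Computes the per-replicate inhibition rate for every dose, clamps raw
#' replicate rates into `[0, 100]`\% (plate noise can push individual wells
#' outside the physical range), and reports the per-dose mean, sample SD
#' and replicate count. The zero-dose point is retained as a QC anchor.
#'
#' @param assay A [plate_assay()].
#' @param clamp Length-2 clamp for raw replicate rates, percent.
#' @return A data frame of class `dose_response` with columns
#'   `conc_mg_ml`, `mean_inhibition_pct`, `sd_pct`, `n_rep`.
#' @export
aggregate_dose_response <- function(assay, clamp = c(0, 100)) {
  stopifnot(inherits(assay, "plate_assay"), length(clamp) == 2)
  wide <- plate_to_wide(assay)
  wide$rate <- inhibition_rate(wide$A, wide$a, wide$B, wide$b)
  wide$rate <- pmin(pmax(wide$rate, clamp[1]), clamp[2])
  agg <- lapply(split(wide, wide$inhibitor_conc_mg_ml), function(g) {
    data.frame(conc_mg_ml = g$inhibitor_conc_mg_ml[1],
               mean_inhibition_pct = mean(g$rate),
               sd_pct = if (nrow(g) > 1) sd(g$rate) else NA_real_,
               n_rep = nrow(g))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$conc_mg_ml), ]
  rownames(out) <- NULL
  class(out) <- c("dose_response", "data.frame")
  out
}

#' IC50 by probit regression
#'
#' Linear least squares of `qnorm(p)` (the probit of the mean inhibition
#' fraction) on `log10(concentration)`. The IC50 is the concentration at
#' which the fitted probit crosses 0 (50\% inhibition):
#' `IC50 = 10^(-intercept/slope)`. A 95\% confidence interval is obtained
#' by the delta method on `log10(IC50)`. Fractions are clamped to
#' `clamp_margin` before the probit transform (the probit is undefined at
#' exactly 0 or 1). The zero-dose anchor is excluded (log of 0).
#'
#' @param dr A [aggregate_dose_response()] table.
#' @param clamp_margin Length-2 clamp for mean inhibition before the
#'   probit transform, percent.
#' @return An object of class `ic50_fit`: list with `ic50` (mg/mL),
#'   `slope` (probit per log10 mg/mL), `intercept`, `ci95` (mg/mL),
#'   `r2`, `n_points`, `extrapolated` (TRUE when all doses sit on one side
#'   of 50\%), and the underlying `lm` fit as `model`.
#' @export
fit_ic50 <- function(dr, clamp_margin = c(0.5, 99.5)) {
  stopifnot(inherits(dr, "dose_response") || is.data.frame(dr))
  pts <- dr[dr$conc_mg_ml > 0, ]
  if (nrow(pts) < 2) {
    stop("insufficient data: need at least 2 doses with positive ",
         "concentration for the probit fit", call. = FALSE)
  }
  if (nrow(pts) < 3) {
    warning("fewer than 3 usable doses; IC50 is an interpolation from ",
            "a two-point line", call. = FALSE)
  }
  p <- pmin(pmax(pts$mean_inhibition_pct, clamp_margin[1]),
            clamp_margin[2]) / 100
  probit <- qnorm(p)
  x <- log10(pts$conc_mg_ml)
  fit <- lm(probit ~ x)
  b <- coef(fit)
  if (!is.finite(b[2]) || b[2] == 0) {
    stop("probit fit has zero slope; IC50 undefined", call. = FALSE)
  }
  l10 <- -b[[1]] / b[[2]]
  grad <- c(-1 / b[[2]], b[[1]] / b[[2]]^2)
  V <- suppressWarnings(vcov(fit))
  se_l10 <- sqrt(drop(t(grad) %*% V %*% grad))
  ci <- 10^(l10 + c(-1, 1) * qnorm(0.975) * se_l10)
  extrapolated <- all(probit > 0) || all(probit < 0)
  if (extrapolated) {
    warning("all doses lie on one side of 50% inhibition; ",
            "IC50 is an extrapolation", call. = FALSE)
  }
  structure(
    list(ic50 = 10^l10,
         slope = b[[2]],
         intercept = b[[1]],
         ci95 = ci,
         r2 = suppressWarnings(summary(fit))$r.squared,
         n_points = nrow(pts),
         extrapolated = extrapolated,
         model = fit),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 fit (probit regression, %d doses)\n", x$n_points))
  cat(sprintf("  IC50: %.4g mg/mL   95%% CI [%.4g, %.4g]\n",
              x$ic50, x$ci95[1], x$ci95[2]))
  cat(sprintf("  slope: %.4g probit/log10(mg/mL)   R^2: %.4f\n",
              x$slope, x$r2))
  if (isTRUE(x$extrapolated)) cat("  note: extrapolated beyond the dose range\n")
  invisible(x)
}
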