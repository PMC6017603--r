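# Steady-state SPR analysis: blank subtraction, equilibrium extraction,
# one-site Langmuir fitting with Scatchard initialisation, RU-to-density
# conversion, and competition metrics.

#' Subtract a reference (blank) sensorgram from an active one
#'
#' Pointwise difference on the active trace's time grid; the reference is
#' linearly interpolated when the grids differ.  The reference must cover
#' the active time range (no extrapolation).
#'
#' @param active,reference [sensorgram()] objects.
#' @return A blank-subtracted [sensorgram()] on the active grid.
#' @export
blank_subtract <- function(active, reference) {
  stopifnot(inherits(active, "sensorgram"), inherits(reference, "sensorgram"))
  rng <- range(reference$time_s)
  if (active$time_s[1] < rng[1] ||
      active$time_s[length(active$time_s)] > rng[2]) {
    stop("reference trace does not cover the active time range")
  }
  ref_interp <- approx(reference$time_s, reference$response_RU,
                       xout = active$time_s)$y
  sensorgram(active$time_s, active$response_RU - ref_interp,
             active$injection_start_s, active$injection_end_s,
             label = paste0(active$label, " - ", reference$label))
}

#' Extract the equilibrium response from a sensorgram
#'
#' Mean response over the final `window_fraction` of the injection
#' phase.  A non-plateau flag is set when the fitted linear slope over
#' that window changes the response by more than `plateau_tol` (relative
#' to the window mean) across the window.
#'
#' @param s a [sensorgram()].
#' @param window_fraction final fraction of the injection used
#'   (default 0.1).
#' @param plateau_tol relative drift across the window above which the
#'   trace is flagged as not at equilibrium (default 0.02).
#' @return List of class `req_estimate`: `Req_RU`, `plateau` (logical),
#'   `window_s` (start/end of the averaging window), `slope_RU_per_s`.
#' @export
extract_equilibrium <- function(s, window_fraction = 0.1,
                                plateau_tol = 0.02) {
  stopifnot(inherits(s, "sensorgram"),
            window_fraction > 0, window_fraction <= 1)
  w0 <- s$injection_end_s -
    window_fraction * (s$injection_end_s - s$injection_start_s)
  idx <- which(s$time_s >= w0 & s$time_s <= s$injection_end_s)
  if (length(idx) < 2L) stop("equilibrium window contains <2 samples")
  t <- s$time_s[idx]; r <- s$response_RU[idx]
  req <- mean(r)
  slope <- unname(coef(lm(r ~ t))[2])
  drift <- abs(slope) * (max(t) - min(t))
  plateau <- drift <= plateau_tol * max(abs(req), 1e-12)
  structure(list(Req_RU = req, plateau = plateau,
                 window_s = c(w0, s$injection_end_s),
                 slope_RU_per_s = slope),
            class = "req_estimate")
}

# Scatchard linearisation Req/C = Bmax/Kd - Req/Kd -> starting values.
.scatchard_start <- function(conc, req) {
  pos <- req > 0
  if (sum(pos) >= 2L) {
    fit <- lm(I(req[pos] / conc[pos]) ~ req[pos])
    slope <- coef(fit)[2]; icpt <- coef(fit)[1]
    if (is.finite(slope) && slope < 0 && icpt > 0) {
      kd <- -1 / slope
      return(c(Bmax = unname(icpt * kd), Kd = unname(kd)))
    }
  }
  # fall back on a curve-free heuristic for degenerate Scatchard plots
  c(Bmax = max(req) * 2, Kd = median(conc))
}

#' Fit a one-site steady-state binding isotherm
#'
#' Nonlinear least squares of the Langmuir hyperbola
#' `Req = Bmax * C / (Kd + C)`, with starting values from the Scatchard
#' linearisation (`Req/C` vs `Req`).  The fit is declared saturable when
#' the highest concentration reaches at least `saturation_factor * Kd`;
#' otherwise the Kd is reported as presumed (extrapolated from the
#' curve's trend).
#'
#' @param iso an [isotherm()] with at least 3 concentrations.
#' @param saturation_factor multiple of Kd the top concentration must
#'   reach for the design to count as saturating (default 2).
#' @return List of class `spr_fit`: `Kd_M`, `Bmax_RU`, `Kd_se`,
#'   `Bmax_se`, `rss`, `saturable`, `presumed` (= !saturable), `n`,
#'   `ligand`.
#' @export
fit_steady_state <- function(iso, saturation_factor = 2) {
  stopifnot(inherits(iso, "isotherm"))
  conc <- iso$concentration_M; req <- iso$Req_RU
  if (length(conc) < 3L) stop("isotherm fitting needs >= 3 concentrations")
  start <- .scatchard_start(conc, req)
  start <- pmax(start, c(Bmax = 1e-9, Kd = 1e-12))
  fit <- tryCatch(
    minpack.lm::nlsLM(req ~ Bmax * conc / (Kd + conc),
                      start = as.list(start),
                      lower = c(Bmax = 0, Kd = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) {
      stop("steady-state fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
    })
  est <- coef(fit)
  if (any(!is.finite(est)) || any(est <= 0)) {
    stop("steady-state fit produced non-positive parameters")
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Bmax = NA_real_, Kd = NA_real_))
  saturable <- max(conc) >= saturation_factor * est[["Kd"]]
  structure(list(Kd_M = est[["Kd"]], Bmax_RU = est[["Bmax"]],
                 Kd_se = unname(se["Kd"]), Bmax_se = unname(se["Bmax"]),
                 rss = sum(stats::resid(fit)^2),
                 saturable = saturable, presumed = !saturable,
                 n = length(conc), ligand = iso$ligand),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf("<spr_fit> %s: Kd = %.4g M (se %.2g), Bmax = %.4g RU (se %.2g), %s\n",
              x$ligand, x$Kd_M, x$Kd_se, x$Bmax_RU, x$Bmax_se,
              if (x$saturable) "saturable" else "presumed (non-saturating)"))
  invisible(x)
}

#' Predict the fitted isotherm
#' @param object an `spr_fit`.
#' @param concentration_M concentrations (M) to evaluate.
#' @param ... unused.
#' @return Predicted Req (RU).
#' @export
predict.spr_fit <- function(object, concentration_M, ...) {
  object$Bmax_RU * concentration_M / (object$Kd_M + concentration_M)
}

#' Convert an immobilisation level to a molar surface density
#'
#' Uses the standard carboxymethyl-dextran chip convention
#' 1 RU = 1 pg/mm^2: density (fmol/mm^2) is the mass density in pg/mm^2
#' divided by the molar mass in g/mol, with unit factors applied.
#'
#' @param RU immobilised response (resonance units, >= 0).
#' @param molar_mass_Da molar mass of the immobilised species (Da, > 0).
#' @return Surface density in fmol/mm^2.
#' @export
ru_to_density <- function(RU, molar_mass_Da) {
  if (any(RU < 0)) stop("RU must be non-negative")
  if (any(molar_mass_Da <= 0)) stop("molar mass must be positive")
  # RU pg/mm^2 -> g/mm^2 (1e-12) -> mol/mm^2 (/M) -> fmol/mm^2 (1e15)
  RU * 1e-12 / molar_mass_Da * 1e15
}

#' Competition / enhancement metric for paired equilibrium responses
#'
#' Signed percent change of the equilibrium response in the presence of
#' a competitor relative to the analyte alone; negative values mean
#' inhibition, positive enhancement.
#'
#' @param Req_alone equilibrium response of the analyte alone (RU, > 0).
#' @param Req_mix equilibrium response in the mixture (RU).
#' @return List of class `competition_result`: `Req_alone_RU`,
#'   `Req_mix_RU`, `percent_change`.
#' @export
competition_metrics <- function(Req_alone, Req_mix) {
  if (!is.finite(Req_alone) || Req_alone <= 0) {
    stop("Req_alone must be positive")
  }
  structure(list(Req_alone_RU = Req_alone, Req_mix_RU = Req_mix,
                 percent_change = 100 * (Req_mix - Req_alone) / Req_alone),
            class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  verb <- if (x$percent_change < 0) "inhibition" else "enhancement"
  cat(sprintf("<competition_result> %.4g -> %.4g RU: %+.1f%% (%s)\n",
              x$Req_alone_RU, x$Req_mix_RU, x$percent_change, verb))
  invisible(x)
}
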