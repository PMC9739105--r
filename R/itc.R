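# Wiseman one-set-of-sites ITC model with standard perfusion-cell
# bookkeeping. Each injection of volume v displaces cell contents, so after
# cumulative injected volume dV the cell macromolecule concentration is
# M = M0 (1 - dV/2V0) / (1 + dV/2V0) and the total titrant concentration is
# X = X0 (dV/V0) / (1 + dV/2V0). The bound fraction Theta solves
#   Theta^2 - Theta (1 + X/NM + 1/(N Ka M)) + X/(NM) = 0
# (physical root in [0,1]); cell heat content Q = N Theta M dH V0 and the
# measured injection heat is the Q increment plus the displaced-volume
# correction q_i = Q_i - Q_{i-1} + (v_i/V0)(Q_i + Q_{i-1})/2. Heats are in
# microjoules throughout.

.R_GAS <- 8.314  # J/mol/K

#' ITC injection schedule
#'
#' @param cell_conc Macromolecule concentration in the cell (uM).
#' @param syringe_conc Titrant concentration in the syringe (uM).
#' @param inj_volumes Injection volumes (uL), non-empty.
#' @param cell_volume Active cell volume (uL). Default 200 uL, the working
#'   volume of modern low-volume calorimeters.
#' @param temperature Temperature (K). Default 293.15 K (20 C).
#' @return Object of class `itc_schedule`.
#' @examples
#' itc_schedule()  # 55 uM tubulin cell, 2.2 mM peptide syringe, 19 x 2 uL
#' @export
itc_schedule <- function(cell_conc = 55, syringe_conc = 2200,
                         inj_volumes = rep(2, 19), cell_volume = 200,
                         temperature = 293.15) {
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0 ||
      temperature <= 0)
    stop("concentrations, volumes and temperature must be > 0")
  if (!length(inj_volumes) || any(inj_volumes <= 0))
    stop("'inj_volumes' must be a non-empty vector of positive volumes")
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 inj_volumes = as.numeric(inj_volumes),
                 cell_volume = cell_volume, temperature = temperature),
            class = "itc_schedule")
}

#' @export
print.itc_schedule <- function(x, ...) {
  cat(sprintf("<itc_schedule> cell %g uM (%g uL), syringe %g uM, %d injection(s), T = %g K\n",
              x$cell_conc, x$cell_volume, x$syringe_conc,
              length(x$inj_volumes), x$temperature))
  invisible(x)
}

#' Derive Gibbs energy, entropy and Kd from (Ka, dH, T)
#'
#' Standard thermodynamic relations: `dG = -R T ln(Ka)`,
#' `dS = (dH - dG) / T`, `Kd = 1 / Ka`.
#'
#' @param Ka Association constant (1/M, > 0).
#' @param dH Binding enthalpy (kJ/mol).
#' @param T Temperature (K, > 0).
#' @return List with `dG` (kJ/mol), `dS` (J/mol/K), `Kd` (M).
#' @examples
#' derive_thermodynamics(Ka = 1 / 5.3e-6, dH = -40)$dG  # about -29.6 kJ/mol
#' @export
derive_thermodynamics <- function(Ka, dH, T = 293.15) {
  if (Ka <= 0 || T <= 0) stop("'Ka' and 'T' must be > 0")
  dG <- -.R_GAS * T * log(Ka) / 1000            # kJ/mol
  dS <- (dH - dG) * 1000 / T                    # J/mol/K
  list(dG = dG, dS = dS, Kd = 1 / Ka)
}

#' One-set-of-sites binding parameters
#'
#' @param N Binding stoichiometry (sites per macromolecule, > 0).
#' @param Ka Association constant (1/M, > 0).
#' @param dH Binding enthalpy (kJ/mol).
#' @param T Temperature (K).
#' @return Object of class `binding_params` with derived `dG` (kJ/mol),
#'   `dS` (J/mol/K) and `Kd` (M).
#' @examples
#' binding_params(N = 2, Ka = 1 / 5.3e-6, dH = -40)
#' @export
binding_params <- function(N, Ka, dH, T = 293.15) {
  if (N <= 0) stop("'N' must be > 0")
  thermo <- derive_thermodynamics(Ka, dH, T)
  structure(list(N = N, Ka = Ka, dH = dH, T = T,
                 dG = thermo$dG, dS = thermo$dS, Kd = thermo$Kd),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("<binding_params> N = %.3g, Kd = %.3g M (Ka = %.3g 1/M)\n",
              x$N, x$Kd, x$Ka))
  cat(sprintf("  dH = %.2f kJ/mol, dG = %.2f kJ/mol, dS = %.2f J/mol/K at %g K\n",
              x$dH, x$dG, x$dS, x$T))
  invisible(x)
}

#' Predicted per-injection heats under the one-set-of-sites model
#'
#' @param params A [binding_params()] object.
#' @param schedule An [itc_schedule()] object.
#' @return Numeric vector of per-injection heats (uJ), one per injection.
#' @export
predict_heats <- function(params, schedule) {
  if (!inherits(params, "binding_params"))
    stop("'params' must be a binding_params object")
  if (!inherits(schedule, "itc_schedule"))
    stop("'schedule' must be an itc_schedule object")
  .predict_heats_raw(params$N, params$Ka, params$dH, schedule)
}

.predict_heats_raw <- function(N, Ka, dH, schedule) {
  v0 <- schedule$cell_volume * 1e-6            # L
  m0 <- schedule$cell_conc * 1e-6              # M
  x0 <- schedule$syringe_conc * 1e-6           # M
  v <- schedule$inj_volumes * 1e-6             # L
  dv <- cumsum(v)
  m_i <- m0 * (1 - dv / (2 * v0)) / (1 + dv / (2 * v0))
  x_i <- x0 * (dv / v0) / (1 + dv / (2 * v0))
  b <- 1 + x_i / (N * m_i) + 1 / (N * Ka * m_i)
  disc <- b^2 - 4 * x_i / (N * m_i)
  if (any(disc < 0))
    stop("one-site quadratic has no physical root; inconsistent inputs")
  theta <- (b - sqrt(disc)) / 2
  q_cell <- N * theta * m_i * (dH * 1000) * v0  # J
  q_prev <- c(0, q_cell[-length(q_cell)])
  q_inj <- q_cell - q_prev + (v / v0) * (q_cell + q_prev) / 2
  q_inj * 1e6                                   # uJ
}

#' Assemble an ITC titration
#'
#' @param schedule An [itc_schedule()] object.
#' @param heats Per-injection heats (uJ), same length as the schedule.
#' @param blank_heats Optional per-injection dilution heats (uJ).
#' @return Object of class `itc_titration`.
#' @export
itc_titration <- function(schedule, heats, blank_heats = NULL) {
  if (!inherits(schedule, "itc_schedule"))
    stop("'schedule' must be an itc_schedule object")
  if (length(heats) != length(schedule$inj_volumes))
    stop("'heats' must have one value per injection")
  if (!is.null(blank_heats) && length(blank_heats) != length(heats))
    stop("'blank_heats' must match 'heats' in length")
  structure(list(schedule = schedule, heats = as.numeric(heats),
                 blank_heats = if (is.null(blank_heats)) NULL
                 else as.numeric(blank_heats)),
            class = "itc_titration")
}

#' @export
print.itc_titration <- function(x, ...) {
  cat(sprintf("<itc_titration> %d injection(s)%s, heat range [%.3g, %.3g] uJ\n",
              length(x$heats),
              if (is.null(x$blank_heats)) "" else " (+blank)",
              min(x$heats), max(x$heats)))
  invisible(x)
}

#' Subtract dilution (blank) heats from a titration
#'
#' @param titration An [itc_titration()] object.
#' @param blank Optional per-injection blank heats (uJ); defaults to the
#'   titration's own `blank_heats`.
#' @param constant Alternative constant dilution-heat offset (uJ).
#' @return Blank-corrected `itc_titration` (with `blank_heats` cleared and
#'   the correction recorded in attribute `"blank_correction"`).
#' @export
subtract_blank <- function(titration, blank = NULL, constant = NULL) {
  if (!inherits(titration, "itc_titration"))
    stop("'titration' must be an itc_titration object")
  if (is.null(blank) && is.null(constant)) blank <- titration$blank_heats
  if (is.null(blank) && is.null(constant))
    stop("no blank heats available: supply 'blank' or 'constant'")
  corr <- if (!is.null(blank)) {
    if (length(blank) != length(titration$heats))
      stop("blank length does not match the number of injections")
    as.numeric(blank)
  } else rep(as.numeric(constant), length(titration$heats))
  out <- itc_titration(titration$schedule, titration$heats - corr)
  attr(out, "blank_correction") <- corr
  out
}

# molar ratio (total ligand / total macromolecule in cell) per injection
.molar_ratio <- function(schedule) {
  v0 <- schedule$cell_volume
  dv <- cumsum(schedule$inj_volumes)
  m_i <- schedule$cell_conc * (1 - dv / (2 * v0)) / (1 + dv / (2 * v0))
  x_i <- schedule$syringe_conc * (dv / v0) / (1 + dv / (2 * v0))
  x_i / m_i
}

#' Fit the one-set-of-sites model to a titration
#'
#' Least-squares fit of (N, Ka, dH) against [predict_heats()], using
#' Levenberg-Marquardt with a multi-start grid (Ka from 1e3 to 1e8 1/M,
#' N from 0.5 to 4) because single-site fits are multimodal at low c-value.
#' Blank heats, if present, are subtracted first. Reports asymptotic
#' standard errors and derived thermodynamics; the c-value
#' (N Ka [macromolecule]) is flagged when outside the well-identified
#' window [1, 1000].
#'
#' @param titration An [itc_titration()] object.
#' @param skip_first Drop the first injection (common ITC practice for the
#'   pre-injection artifact)? Default `FALSE`.
#' @param start Optional named list `(N, Ka, dH)` used as the only start.
#' @return Object of class `itc_fit`; see [coef.itc_fit()],
#'   [predict.itc_fit()], [plot.itc_fit()].
#' @export
fit_one_site <- function(titration, skip_first = FALSE, start = NULL) {
  if (!inherits(titration, "itc_titration"))
    stop("'titration' must be an itc_titration object")
  if (!is.null(titration$blank_heats))
    titration <- subtract_blank(titration)
  sch <- titration$schedule
  q <- titration$heats
  keep <- seq_along(q)
  if (skip_first) keep <- keep[-1L]
  if (length(keep) < 5L)
    stop("need at least 5 informative injections to fit")

  qs <- q[keep]

  model <- function(N, lKa, dH) {
    .predict_heats_raw(N, exp(lKa), dH, sch)[keep]
  }

  # crude dH start: total heat / total moles injected (kJ/mol)
  dh0 <- sum(q[keep]) * 1e-6 /
    (sch$syringe_conc * 1e-6 * sum(sch$inj_volumes[keep]) * 1e-6) / 1000
  starts <- if (!is.null(start)) {
    list(c(N = start$N, lKa = log(start$Ka), dH = start$dH))
  } else {
    grid <- expand.grid(N = c(0.5, 1, 2, 4), lKa = log(10^(3:8)))
    lapply(seq_len(nrow(grid)), function(i)
      c(N = grid$N[i], lKa = grid$lKa[i], dH = dh0))
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        qs ~ model(N, lKa, dH),
        start = as.list(s),
        lower = c(N = 1e-3, lKa = log(1), dH = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      ssr <- sum(stats::residuals(fit)^2)
      if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    }
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, titration = titration,
                          diagnostics = list(message = "no start converged")),
                     class = "itc_fit"))

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  N <- unname(cf["N"]); Ka <- exp(unname(cf["lKa"]))
  dH <- unname(cf["dH"])
  params <- binding_params(N, Ka, dH, T = sch$temperature)
  se_out <- c(N = unname(se["N"]),
              Ka = Ka * unname(se["lKa"]),    # delta method from log scale
              dH = unname(se["dH"]))
  cval <- N * Ka * sch$cell_conc * 1e-6
  fitted_uj <- .predict_heats_raw(N, Ka, dH, sch)
  structure(
    list(params = params, se = se_out, converged = TRUE,
         titration = titration, keep = keep,
         fitted = fitted_uj, residuals = q - fitted_uj,
         ssr = best$ssr,
         diagnostics = list(
           c_value = cval,
           c_value_ok = cval >= 1 && cval <= 1000,
           n_starts = length(starts),
           skip_first = skip_first)),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<itc_fit> NOT CONVERGED:", x$diagnostics$message, "\n")
    return(invisible(x))
  }
  p <- x$params
  cat("<itc_fit> one-set-of-sites\n")
  cat(sprintf("  N  = %.3f +/- %.3f sites\n", p$N, x$se["N"]))
  cat(sprintf("  Kd = %.3g M (Ka = %.3g +/- %.2g 1/M)\n",
              p$Kd, p$Ka, x$se["Ka"]))
  cat(sprintf("  dH = %.2f +/- %.2f kJ/mol; dG = %.2f kJ/mol; dS = %.2f J/mol/K\n",
              p$dH, x$se["dH"], p$dG, p$dS))
  if (!x$diagnostics$c_value_ok)
    cat(sprintf("  warning: c-value %.3g outside [1, 1000]; parameters weakly identified\n",
                x$diagnostics$c_value))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  print(object)
  if (isTRUE(object$converged)) {
    cat(sprintf("  c-value = %.3g, SSR = %.4g uJ^2, %d injection(s) used\n",
                object$diagnostics$c_value, object$ssr, length(object$keep)))
  }
  invisible(object)
}

#' Fitted binding parameters
#'
#' @param object An `itc_fit` object.
#' @param ... Unused.
#' @return Named vector `N`, `Ka`, `Kd`, `dH`, `dG`, `dS`.
#' @export
coef.itc_fit <- function(object, ...) {
  if (!isTRUE(object$converged)) stop("fit did not converge")
  p <- object$params
  c(N = p$N, Ka = p$Ka, Kd = p$Kd, dH = p$dH, dG = p$dG, dS = p$dS)
}

#' Predicted heats from a fitted model
#'
#' @param object An `itc_fit` object.
#' @param schedule Optional [itc_schedule()]; defaults to the fitted one.
#' @param ... Unused.
#' @return Per-injection heats (uJ).
#' @export
predict.itc_fit <- function(object, schedule = NULL, ...) {
  if (!isTRUE(object$converged)) stop("fit did not converge")
  if (is.null(schedule)) schedule <- object$titration$schedule
  predict_heats(object$params, schedule)
}

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' @export
fitted.itc_fit <- function(object, ...) object$fitted

#' Simulate new titrations from a fitted model
#'
#' @param object An `itc_fit` object.
#' @param nsim Number of simulated titrations.
#' @param seed Optional integer seed.
#' @param noise_sd Gaussian heat noise (uJ); defaults to the fit's residual
#'   standard deviation.
#' @param ... Unused.
#' @return List of [itc_titration()] objects.
#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (!isTRUE(object$converged)) stop("fit did not converge")
  if (is.null(noise_sd)) noise_sd <- stats::sd(object$residuals)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_itc(object$params, object$titration$schedule,
                 noise_sd = noise_sd))
}

#' Binding isotherm plot for a fitted titration
#'
#' Normalized heats (kJ per mole of injectant) against molar ratio, with the
#' fitted isotherm overlaid.
#'
#' @param x An `itc_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.itc_fit <- function(x, ...) {
  sch <- x$titration$schedule
  mol_inj <- sch$syringe_conc * 1e-6 * sch$inj_volumes * 1e-6  # mol
  ratio <- .molar_ratio(sch)
  obs_kj <- x$titration$heats * 1e-6 / mol_inj / 1000
  fit_kj <- x$fitted * 1e-6 / mol_inj / 1000
  graphics::plot(ratio, obs_kj, xlab = "molar ratio (peptide / tubulin)",
                 ylab = "heat (kJ/mol of injectant)",
                 main = "one-set-of-sites fit", ...)
  graphics::lines(ratio, fit_kj, col = 2)
  invisible(x)
}
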