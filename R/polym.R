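# Turbidimetric polymerization curve metrics. Conventions (all config
# arguments): baseline = mean of the first 5% of points, plateau = mean of
# the last 10%, lag = first crossing of baseline + 10% of amplitude on the
# smoothed signal, vmax = maximal smoothed finite-difference slope. The lag
# is undefined when the amplitude is within 3 baseline noise SDs of zero.

#' Metrics of a turbidity polymerization curve
#'
#' @param curve A `turbidity_curve` or data.frame with strictly increasing
#'   `time_s` and `a350` (>= 10 samples).
#' @param smooth_window Centered moving-average window (samples, odd
#'   recommended; default 5).
#' @param lag_frac Amplitude fraction defining the lag crossing (default
#'   0.1).
#' @param baseline_frac Fraction of initial points averaged for the
#'   baseline (default 0.05).
#' @param plateau_frac Fraction of final points averaged for the plateau
#'   (default 0.10).
#' @return Object of class `polym_metrics`: list with `baseline`,
#'   `plateau`, `amplitude`, `lag_time` (s, `NA` when undefined), `vmax`
#'   (absorbance/s), `condition`.
#' @export
curve_metrics <- function(curve, smooth_window = 5, lag_frac = 0.1,
                          baseline_frac = 0.05, plateau_frac = 0.10) {
  if (!all(c("time_s", "a350") %in% names(curve)))
    stop("'curve' needs columns 'time_s' and 'a350'")
  t <- curve$time_s; a <- curve$a350
  n <- length(t)
  if (n < 10L) stop("curve needs at least 10 samples")
  if (any(diff(t) <= 0)) stop("'time_s' must be strictly increasing")

  n_base <- max(2L, ceiling(baseline_frac * n))
  n_plat <- max(2L, ceiling(plateau_frac * n))
  baseline <- mean(a[seq_len(n_base)])
  plateau <- mean(a[(n - n_plat + 1L):n])
  amplitude <- plateau - baseline
  noise_sd <- stats::sd(a[seq_len(n_base)])

  sm <- .moving_average(a, smooth_window)
  slope <- diff(sm) / diff(t)
  vmax <- max(slope)

  lag_time <- NA_real_
  defined <- amplitude > 3 * noise_sd &&
    amplitude > 1e-9 * max(1, abs(baseline))
  if (defined) {
    thr <- baseline + lag_frac * amplitude
    idx <- which(sm >= thr)
    if (length(idx)) lag_time <- t[idx[1L]]
  }

  structure(list(baseline = baseline, plateau = plateau,
                 amplitude = amplitude, lag_time = lag_time,
                 vmax = max(vmax, 0),
                 condition = if ("condition" %in% names(curve))
                   curve$condition[1L] else ""),
            class = "polym_metrics")
}

.moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window == 1L) return(x)
  k <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - k):min(n, i + k)])
  }, numeric(1))
}

#' @export
print.polym_metrics <- function(x, ...) {
  cat(sprintf("<polym_metrics>%s baseline %.4g, plateau %.4g, amplitude %.4g\n",
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              x$baseline, x$plateau, x$amplitude))
  cat(sprintf("  lag %s s, vmax %.4g A350/s\n",
              if (is.finite(x$lag_time)) sprintf("%.4g", x$lag_time) else "undefined",
              x$vmax))
  invisible(x)
}

#' Fold-change comparison of two polymerization curves
#'
#' @param control,treated `polym_metrics` objects.
#' @return List of class `polym_comparison`: `plateau_ratio`
#'   (treated amplitude-corrected plateau over control, computed on
#'   baseline-subtracted amplitudes), `lag_difference` (treated - control,
#'   s; `NA` if either lag is undefined), `vmax_ratio`.
#' @export
compare_curves <- function(control, treated) {
  for (m in list(control, treated))
    if (!inherits(m, "polym_metrics"))
      stop("inputs must be polym_metrics objects")
  structure(list(
    plateau_ratio = treated$amplitude / control$amplitude,
    lag_difference = if (is.finite(control$lag_time) &&
                         is.finite(treated$lag_time))
      treated$lag_time - control$lag_time else NA_real_,
    vmax_ratio = treated$vmax / control$vmax
  ), class = "polym_comparison")
}

#' @export
print.polym_comparison <- function(x, ...) {
  cat(sprintf("<polym_comparison> plateau ratio %.3g, lag difference %s s, vmax ratio %.3g\n",
              x$plateau_ratio,
              if (is.finite(x$lag_difference))
                sprintf("%+.4g", x$lag_difference) else "undefined",
              x$vmax_ratio))
  invisible(x)
}
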