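# Synthetic turbidity curves, ITC isotherms and fragment spectra with known
# ground truth, used by the validation suite and by make_fixture_suite().

#' Simulate a turbidimetric polymerization curve
#'
#' Gompertz sigmoid
#' `A(t) = baseline + plateau * exp(-exp(-rate * (t - t_m)))` with the time
#' shift `t_m = lag + log(log(10)) / rate` chosen so that the curve crosses
#' 10% of its amplitude exactly at `t = lag` — i.e. the generator's `lag`
#' parameter is defined on the same 10%-amplitude criterion that
#' [curve_metrics()] uses, making noiseless round-trips exact up to the
#' sampling grid. Gaussian noise is added pointwise.
#'
#' @param plateau Amplitude above baseline at saturation (A350 units, >= 0).
#' @param lag Lag time (s): the 10%-amplitude crossing.
#' @param rate Gompertz rate constant (1/s, > 0).
#' @param baseline Baseline absorbance (A350 units).
#' @param noise_sd Gaussian noise SD (A350 units, >= 0).
#' @param n_points Number of samples (>= 2).
#' @param dt Sampling interval (s).
#' @param condition Condition label.
#' @param seed Optional integer seed.
#' @return Object of class `turbidity_curve`: data.frame `time_s`, `a350`,
#'   `condition`, with the generating parameters in attribute `"truth"`.
#' @export
simulate_turbidity <- function(plateau = 0.25, lag = 120, rate = 0.01,
                               baseline = 0.05, noise_sd = 0,
                               n_points = 121, dt = 10,
                               condition = "sample", seed = NULL) {
  if (plateau < 0) stop("'plateau' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_points < 2) stop("'n_points' must be >= 2")
  if (rate <= 0) stop("'rate' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, by = dt, length.out = n_points)
  t_m <- lag + log(log(10)) / rate
  a <- baseline + plateau * exp(-exp(-rate * (t - t_m)))
  if (noise_sd > 0) a <- a + stats::rnorm(n_points, 0, noise_sd)
  out <- data.frame(time_s = t, a350 = a, condition = condition,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(plateau = plateau, lag = lag, rate = rate,
                             baseline = baseline, noise_sd = noise_sd)
  class(out) <- c("turbidity_curve", "data.frame")
  out
}

#' Simulate a one-set-of-sites ITC titration
#'
#' Per-injection heats are [predict_heats()] under the generating
#' parameters plus an optional constant dilution-heat offset and Gaussian
#' noise. The default schedule mirrors the tubulin experiment: 55 uM
#' macromolecule in the cell, 2.2 mM peptide in the syringe, 2 uL
#' injections.
#'
#' @param truth A [binding_params()] object (generating values).
#' @param schedule An [itc_schedule()] object.
#' @param noise_sd Gaussian heat noise (uJ, >= 0).
#' @param dilution_offset Constant per-injection dilution heat (uJ), also
#'   stored as `blank_heats` so that [subtract_blank()] can undo it.
#' @param seed Optional integer seed.
#' @return An [itc_titration()] with attribute `"truth"`.
#' @export
simulate_itc <- function(truth, schedule = itc_schedule(), noise_sd = 0,
                         dilution_offset = 0, seed = NULL) {
  if (!inherits(truth, "binding_params"))
    stop("'truth' must be a binding_params object")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  q <- predict_heats(truth, schedule) + dilution_offset
  if (noise_sd > 0) q <- q + stats::rnorm(length(q), 0, noise_sd)
  out <- itc_titration(schedule, q,
                       blank_heats = if (dilution_offset != 0)
                         rep(dilution_offset, length(q)) else NULL)
  attr(out, "truth") <- truth
  out
}

#' Simulate an in-source-decay peak list
#'
#' Generates the singly-protonated c/z ladder of a peptide, restricts it to
#' the acquisition window (default 1000-5000 Da, the usual ISD annotation
#' range), drops each ion independently with probability `dropout`, and
#' jitters m/z with Gaussian noise. The retained/dropped mask is kept as
#' ground truth for coverage oracles.
#'
#' @param pep A [peptide()] object or sequence string.
#' @param dropout Per-ion dropout probability in `[0, 1]`.
#' @param mz_noise_sd Gaussian m/z jitter (Da, >= 0).
#' @param window Acquisition window `c(low, high)` in Da.
#' @param seed Optional integer seed.
#' @return data.frame of class `peak_list` with columns `mz`, `intensity`;
#'   attribute `"ladder"` holds the full in-window ladder with a logical
#'   `kept` column.
#' @export
simulate_isd_peaks <- function(pep, dropout = 0, mz_noise_sd = 0,
                               window = c(1000, 5000), seed = NULL) {
  if (dropout < 0 || dropout > 1) stop("'dropout' must be in [0, 1]")
  if (mz_noise_sd < 0) stop("'mz_noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ladder <- isd_ladder(pep)
  ladder <- ladder[ladder$mz_1plus >= window[1] & ladder$mz_1plus <= window[2], ]
  ladder$kept <- if (nrow(ladder))
    stats::runif(nrow(ladder)) >= dropout else logical(0)
  kept <- ladder[ladder$kept, , drop = FALSE]
  mz <- kept$mz_1plus
  if (mz_noise_sd > 0 && length(mz))
    mz <- mz + stats::rnorm(length(mz), 0, mz_noise_sd)
  out <- data.frame(mz = mz,
                    intensity = if (length(mz))
                      stats::rlnorm(length(mz), 0, 0.5) else numeric(0))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ladder") <- ladder
  class(out) <- c("peak_list", "data.frame")
  out
}
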