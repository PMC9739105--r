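# Phase segmentation of microtubule length histories and the dynamic
# instability statistic set. Conventions (documented prominently because
# published tables cannot disambiguate them):
#   catastrophe = G->S or P->S transition; rescue = S->G or S->P;
#   catastrophe frequency per time = catastrophes / (time in G + time in P);
#   rescue frequency per time = rescues / time in S;
#   per-length frequencies normalize by total length grown (catastrophes)
#   or total length shortened (rescues);
#   dynamicity = (total length grown + total |length shortened|) / total time.

.PARAM_NAMES <- c("growth_rate", "shortening_rate",
                  "growth_length", "shortening_length",
                  "pct_time_G", "pct_time_S", "pct_time_P",
                  "cat_per_min", "res_per_min",
                  "cat_per_um", "res_per_um", "dynamicity")

#' Segment a length-history track into growth/shortening/pause phases
#'
#' Consecutive sampling intervals are first classified by instantaneous
#' rate (growth if slope >= `min_rate` um/min, shortening if
#' <= -`min_rate`, else pause), merged into runs, and each run is kept as
#' G (resp. S) only if its net excursion reaches `min_excursion` um (with
#' the matching sign) and its least-squares slope reaches `min_rate` in
#' magnitude; otherwise it is demoted to pause. Adjacent same-phase runs
#' are merged. The result is an exhaustive, non-overlapping, contiguous
#' partition of the track.
#'
#' The default thresholds (0.5 um, 2 um/min) are the customary values in
#' the dynamic-instability literature for noisy video tracking; for
#' noiseless synthetic data smaller thresholds recover the hidden phases
#' essentially exactly.
#'
#' @param track data.frame with strictly increasing `time_s` and
#'   non-negative `length_um` for a single track (>= 3 samples).
#' @param min_excursion Minimum net excursion for a growth/shortening
#'   phase (um, > 0).
#' @param min_rate Minimum phase speed (um/min, > 0).
#' @return data.frame of class `mt_segments`: `phase`, `t_start`, `t_end`,
#'   `delta_length`, `rate` (least-squares slope, um/min). Attribute
#'   `"sample_phase"` gives the phase label assigned to every sample
#'   (boundary samples belong to the following segment).
#' @export
segment_track <- function(track, min_excursion = 0.5, min_rate = 2) {
  if (!all(c("time_s", "length_um") %in% names(track)))
    stop("'track' needs columns 'time_s' and 'length_um'")
  if (nrow(track) < 3L) stop("track needs at least 3 samples")
  t <- track$time_s
  l <- track$length_um
  if (any(diff(t) <= 0)) stop("'time_s' must be strictly increasing")
  if (min_excursion <= 0 || min_rate <= 0) stop("thresholds must be > 0")

  slope <- diff(l) / diff(t) * 60  # um/min per interval
  cls <- ifelse(slope >= min_rate, "G", ifelse(slope <= -min_rate, "S", "P"))

  runs <- rle(cls)
  ends <- cumsum(runs$lengths)          # interval indices
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  phase <- character(length(runs$values))
  for (i in seq_along(runs$values)) {
    i0 <- starts[i]; i1 <- ends[i] + 1L  # sample indices i0..i1
    exc <- l[i1] - l[i0]
    sl <- .ls_slope(t[i0:i1], l[i0:i1])
    ph <- runs$values[i]
    if (ph == "G" && !(exc >= min_excursion && sl >= min_rate)) ph <- "P"
    if (ph == "S" && !(exc <= -min_excursion && sl <= -min_rate)) ph <- "P"
    phase[i] <- ph
  }

  # merge adjacent same-phase runs
  m <- rle(phase)
  m_ends <- cumsum(m$lengths)
  m_starts <- c(1L, utils::head(m_ends, -1L) + 1L)
  seg <- data.frame(phase = m$values,
                    t_start = t[starts[m_starts]],
                    t_end = t[ends[m_ends] + 1L],
                    stringsAsFactors = FALSE)
  seg$delta_length <- l[ends[m_ends] + 1L] - l[starts[m_starts]]
  seg$rate <- vapply(seq_len(nrow(seg)), function(i) {
    idx <- which(t >= seg$t_start[i] & t <= seg$t_end[i])
    .ls_slope(t[idx], l[idx])
  }, numeric(1))

  # per-sample labels: a sample on a boundary joins the following segment
  sample_phase <- character(length(t))
  for (i in seq_len(nrow(seg))) {
    sel <- t >= seg$t_start[i] & t < seg$t_end[i]
    sample_phase[sel] <- seg$phase[i]
  }
  sample_phase[length(t)] <- seg$phase[nrow(seg)]

  class(seg) <- c("mt_segments", "data.frame")
  attr(seg, "sample_phase") <- sample_phase
  attr(seg, "track_id") <- if ("track_id" %in% names(track))
    track$track_id[1L] else NA_character_
  seg
}

.ls_slope <- function(t, l) {
  tc <- t - mean(t)
  sum(tc * (l - mean(l))) / sum(tc^2) * 60  # um/min
}

#' Per-track event statistics from a segmentation
#'
#' Counts catastrophes (G to S, P to S) and rescues (S to G, S to P) at the
#' segment transitions and accumulates time and length excursion per phase.
#'
#' @param segments An `mt_segments` data.frame from [segment_track()].
#' @return One-row data.frame: `n_cat`, `n_res`, `time_G`, `time_S`,
#'   `time_P` (s), `len_grown`, `len_short` (um, both >= 0), per-phase
#'   mean event rates and lengths (`NA` when the phase is absent).
#' @export
track_events <- function(segments) {
  if (!inherits(segments, "mt_segments") || nrow(segments) == 0L)
    stop("'segments' must be a non-empty mt_segments object")
  ph <- segments$phase
  trans <- if (nrow(segments) > 1L)
    paste0(ph[-nrow(segments)], ph[-1L]) else character(0)
  dur <- segments$t_end - segments$t_start
  g <- ph == "G"; s <- ph == "S"; p <- ph == "P"
  data.frame(
    track_id = attr(segments, "track_id"),
    n_cat = sum(trans %in% c("GS", "PS")),
    n_res = sum(trans %in% c("SG", "SP")),
    time_G = sum(dur[g]), time_S = sum(dur[s]), time_P = sum(dur[p]),
    len_grown = sum(segments$delta_length[g]),
    len_short = sum(abs(segments$delta_length[s])),
    mean_rate_G = if (any(g)) mean(segments$rate[g]) else NA_real_,
    mean_rate_S = if (any(s)) mean(abs(segments$rate[s])) else NA_real_,
    mean_len_G = if (any(g)) mean(segments$delta_length[g]) else NA_real_,
    mean_len_S = if (any(s)) mean(abs(segments$delta_length[s])) else NA_real_,
    n_seg_G = sum(g), n_seg_S = sum(s),
    stringsAsFactors = FALSE
  )
}

#' Dynamic-instability parameter set for one condition
#'
#' Segments every track, pools events and times, and computes the full
#' statistic set: growth/shortening rates and lengths averaged per event,
#' percent time per phase, catastrophe and rescue frequencies per minute
#' and per micrometre, and dynamicity. Headline means pool events/times
#' across tracks; SEMs are computed over per-track values with n = number
#' of tracked microtubules. Ratios whose denominator is zero (e.g. rescue
#' frequency with no shortening time) are returned as `NA`.
#'
#' @param tracks An `mt_trackset`, or a data.frame with columns `track_id`,
#'   `time_s`, `length_um` (single condition).
#' @param min_excursion,min_rate Segmentation thresholds, see
#'   [segment_track()].
#' @param condition Optional condition label (defaults to the data's).
#' @return Object of class `mt_dynamics`: list with `stats` (data.frame
#'   `parameter`, `mean`, `sem`, `n`), `per_track`, `condition`,
#'   `thresholds`.
#' @export
aggregate_params <- function(tracks, min_excursion = 0.5, min_rate = 2,
                             condition = NULL) {
  df <- if (inherits(tracks, "mt_trackset")) tracks$tracks else tracks
  if (!all(c("track_id", "time_s", "length_um") %in% names(df)))
    stop("need columns 'track_id', 'time_s', 'length_um'")
  if (is.null(condition))
    condition <- if ("condition" %in% names(df)) df$condition[1L] else ""
  ids <- unique(df$track_id)
  if (!length(ids)) stop("no tracks")

  ev <- do.call(rbind, lapply(ids, function(id) {
    track_events(segment_track(df[df$track_id == id, ],
                               min_excursion, min_rate))
  }))

  total_time <- with(ev, sum(time_G + time_S + time_P))  # s
  pooled <- c(
    growth_rate = .wmean(ev$mean_rate_G, ev$n_seg_G),
    shortening_rate = .wmean(ev$mean_rate_S, ev$n_seg_S),
    growth_length = .wmean(ev$mean_len_G, ev$n_seg_G),
    shortening_length = .wmean(ev$mean_len_S, ev$n_seg_S),
    pct_time_G = 100 * sum(ev$time_G) / total_time,
    pct_time_S = 100 * sum(ev$time_S) / total_time,
    pct_time_P = 100 * sum(ev$time_P) / total_time,
    cat_per_min = .ratio(sum(ev$n_cat), sum(ev$time_G + ev$time_P) / 60),
    res_per_min = .ratio(sum(ev$n_res), sum(ev$time_S) / 60),
    cat_per_um = .ratio(sum(ev$n_cat), sum(ev$len_grown)),
    res_per_um = .ratio(sum(ev$n_res), sum(ev$len_short)),
    dynamicity = (sum(ev$len_grown) + sum(ev$len_short)) / (total_time / 60)
  )

  per_track <- data.frame(track_id = ev$track_id,
                          growth_rate = ev$mean_rate_G,
                          shortening_rate = ev$mean_rate_S,
                          growth_length = ev$mean_len_G,
                          shortening_length = ev$mean_len_S,
                          stringsAsFactors = FALSE)
  tt <- ev$time_G + ev$time_S + ev$time_P
  per_track$pct_time_G <- 100 * ev$time_G / tt
  per_track$pct_time_S <- 100 * ev$time_S / tt
  per_track$pct_time_P <- 100 * ev$time_P / tt
  per_track$cat_per_min <- mapply(.ratio, ev$n_cat, (ev$time_G + ev$time_P) / 60)
  per_track$res_per_min <- mapply(.ratio, ev$n_res, ev$time_S / 60)
  per_track$cat_per_um <- mapply(.ratio, ev$n_cat, ev$len_grown)
  per_track$res_per_um <- mapply(.ratio, ev$n_res, ev$len_short)
  per_track$dynamicity <- (ev$len_grown + ev$len_short) / (tt / 60)

  stats <- data.frame(
    parameter = .PARAM_NAMES,
    mean = unname(pooled[.PARAM_NAMES]),
    sem = vapply(.PARAM_NAMES, function(p) {
      v <- per_track[[p]]
      v <- v[is.finite(v)]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = length(ids),
    stringsAsFactors = FALSE
  )
  rownames(stats) <- NULL

  structure(list(stats = stats, per_track = per_track, events = ev,
                 condition = condition,
                 thresholds = c(min_excursion = min_excursion,
                                min_rate = min_rate)),
            class = "mt_dynamics")
}

.wmean <- function(x, w) {
  ok <- is.finite(x) & w > 0
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

.ratio <- function(num, den) if (!is.finite(den) || den <= 0) NA_real_ else num / den

#' @export
print.mt_dynamics <- function(x, digits = 3, ...) {
  cat(sprintf("<mt_dynamics> condition '%s', n = %d tracks\n",
              x$condition, x$stats$n[1L]))
  s <- x$stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %s\n", s$parameter[i],
                .fmt_pm(s$mean[i], s$sem[i], digits)))
  invisible(x)
}

#' @export
summary.mt_dynamics <- function(object, ...) {
  print(object, ...)
  cat(sprintf("  thresholds: min_excursion %g um, min_rate %g um/min\n",
              object$thresholds["min_excursion"],
              object$thresholds["min_rate"]))
  invisible(object)
}

.fmt_pm <- function(m, s, digits = 3) {
  if (!is.finite(m)) return("NA")
  if (is.finite(s)) sprintf("%.*g +/- %.*g", digits, m, digits, s)
  else sprintf("%.*g", digits, m)
}

# round half away from zero (the reporting convention for percent changes);
# the 1e-9 guard keeps exact halves computed in floating point (14.5 stored
# as 14.499999...) on the away side
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5 + 1e-9)

.sig_code <- function(p) {
  if (!is.finite(p)) return("")
  if (p < 0.001) "A" else if (p < 0.01) "B" else if (p < 0.05) "C" else ""
}

#' Compare dynamic-instability parameters between conditions
#'
#' Percent change `(treated - control) / control * 100`, rounded
#' half-away-from-zero to whole percent (the usual reporting style), with a
#' two-tailed Welch t-test (or Mann-Whitney) on per-track values when they
#' are available, and significance codes A (p < 0.001), B (p < 0.01),
#' C (p < 0.05).
#'
#' Inputs may be [aggregate_params()] results (p-values computed from the
#' per-track values) or plain named numeric vectors of parameter means,
#' e.g. a published table column (percent changes only, p-values `NA`).
#'
#' @param control,treated `mt_dynamics` objects or named numeric vectors.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return data.frame of class `mt_comparison`: `parameter`,
#'   `control_mean`, `treated_mean`, `pct_change`, `p_value`, `code`.
#' @export
compare_conditions <- function(control, treated,
                               test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  cm <- .dyn_means(control); tm <- .dyn_means(treated)
  params <- intersect(names(cm), names(tm))
  if (!length(params)) stop("no common parameters to compare")
  out <- data.frame(parameter = params,
                    control_mean = unname(cm[params]),
                    treated_mean = unname(tm[params]),
                    stringsAsFactors = FALSE)
  out$pct_change <- ifelse(
    is.finite(out$control_mean) & out$control_mean != 0,
    round_half_away((out$treated_mean - out$control_mean) /
                      out$control_mean * 100),
    NA_real_)
  out$p_value <- vapply(params, function(p) {
    x <- .dyn_raw(control, p); y <- .dyn_raw(treated, p)
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (identical(c(x, y), rep(x[1L], length(x) + length(y)))) return(1)
    if (test == "welch")
      stats::t.test(x, y, var.equal = FALSE)$p.value
    else
      stats::wilcox.test(x, y, exact = FALSE)$p.value
  }, numeric(1))
  out$code <- vapply(out$p_value, .sig_code, character(1))
  rownames(out) <- NULL
  class(out) <- c("mt_comparison", "data.frame")
  out
}

.dyn_means <- function(x) {
  if (inherits(x, "mt_dynamics"))
    stats::setNames(x$stats$mean, x$stats$parameter)
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("expected an mt_dynamics object or a named numeric vector")
}

.dyn_raw <- function(x, param) {
  if (inherits(x, "mt_dynamics") && param %in% names(x$per_track))
    x$per_track[[param]]
  else NA_real_
}

#' @export
print.mt_comparison <- function(x, ...) {
  cat("<mt_comparison> percent change vs control\n")
  for (i in seq_len(nrow(x))) {
    pc <- x$pct_change[i]
    cat(sprintf("  %-18s %s%%%s\n", x$parameter[i],
                if (is.finite(pc)) sprintf("%+d", as.integer(pc)) else "NA",
                if (nzchar(x$code[i])) paste0(" (", x$code[i], ")") else ""))
  }
  invisible(x)
}
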