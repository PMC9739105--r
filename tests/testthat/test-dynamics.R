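test_that("a constant-length track is one pause segment", {
  tr <- data.frame(track_id = "t", time_s = seq(0, 60, 2), length_um = 4,
                   condition = "x")
  seg <- segment_track(tr)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$phase, "P")
  expect_equal(seg$t_start, 0)
  expect_equal(seg$t_end, 60)
  expect_error(segment_track(tr[1:2, ]), "3 samples")
})

test_that("noiseless piecewise-linear tracks are recovered exactly", {
  plan <- data.frame(phase = c("G", "P", "S", "G"),
                     duration = c(20, 20, 16, 24),
                     slope = c(24, 0, -30, 18))
  tr <- make_piecewise_track(plan, dt = 2, l0 = 5)
  seg <- segment_track(tr, min_excursion = 0.5, min_rate = 2)
  expect_equal(seg$phase, plan$phase)
  expect_equal(seg$t_start, c(0, cumsum(plan$duration)[-4]))
  expect_equal(seg$t_end, cumsum(plan$duration))
  expect_equal(seg$rate, plan$slope, tolerance = 1e-9)
  expect_equal(seg$delta_length, plan$slope / 60 * plan$duration,
               tolerance = 1e-9)
})

test_that("segmentation partitions the track", {
  ts <- simulate_tracks(di_params(), n_tracks = 4, seed = 21)
  for (id in unique(ts$tracks$track_id)) {
    tr <- ts$tracks[ts$tracks$track_id == id, ]
    seg <- segment_track(tr)
    expect_equal(sum(seg$t_end - seg$t_start), max(tr$time_s) - min(tr$time_s))
    expect_equal(sum(seg$delta_length),
                 tr$length_um[nrow(tr)] - tr$length_um[1L], tolerance = 1e-9)
    expect_true(all(seg$t_start < seg$t_end))
    # contiguity
    if (nrow(seg) > 1L)
      expect_equal(seg$t_start[-1L], seg$t_end[-nrow(seg)])
  }
})

test_that("event counting follows the catastrophe/rescue definitions", {
  # single pure-growth track
  g <- make_piecewise_track(data.frame(phase = "G", duration = 60,
                                       slope = 20), dt = 2)
  dyn <- aggregate_params(g)
  s <- setNames(dyn$stats$mean, dyn$stats$parameter)
  expect_equal(s[["pct_time_G"]], 100)
  expect_equal(s[["dynamicity"]], 20, tolerance = 1e-9)
  expect_equal(s[["growth_rate"]], 20, tolerance = 1e-9)
  ev <- track_events(segment_track(g))
  expect_equal(ev$n_cat + ev$n_res, 0L)

  # G -> S -> G: one catastrophe, one rescue
  gsg <- make_piecewise_track(data.frame(phase = c("G", "S", "G"),
                                         duration = c(20, 10, 20),
                                         slope = c(24, -30, 24)),
                              dt = 2, l0 = 8)
  ev <- track_events(segment_track(gsg))
  expect_equal(ev$n_cat, 1L)
  expect_equal(ev$n_res, 1L)

  # P -> S is a catastrophe; S -> P a rescue
  psp <- make_piecewise_track(data.frame(phase = c("P", "S", "P"),
                                         duration = c(20, 10, 20),
                                         slope = c(0, -30, 0)),
                              dt = 2, l0 = 8)
  ev <- track_events(segment_track(psp))
  expect_equal(ev$n_cat, 1L)
  expect_equal(ev$n_res, 1L)
})

test_that("event counts equal the simulator log on finely sampled tracks", {
  p <- di_params(noise_sd = 0, l0 = 15)
  ts <- simulate_tracks(p, n_tracks = 10, duration = 60, dt = 0.02,
                        seed = 31)
  for (id in unique(ts$tracks$track_id)) {
    seg <- segment_track(ts$tracks[ts$tracks$track_id == id, ],
                         min_excursion = 1e-6, min_rate = 1)
    ev <- track_events(seg)
    log <- ts$events[ts$events$track_id == id, ]
    expect_equal(ev$n_cat, sum(log$to == "S"))
    expect_equal(ev$n_res, sum(log$from == "S"))
  }
})

test_that("aggregate invariants: time fractions sum to 100, dynamicity identity", {
  ts <- simulate_tracks(di_params(), n_tracks = 25, seed = 77)
  dyn <- aggregate_params(ts)
  s <- setNames(dyn$stats$mean, dyn$stats$parameter)
  expect_equal(s[["pct_time_G"]] + s[["pct_time_S"]] + s[["pct_time_P"]],
               100, tolerance = 0.01)
  expect_equal(dyn$stats$n, rep(25L, nrow(dyn$stats)))
  expect_true(all(s[c("cat_per_min", "res_per_min",
                      "cat_per_um", "res_per_um")] >= 0, na.rm = TRUE))
  # dynamicity ~ growth_rate * fG + shortening_rate * fS up to per-event
  # vs time weighting of the rate means
  approx <- s[["growth_rate"]] * s[["pct_time_G"]] / 100 +
    s[["shortening_rate"]] * s[["pct_time_S"]] / 100
  expect_lt(abs(s[["dynamicity"]] - approx) / s[["dynamicity"]], 0.15)
})

test_that("time-rescaled dynamics scale dynamicity exactly", {
  lam <- 2
  base <- di_params(noise_sd = 0, l0 = 20)
  scaled <- di_params(v_g = base$v_g * lam, v_s = base$v_s * lam,
                      k_GS = base$k_GS * lam, k_GP = base$k_GP * lam,
                      k_PG = base$k_PG * lam, k_PS = base$k_PS * lam,
                      k_SG = base$k_SG * lam, k_SP = base$k_SP * lam,
                      noise_sd = 0, l0 = 20)
  a <- simulate_tracks(base, n_tracks = 6, duration = 60, dt = 0.5,
                       seed = 13)
  b <- simulate_tracks(scaled, n_tracks = 6, duration = 60 / lam,
                       dt = 0.5 / lam, seed = 13)
  # same uniform draws, exponential dwell times scale by 1/lambda:
  # identical sample paths on the rescaled clock
  expect_equal(a$tracks$length_um, b$tracks$length_um, tolerance = 1e-9)
  # rate thresholds live in um/min, so they rescale with the clock
  da <- aggregate_params(a, min_excursion = 1e-6, min_rate = 1)
  db <- aggregate_params(b, min_excursion = 1e-6, min_rate = 1 * lam)
  expect_equal(db$stats$mean[db$stats$parameter == "dynamicity"],
               lam * da$stats$mean[da$stats$parameter == "dynamicity"],
               tolerance = 1e-9)
})

test_that("condition comparison: identity, rounding and significance codes", {
  ts <- simulate_tracks(di_params(), n_tracks = 8, seed = 55)
  dyn <- aggregate_params(ts)
  self <- compare_conditions(dyn, dyn)
  expect_true(all(self$pct_change == 0, na.rm = TRUE))
  expect_true(all(self$p_value == 1, na.rm = TRUE))
  expect_true(all(self$code == ""))

  # rounding is half away from zero
  cmp <- compare_conditions(c(dynamicity = 100), c(dynamicity = 114.5))
  expect_equal(cmp$pct_change, 15)
  cmp <- compare_conditions(c(dynamicity = 100), c(dynamicity = 71.5))
  expect_equal(cmp$pct_change, -29)

  # zero control mean is undefined-marked
  cmp <- compare_conditions(c(dynamicity = 0), c(dynamicity = 5))
  expect_true(is.na(cmp$pct_change))

  # clearly separated groups earn the strongest code
  fast <- aggregate_params(simulate_tracks(di_params(), n_tracks = 20,
                                           seed = 60))
  slow_p <- di_params(v_g = 8, v_s = 9)
  slow <- aggregate_params(simulate_tracks(slow_p, n_tracks = 20, seed = 61))
  cmp <- compare_conditions(fast, slow)
  expect_equal(cmp$code[cmp$parameter == "growth_rate"], "A")
})
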