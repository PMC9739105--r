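zero_rate_params <- function(...) {
  di_params(k_GS = 0, k_GP = 0, k_PG = 0, k_PS = 0, k_SG = 0, k_SP = 0,
            noise_sd = 0, ...)
}

test_that("degenerate chains give constant or linearly growing tracks", {
  ts <- simulate_tracks(zero_rate_params(v_g = 0, v_s = 0, l0 = 3),
                        n_tracks = 1, duration = 60, dt = 2,
                        start_state = "P", seed = 1)
  expect_equal(nrow(ts$tracks), 31L)  # floor(60/2) + 1 samples
  expect_true(all(ts$tracks$length_um == 3))
  expect_true(all(ts$states$state == "P"))

  tg <- simulate_tracks(zero_rate_params(v_g = 25, l0 = 2),
                        n_tracks = 1, duration = 60, dt = 2,
                        start_state = "G", seed = 1)
  expect_equal(tg$tracks$length_um[31L], 2 + 25, tolerance = 1e-9)
  expect_equal(nrow(tg$events), 0L)
})

test_that("simulator validates its inputs", {
  expect_error(di_params(k_GS = -1), ">= 0")
  expect_error(di_params(noise_sd = -0.1), ">= 0")
  expect_error(simulate_tracks(di_params(), duration = 0), "> 0")
  expect_error(simulate_tracks(di_params(), dt = -2), "> 0")
  expect_error(simulate_tracks(di_params(), n_tracks = 0), ">= 1")
})

test_that("identical seeds reproduce identical track sets", {
  a <- simulate_tracks(di_params(), n_tracks = 3, seed = 42)
  b <- simulate_tracks(di_params(), n_tracks = 3, seed = 42)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$states, b$states)
  expect_identical(a$events, b$events)
  c <- simulate_tracks(di_params(), n_tracks = 3, seed = 43)
  expect_false(identical(a$tracks, c$tracks))
})

test_that("long-run state occupancy matches the eigenvector stationary law", {
  p <- di_params(noise_sd = 0, l0 = 50)
  ts <- simulate_tracks(p, n_tracks = 1, duration = 2e4, dt = 2, seed = 5)
  occ <- prop.table(table(factor(ts$states$state, c("G", "S", "P"))))
  pi_oracle <- eigen_stationary(generator_matrix(p))
  # Monte-Carlo SE by batch means over 25 batches
  batches <- split(ts$states$state,
                   rep(1:25, each = ceiling(nrow(ts$states) / 25))[
                     seq_len(nrow(ts$states))])
  for (i in 1:3) {
    st <- c("G", "S", "P")[i]
    fr <- vapply(batches, function(b) mean(b == st), numeric(1))
    se <- stats::sd(fr) / sqrt(length(fr))
    expect_lt(abs(occ[[st]] - pi_oracle[i]), 3 * se + 1e-6)
  }
})

test_that("length is clipped at zero with a flagged forced rescue", {
  p <- di_params(v_g = 2, v_s = 40, k_GS = 30, k_SG = 0.5, k_SP = 0,
                 k_GP = 0, k_PG = 0, k_PS = 0, noise_sd = 0, l0 = 1)
  ts <- simulate_tracks(p, n_tracks = 5, duration = 120, dt = 2,
                        start_state = "S", seed = 9)
  expect_true(all(ts$tracks$length_um >= 0))
  forced <- ts$events[ts$events$boundary, ]
  expect_gt(nrow(forced), 0)
  expect_true(all(forced$from == "S" & forced$to == "G"))
})

test_that("turbidity generator is a documented Gompertz with exact anchors", {
  flat <- simulate_turbidity(plateau = 0, baseline = 0.07, noise_sd = 0)
  expect_true(all(abs(flat$a350 - 0.07) < 1e-12))
  expect_error(simulate_turbidity(noise_sd = -1), ">= 0")

  # noiseless round-trip: lag within one sample, plateau within 1%.
  # Valid parameter regime: the onset must clear the 5% baseline window
  # and the plateau must be reached within the record (see the vignette).
  cases <- data.frame(lag = c(120, 150, 300), rate = c(0.01, 0.02, 0.01))
  for (i in seq_len(nrow(cases))) {
    cur <- simulate_turbidity(plateau = 0.25, lag = cases$lag[i],
                              rate = cases$rate[i], baseline = 0.05,
                              noise_sd = 0, n_points = 121, dt = 10)
    m <- curve_metrics(cur)
    expect_lte(abs(m$lag_time - cases$lag[i]), 10)
    expect_lt(abs(m$plateau - 0.30) / 0.30, 0.01)
    expect_lt(abs(m$amplitude - 0.25) / 0.25, 0.015)
  }
})

test_that("ITC generator is the forward model plus noise and offset", {
  truth <- binding_params(N = 2, Ka = 1 / 5.3e-6, dH = -40)
  sch <- itc_schedule()
  expect_equal(sch$cell_conc, 55)      # tubulin cell concentration (uM)
  expect_equal(sch$syringe_conc, 2200) # peptide syringe concentration (uM)
  expect_true(all(sch$inj_volumes == 2))

  noiseless <- simulate_itc(truth, sch, noise_sd = 0)
  expect_identical(noiseless$heats, predict_heats(truth, sch))

  zero <- simulate_itc(binding_params(N = 2, Ka = 1e5, dH = 0), sch,
                       noise_sd = 0)
  expect_true(all(zero$heats == 0))

  a <- simulate_itc(truth, sch, noise_sd = 1, seed = 3)
  b <- simulate_itc(truth, sch, noise_sd = 1, seed = 3)
  expect_identical(a$heats, b$heats)
})

test_that("fragment-spectrum generator respects dropout and window", {
  pep <- myotoxin3_peptide("45H")
  empty <- simulate_isd_peaks(pep, dropout = 1, seed = 1)
  expect_equal(nrow(empty), 0L)

  full <- simulate_isd_peaks(pep, dropout = 0, mz_noise_sd = 0, seed = 1)
  lad <- isd_ladder(pep)
  expected <- sort(lad$mz_1plus[lad$mz_1plus >= 1000 & lad$mz_1plus <= 5000])
  expect_equal(full$mz, expected, tolerance = 1e-12)
  expect_true(all(full$mz >= 1000 & full$mz <= 5000))
  expect_error(simulate_isd_peaks(pep, dropout = 2), "\\[0, 1\\]")
})
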