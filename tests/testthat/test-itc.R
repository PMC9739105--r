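paper_schedule <- function(n_inj = 19) {
  itc_schedule(cell_conc = 55, syringe_conc = 2200,
               inj_volumes = rep(2, n_inj), cell_volume = 200)
}

test_that("forward model limits: zero enthalpy, tight binding, saturation", {
  sch <- paper_schedule()
  expect_true(all(predict_heats(binding_params(2, 1e5, 0), sch) == 0))

  # tight binding: every injected mole binds until the equivalence point,
  # so early heats approach dH x moles injected
  tight <- binding_params(N = 2, Ka = 1e12, dH = -40)
  q <- predict_heats(tight, sch)
  moles_inj <- sch$syringe_conc * 1e-6 * sch$inj_volumes * 1e-6
  # injections well before the equivalence point (ratio 2 at injection 5)
  expect_equal(q[1:3], -40 * 1000 * moles_inj[1:3] * 1e6,
               tolerance = 5e-3)

  # far past saturation the heats vanish
  long <- paper_schedule(n_inj = 60)
  q2 <- predict_heats(binding_params(2, 1 / 5.3e-6, -40), long)
  expect_lt(abs(q2[60]) / abs(q2[1]), 1e-2)
  # exothermic heats stay negative up to saturation, then are negligible
  # (the displaced-volume correction allows tiny sign flips past it)
  expect_true(all(q2[1:8] < 0))
  expect_lt(max(q2), 0.02 * abs(q2[1]))
})

test_that("isotherm inflection sits near the stoichiometric ratio", {
  sch <- paper_schedule(n_inj = 40)
  q <- predict_heats(binding_params(N = 2, Ka = 1e7, dH = -40), sch)
  dv <- cumsum(sch$inj_volumes)
  ratio <- (sch$syringe_conc * dv / sch$cell_volume) /
    (sch$cell_conc * (1 - dv / (2 * sch$cell_volume)))
  infl <- ratio[which.max(abs(diff(q)))]
  expect_lt(abs(infl - 2), 0.3)
})

test_that("blank subtraction is exact and shape-checked", {
  truth <- binding_params(2, 1 / 5.3e-6, -40)
  sch <- paper_schedule()
  tit <- simulate_itc(truth, sch, noise_sd = 0, dilution_offset = -7)
  corr <- subtract_blank(tit)
  expect_equal(corr$heats, predict_heats(truth, sch), tolerance = 1e-12)

  same <- subtract_blank(itc_titration(sch, tit$heats, tit$heats))
  expect_true(all(same$heats == 0))

  const <- subtract_blank(itc_titration(sch, rep(5, 19)), constant = 2)
  expect_true(all(const$heats == 3))
  expect_error(subtract_blank(itc_titration(sch, rep(5, 19)),
                              blank = rep(1, 5)), "length")
})

test_that("noiseless fits recover the generating parameters to 0.1%", {
  truth <- binding_params(N = 2, Ka = 1 / 5.3e-6, dH = -40)
  fit <- fit_one_site(simulate_itc(truth, paper_schedule(), noise_sd = 0))
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_lt(abs(cf["N"] - 2) / 2, 1e-3)
  expect_lt(abs(cf["Ka"] - truth$Ka) / truth$Ka, 1e-3)
  expect_lt(abs(cf["dH"] - (-40)) / 40, 1e-3)
  expect_true(fit$diagnostics$c_value_ok)

  # exothermic data give a negative fitted enthalpy
  expect_lt(cf["dH"], 0)
})

test_that("fits are invariant to joint rescaling of heats and dH units", {
  truth <- binding_params(2, 1 / 5.3e-6, -40)
  tit <- simulate_itc(truth, paper_schedule(), noise_sd = 1.5, seed = 4)
  f1 <- fit_one_site(tit)
  scaled <- itc_titration(tit$schedule, tit$heats * 1000)
  f2 <- fit_one_site(scaled)
  expect_equal(coef(f2)["N"], coef(f1)["N"], tolerance = 1e-5)
  expect_equal(coef(f2)["Ka"], coef(f1)["Ka"], tolerance = 1e-4)
  expect_equal(unname(coef(f2)["dH"]), unname(coef(f1)["dH"]) * 1000,
               tolerance = 1e-4)
})

test_that("model-object methods are coherent", {
  truth <- binding_params(2, 1 / 5.3e-6, -40)
  tit <- simulate_itc(truth, paper_schedule(), noise_sd = 1, seed = 8)
  fit <- fit_one_site(tit)
  expect_equal(fitted(fit) + residuals(fit), tit$heats, tolerance = 1e-9)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "itc_titration")
  expect_output(print(fit), "one-set-of-sites")
  # skipping the first injection still converges near truth
  f2 <- fit_one_site(tit, skip_first = TRUE)
  expect_lt(abs(coef(f2)["N"] - 2) / 2, 0.05)
})

test_that("weakly identified fits are flagged by c-value", {
  weak <- binding_params(N = 1, Ka = 2e3, dH = -40)
  sch <- paper_schedule(n_inj = 30)
  fit <- fit_one_site(simulate_itc(weak, sch, noise_sd = 0))
  expect_false(fit$diagnostics$c_value_ok)
})

test_that("thermodynamic derivations satisfy the standard identities", {
  th <- derive_thermodynamics(Ka = 1 / 5.3e-6, dH = -40, T = 293.15)
  expect_equal(th$dG, -29.6, tolerance = 0.02)
  expect_equal(th$Kd, 5.3e-6)
  expect_equal(th$dG, -40 - 293.15 * th$dS / 1000, tolerance = 1e-12)

  flatS <- derive_thermodynamics(Ka = exp(40 * 1000 / (8.314 * 293.15)),
                                 dH = -40, T = 293.15)
  expect_equal(flatS$dS, 0, tolerance = 1e-9)
  expect_error(derive_thermodynamics(Ka = -1, dH = 0), "> 0")
  expect_error(derive_thermodynamics(Ka = 1e5, dH = 0, T = 0), "> 0")

  bp <- binding_params(2, 1e6, -35)
  expect_equal(bp$dG, bp$dH - bp$T * bp$dS / 1000, tolerance = 1e-12)
})
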