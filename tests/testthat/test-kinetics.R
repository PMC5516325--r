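test_that("calibration recovers exact lines and enforces the linear range", {
  std <- data.frame(conc_mM = c(0.3, 0.8, 1.5, 2.5),
                    absorbance_AU = 0.3 * c(0.3, 0.8, 1.5, 2.5))
  cal <- fit_calibration(std)
  expect_equal(cal$slope, 0.3, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r2, 1)

  # standards beyond 0.85 AU are excluded with a warning
  std2 <- data.frame(conc_mM = c(0.3, 0.8, 1.5, 2.5, 3.13),
                     absorbance_AU = c(0.1, 0.25, 0.45, 0.84, 1.05))
  expect_warning(cal2 <- fit_calibration(std2), "linear range")
  expect_equal(nrow(cal2$standards), 4L)

  expect_error(suppressWarnings(fit_calibration(
    data.frame(conc_mM = 1:4, absorbance_AU = c(0.9, 1, 1.1, 0.5)))),
    "at least 3")
})

test_that("calibration slope matches the normal-equations oracle", {
  x <- c(0.1, 0.4, 0.9, 1.6, 2.5)
  y <- impscan:::withr_seed(31, 0.05 + 0.28 * x + stats::rnorm(5, 0, 0.01))
  y <- pmin(pmax(y, 0.071), 0.849)
  cal <- fit_calibration(data.frame(conc_mM = x, absorbance_AU = y))
  oracle <- ols_line(x, y)
  expect_equal(cal$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(cal$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
})

test_that("calibration inversion round-trips inside the linear range", {
  cal <- fit_calibration(data.frame(conc_mM = c(0.3, 0.9, 1.8, 2.8),
                                    absorbance_AU = c(0.1, 0.28, 0.55, 0.84)))
  conc <- seq(0.3, 2.5, by = 0.2)
  expect_equal(pi_from_absorbance(cal, absorbance_from_pi(cal, conc)), conc,
               tolerance = 1e-9)
  expect_warning(pi_from_absorbance(cal, 0.95), "linear range")
})

test_that("time-course rates are OLS slopes with a zero floor", {
  expect_equal(rate_from_timecourse(
    data.frame(timepoint_min = 1:3, pi = c(10, 20, 30))), 10)
  expect_equal(rate_from_timecourse(
    data.frame(timepoint_min = 1:3, pi = c(5, 5, 5))), 0)
  expect_warning(
    r <- rate_from_timecourse(data.frame(timepoint_min = 1:3,
                                         pi = c(30, 20, 10))),
    "negative")
  expect_equal(r, 0)
  tc <- data.frame(timepoint_min = c(1, 2, 3, 5),
                   pi = c(11.2, 19.5, 31.0, 50.1))
  expect_equal(rate_from_timecourse(tc),
               unname(ols_line(tc$timepoint_min, tc$pi)["slope"]),
               tolerance = 1e-12)
})

test_that("noiseless Hill data is inverted exactly", {
  conc <- c(5, 10, 25, 50, 100, 250)
  truth <- list(vmax = 0.42, s50 = 30, h = 1.6)
  rates <- data.frame(conc = conc,
                      rate = impscan:::hill_model(conc, truth$vmax,
                                                  truth$s50, truth$h))
  fit <- fit_hill(rates, enzyme_conc = 0.4)
  expect_equal(fit$vmax, truth$vmax, tolerance = 1e-6)
  expect_equal(fit$s50, truth$s50, tolerance = 1e-6)
  expect_equal(fit$h, truth$h, tolerance = 1e-6)
  expect_equal(fit$kcat, truth$vmax / 0.4, tolerance = 1e-6)
  # half-saturation identity: model value at s50 is exactly vmax / 2
  expect_equal(impscan:::hill_model(fit$s50, fit$vmax, fit$s50, fit$h),
               fit$vmax / 2)
  expect_error(fit_hill(rates[1:3, ], 0.4), "5")
})

test_that("the Hill fit matches a dense grid-plus-polish oracle", {
  spec <- kinetics_sim_spec("hill", list(vmax = 0.37, s50 = 24, h = 1.5),
                            c(17.5, 25, 37.5, 50, 75, 100, 150, 200),
                            replicates = 2, cv = 0.05, seed = 1069)
  rates <- simulate_kinetics(spec)
  fit <- fit_hill(rates, enzyme_conc = 0.36)
  expect_equal(fit$rss, grid_hill_rss(rates), tolerance = 1e-6)
})

test_that("catalytic efficiency arithmetic and homogeneity", {
  expect_equal(catalytic_efficiency(1, 1e6), 1) # 1 M: unit identity
  for (c_fac in c(0.5, 2, 10))
    expect_equal(catalytic_efficiency(1.04 * c_fac, 23.6),
                 c_fac * catalytic_efficiency(1.04, 23.6))
  expect_error(catalytic_efficiency(-1, 10), "positive")
  expect_error(catalytic_efficiency(1, 0), "positive")
})

test_that("activation fits recover exact curves and flag flat ones", {
  x <- c(0, 0.25, 0.5, 1, 2.5, 5, 10, 20, 40)
  exact <- data.frame(conc = x,
                      rate = impscan:::activation_model(x, 100, 5, 0.86))
  fit <- fit_activation(exact)
  expect_equal(fit$v0, 100, tolerance = 1e-6)
  expect_equal(fit$fold, 5, tolerance = 1e-6)
  expect_equal(fit$k_act, 0.86, tolerance = 1e-6)
  expect_false(fit$no_activation)
  # half-stimulation identity
  expect_equal(impscan:::activation_model(fit$k_act, fit$v0, fit$fold,
                                          fit$k_act),
               fit$v0 * (1 + fit$fold) / 2, tolerance = 1e-6)

  flat <- data.frame(conc = x, rate = rep(100, length(x)))
  expect_true(fit_activation(flat)$no_activation)
  expect_error(fit_activation(data.frame(conc = c(1, 2, 4, 8, 16),
                                         rate = 1:5)), "0")
})

test_that("Hill parameter recovery is unbiased with honest uncertainty", {
  # repeated simulation at the HolP saturation design: the median relative
  # S50 error stays within 5% and the +-2 SE interval covers the truth in
  # at least 85% of runs
  truth <- list(vmax = 0.373, s50 = 23.6, h = 1.47)
  concs <- c(17.5, 25, 37.5, 50, 75, 100, 150, 200)
  n_sim <- 200L
  res <- vapply(seq_len(n_sim), function(i) {
    spec <- kinetics_sim_spec("hill", truth, concs, replicates = 6,
                              cv = 0.05, seed = 1069 + i)
    fit <- fit_hill(simulate_kinetics(spec), enzyme_conc = 0.3585)
    c(rel = abs(fit$s50 - truth$s50) / truth$s50,
      covered = abs(fit$s50 - truth$s50) <= 2 * fit$se[["s50"]])
  }, numeric(2))
  expect_lte(stats::median(res["rel", ]), 0.05)
  expect_gte(mean(res["covered", ]), 0.85)
})

test_that("relative activity normalizes to the metal-ion reference", {
  ra <- relative_activity(c(Mg = 2.0, Co = 0.4, Mn = 0.22, Zn = 0),
                          reference = "Mg")
  expect_equal(ra$pct[ra$condition == "Mg"], 100)
  expect_equal(ra$pct[ra$condition == "Co"], 20)
  expect_equal(ra$label[ra$condition == "Zn"], "n.d.")
  expect_true(is.na(ra$pct[ra$condition == "Zn"]))
  expect_error(relative_activity(c(Mg = 0, Co = 1), "Mg"), "positive")
  expect_error(relative_activity(c(Co = 1), "Mg"), "not present")
})

test_that("assay enzyme molarity follows from mass and amounts", {
  # 10 ul of 0.1 ug/ul enzyme in 100 ul at 27893.16 g/mol
  expect_equal(enzyme_molar_uM(1, 100, 27893.16), 0.3585, tolerance = 1e-4)
})
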