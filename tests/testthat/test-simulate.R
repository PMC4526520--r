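# Synthetic signal generator: determinism, degenerate inputs,
# monotonicity and linearity contracts.

test_that("amplification parameter validation names the offending field", {
  expect_error(amp_model(N0 = -1), "N0")
  expect_error(amp_model(N0 = 10, E0 = 1.5), "E0")
  expect_error(amp_model(N0 = 10, K = 5), "K")
  expect_error(amp_model(N0 = 10, noise_sd = -1), "noise_sd")
  expect_error(amp_model(N0 = 10, n_cycles = 5), "n_cycles")
})

test_that("identical seeds give bit-identical simulated curves", {
  p <- amp_model(N0 = 1e4, E0 = 0.95, noise_sd = 0.01, seed = 42)
  c1 <- simulate_amplification(p)
  c2 <- simulate_amplification(p)
  expect_identical(c1$fluorescence, c2$fluorescence)

  m1 <- simulate_melt(list(melt_component(84)), noise_sd = 0.01, seed = 7)
  m2 <- simulate_melt(list(melt_component(84)), noise_sd = 0.01, seed = 7)
  expect_identical(m1$fluorescence, m2$fluorescence)

  s1 <- simulate_survey(survey_design(stations = 5, seed = 3),
                        melt_curves = FALSE)
  s2 <- simulate_survey(survey_design(stations = 5, seed = 3),
                        melt_curves = FALSE)
  expect_identical(s1$cp_calls, s2$cp_calls)

  e1 <- simulate_exposure(exposure_design(seed = 9))
  e2 <- simulate_exposure(exposure_design(seed = 9))
  expect_identical(e1$dcp_treatment, e2$dcp_treatment)
})

test_that("a no-template control yields a flat baseline-only curve", {
  p <- amp_model(N0 = 0, noise_sd = 0, baseline_slope = 0.002)
  cv <- simulate_amplification(p)
  # residuals from the linear baseline are exactly zero
  fit <- lm(cv$fluorescence ~ cv$cycles)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("increasing template strictly decreases the called Cp (noiseless)", {
  cps <- vapply(10^seq(2, 7), function(n0) call_cp(quiet_curve(n0))$cp,
                numeric(1))
  expect_true(all(diff(cps) < 0))
})

test_that("melt signal is linear in amplitude and component validation holds", {
  expect_error(melt_component(tm = 60), "tm")
  expect_error(melt_component(tm = 84, width = 0), "width")
  expect_error(simulate_melt(list(melt_component(84)), step = 0), "step")
  expect_error(simulate_melt(list(melt_component(84)), t_start = 95,
                             t_end = 65), "range")

  m1 <- simulate_melt(list(melt_component(84, amplitude = 1)),
                      background_intercept = 0, background_slope = 0)
  m3 <- simulate_melt(list(melt_component(84, amplitude = 3)),
                      background_intercept = 0, background_slope = 0)
  d1 <- derivative_profile(m1)
  d3 <- derivative_profile(m3)
  expect_equal(d3$neg_dfdt, 3 * d1$neg_dfdt, tolerance = 1e-12)
  expect_equal(call_peaks(d3)$peaks$tm[1], call_peaks(d1)$peaks$tm[1],
               tolerance = 1e-9)
})

test_that("survey draws respect the design's truncation and replicate structure", {
  des <- survey_design(stations = 40, seed = 12)
  sim <- simulate_survey(des, melt_curves = FALSE)
  expect_true(all(sim$cp_calls$cp > 0 & sim$cp_calls$cp <= 45))
  counts <- table(sim$cp_calls$sample_id, sim$cp_calls$target)
  expect_true(all(counts == 2))  # duplicates everywhere
  # replicate spread is consistent with the small technical sd
  deltas <- tapply(sim$cp_calls$cp,
                   paste(sim$cp_calls$sample_id, sim$cp_calls$target),
                   function(v) abs(diff(v)))
  expect_lt(mean(deltas > 0.25), 0.02)
})

test_that("survey Synechococcus mixture fraction drives the drawn Tm windows", {
  des <- survey_design(stations = 30, seed = 5,
                       syn_fraction = c("3m" = 1, "DCM" = 0, "DCM+40" = 0))
  sim <- simulate_survey(des, melt_curves = FALSE)
  tm3 <- sim$tm_truth[sim$tm_truth$depth_class == "3m", ]
  expect_true(all(tm3$true_taxon == "synechococcus"))
  expect_true(all(tm3$true_tm >= 88 & tm3$true_tm <= 89))
  deep <- sim$tm_truth[sim$tm_truth$depth_class != "3m", ]
  expect_true(all(deep$true_taxon == "prochlorococcus"))
})

test_that("exposure simulation preserves pairing and injects exact effects", {
  des <- exposure_design(fold_effects = c(rbcL = 1, psbA = 1),
                         noise_sd = 0, between_sd = 0.3, seed = 4)
  x <- simulate_exposure(des)
  expect_equal(x$dcp_treatment, x$dcp_control, tolerance = 1e-12)

  des2 <- exposure_design(fold_effects = c(rbcL = 0.5), dcp_base = c(rbcL = 0),
                          noise_sd = 0, seed = 4)
  x2 <- simulate_exposure(des2)
  expect_equal(x2$dcp_treatment - x2$dcp_control, rep(-1, nrow(x2)),
               tolerance = 1e-12)

  # cell-specific effects via the data-frame form
  fe <- data.frame(gene = "rbcL", strain = "MIT9313", time = "24h",
                   fold = 0.25)
  des3 <- exposure_design(fold_effects = fe, dcp_base = c(rbcL = 0),
                          noise_sd = 0, seed = 4)
  x3 <- simulate_exposure(des3)
  hit <- x3$strain == "MIT9313" & x3$time == "24h"
  expect_equal(unique(x3$true_fold[hit]), 0.25)
  expect_equal(unique(x3$true_fold[!hit]), 1)
})
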