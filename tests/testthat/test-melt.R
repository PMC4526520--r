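# Melt derivative profiles, peak calling, taxon classification and
# heterogeneity summaries.

test_that("a linear melt signal has a constant derivative and no peaks", {
  temps <- seq(65, 95, by = 0.1)
  cv <- melt_curve("s", "t", temps, 10 - 0.05 * temps)
  d <- derivative_profile(cv)
  expect_lt(diff(range(d$neg_dfdt)), 1e-9)
  expect_equal(call_peaks(d)$profile_class, "none")
})

test_that("single-component Tm is recovered within 0.2 C across the span", {
  for (tm in c(70, 77, 84, 90, 94)) {
    for (w in c(0.4, 0.8, 1.2)) {
      if (tm + 3 * w >= 95 || tm - 3 * w <= 65) next
      prof <- profile_from_tms(tm, width = w)
      expect_equal(prof$profile_class, "single")
      expect_lt(abs(prof$peaks$tm[1] - tm), 0.2)
    }
  }
})

test_that("equal components are resolved at >= 2 C and merged at <= 0.3 C", {
  for (centre in c(80, 84, 88)) {
    for (sep in c(2.0, 2.5, 3.5)) {
      prof <- profile_from_tms(c(centre - sep / 2, centre + sep / 2))
      expect_equal(prof$profile_class, "double")
      expect_equal(sort(prof$peaks$tm), c(centre - sep / 2, centre + sep / 2),
                   tolerance = 0.15)
    }
    for (sep in c(0.1, 0.2, 0.3)) {
      prof <- profile_from_tms(c(centre - sep / 2, centre + sep / 2))
      expect_equal(prof$profile_class, "single")
    }
  }
})

test_that("a mixed Prochlorococcus/Synechococcus melt yields a double profile", {
  prof <- profile_from_tms(c(83.0, 88.5))
  expect_equal(prof$profile_class, "double")
  cl <- classify_taxon(prof)
  expect_equal(cl$taxon_call, "ambiguous")
  expect_setequal(cl$taxon_flags, c("prochlorococcus", "synechococcus"))
})

test_that("taxon classification follows the major-peak Tm window", {
  expect_equal(classify_taxon(fake_profile(89.0))$taxon_call, "synechococcus")
  expect_equal(classify_taxon(fake_profile(83.2))$taxon_call, "prochlorococcus")
  expect_equal(classify_taxon(fake_profile(86.7))$taxon_call, "ambiguous")
  expect_equal(classify_taxon(fake_profile(84, target = "rnpB-LL"))$taxon_call,
               "non_discriminative")
  nop <- classify_taxon(fake_profile(numeric(0)))
  expect_equal(nop$taxon_call, "ambiguous")
  expect_true("no_peaks" %in% nop$taxon_flags)
})

test_that("classification is a pure function of major Tm and the windows", {
  set.seed(31)
  cfg <- tm_windows()
  w <- cfg$windows[["rbcL-LL"]]
  for (tm in runif(200, 78, 94)) {
    call <- classify_taxon(fake_profile(tm), cfg)$taxon_call
    want <- if (tm >= w$prochlorococcus[1] && tm <= w$prochlorococcus[2])
      "prochlorococcus"
    else if (tm >= w$synechococcus[1] && tm <= w$synechococcus[2])
      "synechococcus"
    else "ambiguous"
    expect_equal(call, want)
  }
  expect_error(tm_windows(list(x = list(prochlorococcus = c(81, 88),
                                        synechococcus = c(87, 90)))),
               "disjoint")
})

test_that("survey-simulated surface rbcL-LL melts classify as drawn", {
  des <- survey_design(stations = 8, seed = 21,
                       syn_fraction = c("3m" = 1, "DCM" = 0, "DCM+40" = 0))
  sim <- simulate_survey(des)
  calls <- vapply(sim$melt_curves, function(cv)
    classify_taxon(call_peaks(derivative_profile(cv)))$taxon_call,
    character(1))
  expect_equal(calls[sim$tm_truth$depth_class == "3m"],
               rep("synechococcus", 8), ignore_attr = TRUE)
  expect_equal(calls[sim$tm_truth$depth_class != "3m"],
               rep("prochlorococcus", 16), ignore_attr = TRUE)
})

test_that("heterogeneity summary computes double-peak and outlier rates", {
  # uniform single peaks: no doubles, no non-average majors
  unif <- lapply(1:10, function(i) fake_profile(84, sample_id = paste0("s", i)))
  h <- heterogeneity_summary(unif)
  expect_equal(h$pct_double_peaks, 0)
  expect_equal(h$pct_nonaverage_major_peaks, 0)

  # 16 double-peaked profiles among 61
  profs <- c(lapply(1:45, function(i) fake_profile(84, sample_id = paste0("a", i))),
             lapply(1:16, function(i) fake_profile(c(83.5, 88.5),
                                                   sample_id = paste0("b", i))))
  h2 <- heterogeneity_summary(profs)
  expect_equal(h2$n, 61)
  expect_equal(round(h2$pct_double_peaks, 1), 26.2)

  # planted outlier beyond 2 sd of the group Tm distribution
  set.seed(8)
  tms <- rnorm(40, 84.4, 1.0)
  profs3 <- c(lapply(tms, fake_profile), list(fake_profile(90.0)))
  h3 <- heterogeneity_summary(profs3)
  expect_gte(h3$pct_nonaverage_major_peaks, 100 / 41 - 1e-9)

  # grouping splits summaries and tiny groups are skipped
  g <- c(rep("3m", 10), rep("DCM", 1))
  profs4 <- lapply(1:11, function(i) fake_profile(84, sample_id = i))
  expect_message(h4 <- heterogeneity_summary(profs4, g), "fewer than 2")
  expect_equal(h4$group, "3m")
})
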