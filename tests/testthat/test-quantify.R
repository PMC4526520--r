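# Delta-Cp algebra: fold changes, ratios, clade fractions and the
# quantification filters.

test_that("delta_cp reproduces the worked survey-summary examples", {
  expect_equal(delta_cp(20.98, 21.09), -0.11)
  expect_equal(delta_cp(20.98, 16.87), 4.11)
  expect_equal(delta_cp(17, 17), 0)
  expect_true(is.na(delta_cp(NA, 17)))
})

test_that("fold change follows 2^(dCp_a - dCp_b) with NA propagation", {
  expect_equal(fold_change(3.2, 3.2)$value, 1)
  expect_equal(fold_change(10, 0)$value, 1024)
  expect_equal(fold_change(5, 0)$value, 32)
  # surface vs deep contrast from the survey summary means
  expect_equal(fold_change(-0.11, -2.54)$value, 2^2.43)
  expect_equal(round(fold_change(-0.11, -2.54)$value), 5)
  expect_true(is.na(fold_change(NA, 1)$value))
})

test_that("fold change is antisymmetric", {
  set.seed(19)
  for (i in 1:50) {
    a <- runif(1, -8, 8); b <- runif(1, -8, 8)
    expect_equal(fold_change(a, b)$value * fold_change(b, a)$value, 1,
                 tolerance = 1e-12)
  }
})

test_that("rbcL/psbA ratio matches its closed form", {
  expect_equal(rbcl_psba_ratio(2, 2)$value, 1)
  r <- rbcl_psba_ratio(-0.11, 4.11)
  expect_equal(r$value, 2^-4.22, tolerance = 1e-12)
  expect_equal(round(r$value, 3), 0.054)
  # cross-check: 2^(Cp_psbA - Cp_rbcL) with the shared reference cancelling
  expect_equal(r$value, 2^(16.87 - 21.09), tolerance = 1e-12)
})

test_that("clade fractions conserve mass, respect symmetry and match the oracle", {
  set.seed(23)
  for (i in 1:100) {
    hl <- runif(1, 12, 38); ll <- runif(1, 12, 38)
    cf <- clade_fraction(hl, ll)
    expect_equal(cf$fraction_HL + cf$fraction_LL, 1, tolerance = 1e-15)
    # brute-force oracle: evaluate N0 = k (1+E)^-Cp with arbitrary k
    k <- runif(1, 1, 100)
    n_hl <- k * 2^(-hl); n_ll <- k * 2^(-ll)
    expect_equal(cf$fraction_HL, n_hl / (n_hl + n_ll), tolerance = 1e-12)
  }
  expect_equal(clade_fraction(25, 25)$fraction_HL, 0.5)

  # general-efficiency form against the same oracle
  for (i in 1:50) {
    hl <- runif(1, 15, 35); ll <- runif(1, 15, 35)
    e_hl <- runif(1, 0.9, 1); e_ll <- runif(1, 0.9, 1)
    cf <- clade_fraction(hl, ll, e_hl, e_ll)
    n_hl <- 7 * (1 + e_hl)^(-hl); n_ll <- 7 * (1 + e_ll)^(-ll)
    expect_equal(cf$fraction_HL, n_hl / (n_hl + n_ll), tolerance = 1e-9)
    expect_false(cf$assumes_equal_efficiency && e_hl != e_ll)
  }

  cen <- clade_fraction(NA, 25)
  expect_true(cen$undefined)
  expect_true(is.na(cen$fraction_HL))
})

test_that("survey-summary means reproduce the headline clade fractions", {
  expect_equal(round(100 * clade_fraction(20.98, 26.00)$fraction_HL), 97)
  expect_equal(round(100 * clade_fraction(22.65, 18.80)$fraction_HL), 6)
  expect_equal(round(100 * clade_fraction(26.17, 20.67)$fraction_HL), 2)
})

test_that("quantify_samples builds per-clade records with exact identities", {
  calls <- data.frame(
    sample_id = "s1",
    target = c("rnpB-HL", "rbcL-HL", "psbA-HL", "rnpB-LL", "rbcL-LL",
               "psbA-LL"),
    cp = c(20.98, 21.09, 16.87, 26.00, 31.83, 25.07))
  q <- quantify_samples(calls)
  hl <- q[q$clade == "HL", ]
  expect_equal(hl$delta_cp_rbcL, -0.11)
  expect_equal(hl$delta_cp_psbA, 4.11)
  expect_equal(hl$ratio, 2^(-0.11 - 4.11), tolerance = 1e-12)
  expect_equal(hl$rel_rbcL, 2^-0.11, tolerance = 1e-12)
  expect_equal(round(100 * hl$fraction_HL), 97)
  ll <- q[q$clade == "LL", ]
  expect_equal(ll$delta_cp_rbcL, 26.00 - 31.83)
  expect_true(is.na(ll$fraction_HL))
})

test_that("quantification filters enforce the single-peak and replicate rules", {
  records <- data.frame(sample_id = c("s1", "s2", "s3"), clade = "LL",
                        delta_cp_rbcL = 0, delta_cp_psbA = 0,
                        rel_rbcL = 1, rel_psbA = 1, ratio = 1,
                        fraction_HL = NA_real_, included = TRUE)
  melt <- expand.grid(sample_id = c("s1", "s2", "s3"),
                      target = c("rnpB-LL", "rbcL-LL", "psbA-LL"),
                      stringsAsFactors = FALSE)
  melt$profile_class <- "single"
  melt$profile_class[melt$sample_id == "s2" & melt$target == "rbcL-LL"] <-
    "double"
  cp_calls <- expand.grid(sample_id = c("s1", "s2", "s3"),
                          target = c("rnpB-LL", "rbcL-LL", "psbA-LL"),
                          stringsAsFactors = FALSE)
  cp_calls$qc_flags <- ""
  cp_calls$qc_flags[cp_calls$sample_id == "s3" &
                      cp_calls$target == "rnpB-LL"] <- "replicate_disagreement"
  out <- apply_quant_filters(records, melt, cp_calls)
  expect_true(out$included[out$sample_id == "s1"])
  expect_true(is.na(out$exclusion_reason[out$sample_id == "s1"]))
  expect_false(out$included[out$sample_id == "s2"])
  expect_equal(out$exclusion_reason[out$sample_id == "s2"], "single_peak_rule")
  expect_false(out$included[out$sample_id == "s3"])
  expect_equal(out$exclusion_reason[out$sample_id == "s3"],
               "replicate_disagreement")

  # missing melt profile excludes with its own reason
  out2 <- apply_quant_filters(records[1, ], melt[melt$sample_id == "s2", ])
  expect_false(out2$included)
  expect_equal(out2$exclusion_reason, "missing_melt_profile")
})

test_that("noiseless survey at the summary means reproduces the headline numbers", {
  cs <- survey_summary_fixture()
  cs$sd_cp <- 0
  des <- survey_design(stations = 3, cp_summary = cs, replicate_sd = 0,
                       seed = 1)
  sim <- simulate_survey(des, melt_curves = FALSE)
  calls <- aggregate(cp ~ sample_id + target, sim$cp_calls, mean)
  q <- quantify_samples(calls)
  hl <- q[q$clade == "HL", ]
  expect_equal(round(100 * hl$fraction_HL[1]), 97)
  # depth ratios recovered exactly through the pipeline
  merged <- merge(q, unique(sim$cp_calls[c("sample_id", "depth_class")]),
                  by = "sample_id")
  m3 <- merged[merged$depth_class == "3m" & merged$clade == "HL", ][1, ]
  m40 <- merged[merged$depth_class == "DCM+40" & merged$clade == "HL", ][1, ]
  expect_equal(round(fold_change(m3$delta_cp_rbcL, m40$delta_cp_rbcL)$value), 5)
  expect_equal(round(fold_change(m3$delta_cp_psbA, m40$delta_cp_psbA)$value), 3)
})
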