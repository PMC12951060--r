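test_that("beat_harmonics matches single-harmonic closed forms", {
  L <- 256; x <- 0:(L - 1)
  h <- beat_harmonics(5 + 2 * cos(2 * pi * x / L - 1.0))
  expect_equal(unname(h$A[1]), 5, tolerance = 1e-12)
  expect_equal(unname(h$A[2]), 2, tolerance = 1e-12)
  expect_equal(unname(h$theta[2]), 1.0, tolerance = 1e-12)
  expect_lt(max(h$A[3:12]), 1e-12)

  h2 <- beat_harmonics(3 * cos(4 * pi * x / L))
  expect_equal(unname(h2$A[3]), 3, tolerance = 1e-12)
  expect_equal(unname(h2$theta[3]), 0, tolerance = 1e-12)
  expect_lt(max(h2$A[-3]), 1e-12)

  # degenerate constant beat: zero amplitudes, flagged, phases 0
  hc <- beat_harmonics(rep(2.5, 64))
  expect_true(hc$degenerate)
  expect_equal(unname(hc$A[1]), 2.5)
  expect_true(all(hc$theta == 0))

  expect_error(beat_harmonics(rep(1, 20)), "24")
})

test_that("energy fractions obey Parseval across the full spectrum", {
  set.seed(33)
  for (i in 1:10) {
    b <- synthesize_beat(c(runif(1, 1, 5), runif(11)),
                         c(0, runif(11, -pi, pi)), 128)
    h <- beat_harmonics(b)
    expect_equal(sum(h$E), 1, tolerance = 1e-12)
    expect_equal(sum(beat_energy_spectrum(b)), 1, tolerance = 1e-12)
  }
  # default synthetic beats keep >= 98% of energy in orders 0-11
  sub <- template_subject(jitter_amp_cv = 0.05, jitter_phase_sd = 0.03,
                          jitter_period_cv = 0.03, noise_sd = 0.01)
  wf <- generate_subject_waveforms(sub, test_acq(duration = 10), seed = 5)
  bs <- segment_beats(wf$left)
  for (k in which(bs$quality_flags)[1:5]) {
    spec <- beat_energy_spectrum(resample_beat(bs$beats[[k]], 256))
    expect_gte(sum(spec[as.character(0:11)]), 0.98)
  }
})

test_that("summarize_record computes means, circular means and CVs", {
  # constant beats: every CV is zero
  A <- matrix(rep(c(2, 1, 0.5, rep(0.1, 9)), 6), 12)
  th <- matrix(rep(seq(0, 1.1, length.out = 12), 6), 12)
  E <- matrix(rep(c(0.9, rep(0.1 / 11, 11)), 6), 12)
  s <- summarize_record(manual_beat_matrix(A, th, E))
  expect_true(all(unlist(s[c("C_cv", "P_cv", "D_cv")]) == 0))
  expect_equal(unname(s$C["0"]), 1)
  expect_equal(unname(s$C["1"]), 0.5)
  expect_equal(unname(s$P["3"]), th[4, 1])

  # normalized order-3 amplitudes {1,3,1,3,1,3}: C3 = 2, CV = sd/mean
  A2 <- A; A2[4, ] <- c(1, 3, 1, 3, 1, 3) * A2[1, ]
  s2 <- summarize_record(manual_beat_matrix(A2, th, E))
  expect_equal(unname(s2$C["3"]), 2)
  expect_equal(unname(s2$C_cv["3"]), sd(c(1, 3, 1, 3, 1, 3)) / 2)

  # phases straddling the branch cut average to +/- pi, not 0
  th3 <- th; th3[5, ] <- c(3.1, -3.1, 3.1, -3.1, 3.1, -3.1)
  s3 <- summarize_record(manual_beat_matrix(A, th3, E))
  expect_equal(abs(unname(s3$P["4"])), pi, tolerance = 1e-6)
  # and the re-branched CV is small (phases are 0.0832 rad apart)
  expect_lt(s3$P_cv["4"], 0.05)

  # fewer than 5 beats is a contract violation
  expect_error(summarize_record(manual_beat_matrix(A[, 1:4], th[, 1:4],
                                                   E[, 1:4])), ">= 5")
  # non-positive beat mean is non-physiological
  A3 <- A; A3[1, 2] <- 0
  expect_error(summarize_record(manual_beat_matrix(A3, th, E)),
               "non-physiological")
})

test_that("record summaries are invariant to positive rescaling", {
  sub <- template_subject(jitter_amp_cv = 0.04, jitter_phase_sd = 0.02,
                          jitter_period_cv = 0.02, noise_sd = 0.005)
  wf <- generate_subject_waveforms(sub, test_acq(duration = 10), seed = 21)
  s1 <- summarize_record(harmonic_beat_matrix(wf$left))
  rec2 <- waveform_record(wf$left$subject_id, "left", 200,
                          3.7 * wf$left$samples)
  s2 <- summarize_record(harmonic_beat_matrix(rec2))
  for (f in c("C", "P", "D", "C_cv", "P_cv", "D_cv"))
    expect_equal(s1[[f]], s2[[f]], tolerance = 1e-9)
})

test_that("inter-hand differences are antisymmetric and wrap phases", {
  sL <- sR <- summarize_record(manual_beat_matrix(
    matrix(rep(c(2, 1, 0.5, rep(0.1, 9)), 6), 12),
    matrix(rep(seq(-3, 3, length.out = 12), 6), 12),
    matrix(rep(c(0.9, rep(0.1 / 11, 11)), 6), 12)))
  sR$C["6"] <- 0.30; sL$C["6"] <- 0.50
  sR$P["4"] <- -3.0; sL$P["4"] <- 3.0
  fv <- inter_hand_differences(sL, sR)
  expect_equal(unname(fv$dC["6"]), 0.20)
  expect_equal(unname(fv$abs_dC["6"]), 0.20)
  # wrapped short-way difference, not 6.0
  expect_equal(unname(fv$dP["4"]), -(2 * pi - 6.0), tolerance = 1e-12)
  expect_equal(unname(fv$abs_dP["4"]), 2 * pi - 6.0, tolerance = 1e-12)

  # swapping hands negates signed entries, leaves absolute ones
  fv2 <- inter_hand_differences(sR, sL)
  for (f in c("dC", "dP", "dD", "dC_cv", "dP_cv", "dD_cv")) {
    expect_equal(fv2[[f]], -fv[[f]], tolerance = 1e-12)
    expect_equal(fv2[[paste0("abs_", f)]], fv[[paste0("abs_", f)]])
    expect_equal(fv[[paste0("abs_", f)]], abs(fv[[f]]))
  }

  sR$subject_id <- "OTHER"
  expect_error(inter_hand_differences(sL, sR), "mismatched subject ids")
})

test_that("noiseless synthetic subjects are recovered to machine precision", {
  tm <- default_beat_template()
  dA <- setNames(numeric(12), 0:11)
  dA[c("3", "6")] <- c(0.02, -0.01)
  sub <- subject_truth("R1", "female", 55, 30, tm$A, tm$theta,
                       asym_amplitudes = dA)
  wf <- generate_subject_waveforms(sub, test_acq(20, heart_rate = 60),
                                   seed = 14)
  for (hand in c("left", "right")) {
    s <- summarize_record(harmonic_beat_matrix(wf[[hand]]))
    gt <- ground_truth_summary(sub, hand)
    expect_equal(s$C, gt$C, tolerance = 1e-6)
    expect_equal(s$D, gt$D, tolerance = 1e-6)
    expect_lt(max(s$C_cv, s$D_cv), 1e-6)
    # phases match up to the beat-alignment ramp: compare the
    # shift-invariant combination theta_n - n * theta_1
    n <- 0:11
    expect_equal(wrap_pi(s$P - n * s$P["1"]),
                 wrap_pi(gt$P - n * gt$P["1"]), tolerance = 1e-6)
  }
})

test_that("feature rows use the documented portable column names", {
  sub <- template_subject(jitter_amp_cv = 0.03, noise_sd = 0.005)
  wf <- generate_subject_waveforms(sub, test_acq(duration = 10), seed = 30)
  row <- feature_row(extract_features(wf$left, wf$right))
  expect_true(all(c("dC1", "dC11", "dP1", "dD0", "dC1CV", "dP1CV", "dD0CV",
                    "absdC1", "absdP11", "absdD11CV") %in% names(row)))
  # order-0 amplitude/phase differences are uninformative and omitted
  expect_false(any(c("dC0", "dP0", "absdC0", "absdP0") %in% names(row)))
  expect_equal(row$absdC6, abs(row$dC6))
  row2 <- feature_row(extract_features(wf$left, wf$right),
                      include_dcv = FALSE)
  expect_false(any(grepl("^(absd|d)D\\d+CV$", names(row2))))
})
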