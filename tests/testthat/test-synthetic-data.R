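test_that("cohort generation reproduces configured composition exactly", {
  cfg <- cohort_config(seed = 11)   # study defaults: 249/99 with 32/13 events
  coh <- generate_cohort(cfg)
  tab <- cohort_table(coh)
  expect_equal(sum(tab$sex == "male"), 249)
  expect_equal(sum(tab$sex == "female"), 99)
  expect_equal(sum(tab$sex == "male" & tab$syntax_score >= 22), 32)
  expect_equal(sum(tab$sex == "female" & tab$syntax_score >= 22), 13)
  expect_true(all(tab$label == (tab$syntax_score >= 22)))
  # non-events stay strictly below the threshold
  expect_true(all(tab$syntax_score[!tab$label] < 22))

  # seeded determinism: byte-identical cohorts
  expect_identical(coh, generate_cohort(cohort_config(seed = 11)))
  # and a different seed actually changes the draw
  expect_false(identical(coh, generate_cohort(cohort_config(seed = 12))))
})

test_that("prevalence mode and config validation behave as documented", {
  cfg <- cohort_config(n_male = 400, n_female = 0, prevalence_male = 0.25,
                       seed = 2)
  tab <- cohort_table(generate_cohort(cfg))
  expect_gt(mean(tab$label), 0.15)
  expect_lt(mean(tab$label), 0.35)

  expect_error(cohort_config(n_events_male = 300), "n_events_male")
  expect_error(cohort_config(prevalence_female = 1.5), "prevalence_female")
  expect_error(cohort_config(syntax_low_range = c(0, 25)),
               "syntax_low_range")
  expect_error(cohort_config(syntax_high_range = c(20, 45)),
               "syntax_high_range")
  expect_error(acquisition_config(sampling_rate = 10), "sampling_rate")
  expect_error(acquisition_config(heart_rate = 250), "heart_rate")
})

test_that("synthesize_beat matches its closed form and round-trips", {
  # single harmonic: A0 = 5, A1 = 2 -> mean 5, peak-to-peak 4
  A <- c(5, 2, rep(0, 10)); th <- c(0, 1, rep(0, 10))
  b <- synthesize_beat(A, th, 256)
  expect_equal(mean(b), 5, tolerance = 1e-12)
  expect_equal(diff(range(b)), 4, tolerance = 1e-4)  # grid may miss the peak

  expect_equal(synthesize_beat(rep(0, 12), rep(0, 12), 64), rep(0, 64))
  expect_error(synthesize_beat(rep(1, 11), rep(0, 11)), "12")
  expect_error(synthesize_beat(rep(1, 13), rep(0, 13)), "12")

  # random admissible parameters round-trip through the analyzer
  set.seed(41)
  for (i in 1:25) {
    A <- c(runif(1, 1, 10), runif(11, 0, 2))
    th <- c(0, runif(11, -pi, pi))
    h <- beat_harmonics(synthesize_beat(A, th, 256))
    expect_lt(max(abs(h$A - A)), 1e-9)
    expect_lt(max(abs(wrap_pi(h$theta - th))), 1e-9)
  }
})

test_that("two-hand generation is symmetric, seeded, and beat-complete", {
  sub <- template_subject()   # zero jitter, noise, asymmetry
  acq <- test_acq(duration = 60, heart_rate = 60)
  wf <- generate_subject_waveforms(sub, acq, seed = 7)
  expect_identical(wf$left$samples, wf$right$samples)
  expect_identical(wf$left$samples,
                   generate_subject_waveforms(sub, acq, seed = 7)$left$samples)

  # 60 s at 60 bpm: segmentation finds 55-60 complete beats
  bs <- segment_beats(wf$left)
  expect_gte(sum(bs$quality_flags), 55)
  expect_lte(sum(bs$quality_flags), 60)

  # records cover the full duration
  expect_equal(length(wf$left$samples),
               acq$duration * acq$sampling_rate)
})

test_that("a configured order-6 amplitude offset drives the sign of dC6", {
  # Monte-Carlo over seeded subjects: the signed left-minus-right
  # amplitude difference must inherit the configured offset sign
  acq <- test_acq(duration = 12)
  tm <- default_beat_template()
  n <- 60
  hits <- 0L
  for (i in seq_len(n)) {
    delta <- sample(c(-1, 1), 1) * 0.25 * tm$A["6"]
    dA <- setNames(numeric(12), 0:11); dA["6"] <- delta
    sub <- subject_truth(sprintf("A%03d", i), "male", 60, 10, tm$A, tm$theta,
                         asym_amplitudes = dA,
                         jitter_amp_cv = 0.05, jitter_phase_sd = 0.03,
                         jitter_period_cv = 0.03, noise_sd = 0.01,
                         drift_amplitude = 0.03)
    wf <- generate_subject_waveforms(sub, acq, seed = 1000 + i)
    fv <- extract_features(wf$left, wf$right)
    hits <- hits + (sign(fv$dC["6"]) == sign(delta))
  }
  expect_gte(hits / n, 0.95)
})

test_that("null asymmetry yields centered signed difference features", {
  # degenerate-at-zero asymmetry: signed deltas have |mean| < 3 SE
  cfg <- cohort_config(n_male = 200, n_female = 0, n_events_male = 30,
                       effect_amplitude = 0, effect_phase = 0, seed = 17)
  coh <- generate_cohort(cfg)
  ft <- extract_cohort_features(coh, test_acq(duration = 12), seed = 17)
  for (v in c("dC2", "dC6", "dD9", "dP8", "dC9CV")) {
    m <- mean(ft[[v]])
    se <- sd(ft[[v]]) / sqrt(nrow(ft))
    expect_lt(abs(m), 3 * se + 1e-12)
  }
})

test_that("default beat template is physiological and band-concentrated", {
  tm <- default_beat_template()
  expect_true(all(tm$A >= 0))
  expect_equal(which.max(tm$A[-1]), 1L, ignore_attr = TRUE) # dominant order 1
  expect_true(all(diff(tm$A[as.character(6:11)]) < 0))      # decay above 6

  spec <- beat_energy_spectrum(beat_morphology((0:255) / 256))
  expect_gte(sum(spec[as.character(0:11)]), 0.98)
  expect_equal(sum(spec), 1, tolerance = 1e-12)
})
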