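#' Acquisition settings for synthetic PPG recordings
#'
#' The source study never states its device's sampling rate or recording
#' length; the defaults here (200 Hz, 60 s — consistent with a one-minute
#' fingertip measurement) are package assumptions, not published values.
#'
#' @param sampling_rate sampling rate in Hz, >= 50.
#' @param duration recording length per hand in seconds, > 0.
#' @param heart_rate mean heart rate in beats per minute, in (30, 200).
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate = 200, duration = 60,
                               heart_rate = 70) {
  check_scalar(sampling_rate, "sampling_rate", lower = 50)
  check_scalar(duration, "duration", lower = 1e-9)
  check_scalar(heart_rate, "heart_rate", lower = 30 + 1e-9, upper = 200 - 1e-9)
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 heart_rate = heart_rate),
            class = "acquisition_config")
}

#' Cohort composition and disease-effect settings
#'
#' Defaults reproduce the composition of the study cohort this package
#' emulates: 249 male subjects with 32 events (SYNTAX score >= 22) and 99
#' female subjects with 13 events, in exact-count mode. Alternatively a
#' per-sex prevalence can be given, in which case event status is drawn
#' per subject.
#'
#' Disease linkage: event subjects receive Gaussian additive asymmetry
#' offsets on the amplitudes of `asym_amp_orders` (SD =
#' `effect_amplitude` times that order's template amplitude) and on the
#' phases of `asym_phase_orders` (SD = `effect_phase` radians);
#' non-event subjects receive the same distributions scaled by
#' `null_fraction` — a baseline physiological inter-hand asymmetry that
#' disease amplifies, so the classes overlap rather than separate
#' trivially. The offset is the target left-minus-right difference and
#' is subtracted from the right hand.
#'
#' @param n_male,n_female subjects per sex stratum.
#' @param n_events_male,n_events_female exact event counts (used unless a
#'   prevalence is supplied).
#' @param prevalence_male,prevalence_female optional event probabilities
#'   in `[0, 1]`; when given they replace the exact counts for that sex.
#' @param syntax_low_range SYNTAX score interval for non-events (entirely
#'   below 22).
#' @param syntax_high_range SYNTAX score interval for events (at or above
#'   22).
#' @param effect_amplitude,effect_phase event effect-size SDs (relative
#'   amplitude units; radians).
#' @param null_fraction scale of non-event offsets relative to event
#'   offsets.
#' @param asym_amp_orders,asym_phase_orders harmonic orders receiving
#'   amplitude / phase offsets.
#' @param jitter_amp_cv beat-to-beat multiplicative amplitude CV
#'   (lognormal, mean 1).
#' @param jitter_phase_sd beat-to-beat phase dispersion, radians
#'   (wrapped normal).
#' @param jitter_period_cv beat-to-beat period CV (lognormal).
#' @param noise_sd additive white-noise SD (waveform units; the default
#'   beat has peak-to-peak amplitude near 1).
#' @param drift_amplitude baseline-wander amplitude (waveform units).
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_male = 249L, n_female = 99L,
                          n_events_male = 32L, n_events_female = 13L,
                          prevalence_male = NULL, prevalence_female = NULL,
                          syntax_low_range = c(0, 21.5),
                          syntax_high_range = c(22, 45),
                          effect_amplitude = 0.3, effect_phase = 0.3,
                          null_fraction = 0.5,
                          asym_amp_orders = c(2L, 3L, 5L, 6L, 9L, 10L),
                          asym_phase_orders = c(1L, 8L, 10L),
                          jitter_amp_cv = 0.05, jitter_phase_sd = 0.03,
                          jitter_period_cv = 0.03,
                          noise_sd = 0.01, drift_amplitude = 0.03,
                          seed = 1L) {
  check_scalar(n_male, "n_male", lower = 0, integer = TRUE)
  check_scalar(n_female, "n_female", lower = 0, integer = TRUE)
  # the study-default event counts only apply to the study-default strata
  if (missing(n_events_male)) n_events_male <- min(n_events_male, n_male)
  if (missing(n_events_female)) n_events_female <- min(n_events_female, n_female)
  check_scalar(n_events_male, "n_events_male", lower = 0,
               upper = n_male, integer = TRUE)
  check_scalar(n_events_female, "n_events_female", lower = 0,
               upper = n_female, integer = TRUE)
  check_scalar(prevalence_male, "prevalence_male", 0, 1, allow_null = TRUE)
  check_scalar(prevalence_female, "prevalence_female", 0, 1, allow_null = TRUE)
  if (length(syntax_low_range) != 2L || any(syntax_low_range >= 22) ||
      syntax_low_range[1] > syntax_low_range[2] || any(syntax_low_range < 0))
    stop("field 'syntax_low_range' must be an interval entirely in [0, 22)")
  if (length(syntax_high_range) != 2L || any(syntax_high_range < 22) ||
      syntax_high_range[1] > syntax_high_range[2])
    stop("field 'syntax_high_range' must be an interval at or above 22")
  check_scalar(effect_amplitude, "effect_amplitude", lower = 0)
  check_scalar(effect_phase, "effect_phase", lower = 0)
  check_scalar(null_fraction, "null_fraction", lower = 0)
  check_scalar(jitter_amp_cv, "jitter_amp_cv", lower = 0)
  check_scalar(jitter_phase_sd, "jitter_phase_sd", lower = 0)
  check_scalar(jitter_period_cv, "jitter_period_cv", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(drift_amplitude, "drift_amplitude", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(as.list(environment()), class = "cohort_config")
}

#' Default PPG beat morphology
#'
#' One period of the default synthetic pulse shape on `t in [0, 1)`: a
#' baseline plus a dominant systolic peak and a smaller, wider dicrotic
#' wave, each a periodized Gaussian bump. The shape is continuous-time;
#' its harmonic content is concentrated in, but not limited to, orders
#' 0--11.
#'
#' @param t numeric vector of phases in beat units (any real; the shape
#'   has period 1).
#' @return waveform values.
#' @export
beat_morphology <- function(t) {
  bump <- function(t, center, width) {
    # periodize: neighbouring periods' tails
    exp(-((t - center) / width)^2) +
      exp(-((t - center - 1) / width)^2) +
      exp(-((t - center + 1) / width)^2)
  }
  0.8 + 1.0 * bump(t %% 1, 0.30, 0.075) + 0.32 * bump(t %% 1, 0.62, 0.115)
}

#' Harmonic template of the default beat
#'
#' Orders 0--11 amplitudes and phases of [beat_morphology()], obtained by
#' discrete Fourier analysis at high resolution. These are the
#' ground-truth left-hand harmonics a synthetic subject starts from.
#'
#' @param n_orders highest order (default 11).
#' @return list with `A` and `theta`, each length `n_orders + 1` and
#'   named by order.
#' @export
default_beat_template <- function(n_orders = 11L) {
  L <- 2048L
  h <- beat_harmonics(beat_morphology((0:(L - 1L)) / L), n_orders = n_orders)
  list(A = stats::setNames(h$A, 0:n_orders),
       theta = stats::setNames(h$theta, 0:n_orders))
}

#' Synthesize one beat from 12 harmonic amplitude/phase pairs
#'
#' Evaluates `f(x) = A0 + sum_{n=1..11} A_n cos(2 pi n x / L - theta_n)`
#' on `x = 0, ..., n_points - 1`. This is the exact inverse of
#' [beat_harmonics()] restricted to orders 0--11.
#'
#' @param amplitudes numeric vector of 12 amplitudes (orders 0--11), all
#'   `>= 0`.
#' @param phases numeric vector of 12 phases in radians (order 0 entry is
#'   ignored).
#' @param n_points samples per beat, `>= 24`.
#' @return numeric vector of length `n_points`.
#' @export
synthesize_beat <- function(amplitudes, phases, n_points = 256L) {
  if (length(amplitudes) != 12L || length(phases) != 12L)
    stop(sprintf("need exactly 12 amplitude/phase pairs (orders 0-11), got %d/%d",
                 length(amplitudes), length(phases)))
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  check_scalar(n_points, "n_points", lower = 24, integer = TRUE)
  x <- 0:(n_points - 1L)
  f <- rep(amplitudes[1L], n_points)
  for (n in 1:11) {
    if (amplitudes[n + 1L] == 0) next
    f <- f + amplitudes[n + 1L] * cos(2 * pi * n * x / n_points - phases[n + 1L])
  }
  f
}

#' Generate a synthetic cohort of subject ground truths
#'
#' Draws per-subject ages, SYNTAX scores, individual harmonic templates
#' (lognormal perturbations of [default_beat_template()]), and
#' disease-linked inter-hand asymmetry offsets, with event counts fixed
#' exactly (exact-count mode) or drawn at a configured prevalence.
#' Deterministic given `config$seed`.
#'
#' @param config a `cohort_config`.
#' @return list of `subject_truth` objects; see [cohort_table()] for the
#'   metadata view.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  tmpl <- default_beat_template()

  make_stratum <- function(sex, n, n_events, prevalence, id0) {
    if (n == 0L) return(list())
    event <- if (!is.null(prevalence)) {
      stats::runif(n) < prevalence
    } else {
      sample(rep(c(TRUE, FALSE), c(n_events, n - n_events)))
    }
    age_mu <- if (sex == "male") 59.80 else 67.52
    lapply(seq_len(n), function(i) {
      age <- round(stats::rnorm(1, age_mu, 9), 1)
      syntax <- if (event[i]) {
        stats::runif(1, config$syntax_high_range[1], config$syntax_high_range[2])
      } else {
        stats::runif(1, config$syntax_low_range[1], config$syntax_low_range[2])
      }
      syntax <- round(2 * syntax) / 2   # two-reader averaged scores step by 0.5

      # subject-specific template: gain + per-order lognormal wobble
      A <- tmpl$A
      A[-1L] <- A[-1L] * exp(stats::rnorm(11, 0, 0.08)) *
        exp(stats::rnorm(1, 0, 0.15))
      theta <- tmpl$theta
      theta[-1L] <- wrap_pi(theta[-1L] + stats::rnorm(11, 0, 0.05))

      scale <- if (event[i]) 1 else config$null_fraction
      dA <- stats::setNames(numeric(12), 0:11)
      dA[as.character(config$asym_amp_orders)] <-
        stats::rnorm(length(config$asym_amp_orders), 0,
                     scale * config$effect_amplitude *
                       A[as.character(config$asym_amp_orders)])
      dtheta <- stats::setNames(numeric(12), 0:11)
      dtheta[as.character(config$asym_phase_orders)] <-
        stats::rnorm(length(config$asym_phase_orders), 0,
                     scale * config$effect_phase)

      subject_truth(
        subject_id = sprintf("S%04d", id0 + i), sex = sex, age = age,
        syntax_score = round(syntax, 1),
        base_amplitudes = A, base_phases = theta,
        asym_amplitudes = dA, asym_phases = dtheta,
        jitter_amp_cv = config$jitter_amp_cv,
        jitter_phase_sd = config$jitter_phase_sd,
        jitter_period_cv = config$jitter_period_cv,
        noise_sd = config$noise_sd,
        drift_amplitude = config$drift_amplitude)
    })
  }

  c(make_stratum("male", config$n_male, config$n_events_male,
                 config$prevalence_male, 0L),
    make_stratum("female", config$n_female, config$n_events_female,
                 config$prevalence_female, config$n_male))
}

#' Construct a subject ground truth
#'
#' The generative model behind one subject's two-hand recordings: the
#' left hand follows `base_amplitudes`/`base_phases`; the right hand uses
#' the base minus the asymmetry offsets (so the offset equals the
#' expected left-minus-right difference), with amplitudes floored at 0.
#'
#' @param subject_id identifier.
#' @param sex `"male"` or `"female"`.
#' @param age years.
#' @param syntax_score non-negative SYNTAX score.
#' @param base_amplitudes,base_phases length-12 ground-truth left-hand
#'   harmonics (orders 0--11).
#' @param asym_amplitudes,asym_phases length-12 additive offsets.
#' @param jitter_amp_cv,jitter_phase_sd,jitter_period_cv beat-to-beat
#'   variability parameters, all `>= 0`.
#' @param noise_sd,drift_amplitude waveform noise and baseline-wander
#'   scales, `>= 0`.
#' @return object of class `subject_truth`.
#' @export
subject_truth <- function(subject_id, sex, age, syntax_score,
                          base_amplitudes, base_phases,
                          asym_amplitudes = numeric(12),
                          asym_phases = numeric(12),
                          jitter_amp_cv = 0, jitter_phase_sd = 0,
                          jitter_period_cv = 0, noise_sd = 0,
                          drift_amplitude = 0) {
  sex <- match.arg(sex, c("male", "female"))
  check_scalar(age, "age", lower = 0)
  check_scalar(syntax_score, "syntax_score", lower = 0)
  if (length(base_amplitudes) != 12L || length(base_phases) != 12L)
    stop("base_amplitudes/base_phases must have length 12 (orders 0-11)")
  if (any(base_amplitudes < 0)) stop("field 'base_amplitudes' must be >= 0")
  for (f in c("jitter_amp_cv", "jitter_phase_sd", "jitter_period_cv",
              "noise_sd", "drift_amplitude"))
    check_scalar(get(f), f, lower = 0)
  structure(list(
    subject_id = as.character(subject_id), sex = sex, age = age,
    syntax_score = syntax_score, label = syntax_score >= 22,
    base_amplitudes = stats::setNames(base_amplitudes, 0:11),
    base_phases = stats::setNames(wrap_pi(base_phases), 0:11),
    asym_amplitudes = stats::setNames(asym_amplitudes, 0:11),
    asym_phases = stats::setNames(asym_phases, 0:11),
    jitter_amp_cv = jitter_amp_cv, jitter_phase_sd = jitter_phase_sd,
    jitter_period_cv = jitter_period_cv, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude),
    class = "subject_truth")
}

# per-hand harmonics implied by a subject truth
hand_harmonics <- function(subject, hand) {
  if (hand == "left") {
    list(A = subject$base_amplitudes, theta = subject$base_phases)
  } else {
    list(A = pmax(subject$base_amplitudes - subject$asym_amplitudes, 0),
         theta = wrap_pi(subject$base_phases - subject$asym_phases))
  }
}

#' Generate the two-hand waveform pair for one subject
#'
#' Concatenates beats with beat-to-beat jittered periods, amplitudes and
#' phases; both hands share the same cardiac jitter realizations (one
#' heart drives both), while additive white noise and slow baseline
#' drift are drawn independently per hand. The record starts mid-beat
#' and is trimmed to the exact duration, so partial edge beats exist for
#' the segmenter to discard. Deterministic given `seed`.
#'
#' @param subject a `subject_truth`.
#' @param acq an `acquisition_config`.
#' @param seed integer seed for this subject's randomness.
#' @return list with elements `left` and `right`, both `waveform_record`s.
#' @export
generate_subject_waveforms <- function(subject, acq, seed = 1L) {
  stopifnot(inherits(subject, "subject_truth"),
            inherits(acq, "acquisition_config"))
  set.seed(seed)
  fs <- acq$sampling_rate
  n_total <- as.integer(round(acq$duration * fs))
  base_period <- 60 / acq$heart_rate
  n_beats <- ceiling(acq$duration / base_period * 1.3) + 3L

  # shared cardiac realizations
  sdlog <- sqrt(log(1 + subject$jitter_period_cv^2))
  periods <- base_period * exp(stats::rnorm(n_beats, -sdlog^2 / 2, sdlog))
  sdlog_a <- sqrt(log(1 + subject$jitter_amp_cv^2))
  gains <- exp(stats::rnorm(n_beats, -sdlog_a^2 / 2, sdlog_a))
  dphase <- matrix(stats::rnorm(n_beats * 11, 0, subject$jitter_phase_sd),
                   n_beats, 11)
  start_skip <- stats::runif(1, 0.1, 0.9)   # start mid-beat (partial beat)

  one_hand <- function(hand) {
    h <- hand_harmonics(subject, hand)
    segs <- vector("list", n_beats)
    for (m in seq_len(n_beats)) {
      np <- max(24L, as.integer(round(periods[m] * fs)))
      A <- h$A
      A[-1L] <- A[-1L] * gains[m]
      th <- h$theta
      th[-1L] <- wrap_pi(th[-1L] + dphase[m, ])
      segs[[m]] <- synthesize_beat(A, th, np)
    }
    x <- unlist(segs, use.names = FALSE)
    x <- x[-seq_len(as.integer(start_skip * length(segs[[1L]])))]
    if (length(x) < n_total)
      stop("internal: synthesized fewer samples than requested")
    x <- x[seq_len(n_total)]
    t <- (seq_len(n_total) - 1L) / fs
    if (subject$drift_amplitude > 0) {
      fd <- stats::runif(1, 0.05, 0.15)
      x <- x + subject$drift_amplitude * sin(2 * pi * fd * t +
                                             stats::runif(1, 0, 2 * pi))
    }
    if (subject$noise_sd > 0)
      x <- x + stats::rnorm(n_total, 0, subject$noise_sd)
    waveform_record(subject$subject_id, hand, fs, x)
  }
  list(left = one_hand("left"), right = one_hand("right"))
}

#' Ground-truth record-level summary implied by a subject truth
#'
#' The noiseless, jitter-free harmonic summary the analysis pipeline
#' should recover for one hand: `C[n] = A[n]/A[0]`, `P[n] = theta[n]`,
#' `D[n]` the Parseval energy fraction of the 12-order beat, all CVs 0.
#' Note the recovered phases differ from `P` by a linear-in-order ramp
#' `2 pi n s / L` fixed by where the segmenter places the beat foot;
#' shift-invariant comparisons should use `P[n] - n * P[1]`.
#'
#' @param subject a `subject_truth`.
#' @param hand `"left"` or `"right"`.
#' @return a `harmonic_summary`-like list (without beat count).
#' @export
ground_truth_summary <- function(subject, hand = c("left", "right")) {
  hand <- match.arg(hand)
  h <- hand_harmonics(subject, hand)
  pw <- h$A[1L]^2 + sum(h$A[-1L]^2 / 2)
  E <- c(h$A[1L]^2, h$A[-1L]^2 / 2) / pw
  z <- stats::setNames(numeric(12), 0:11)
  structure(list(C = h$A / h$A[1L], P = stats::setNames(wrap_pi(h$theta), 0:11),
                 D = stats::setNames(E, 0:11),
                 C_cv = z, P_cv = z, D_cv = z,
                 subject_id = subject$subject_id, hand = hand),
            class = "harmonic_summary")
}

#' Metadata table of a generated cohort
#'
#' @param cohort list of `subject_truth` objects.
#' @return data frame with `subject_id`, `sex`, `age`, `syntax_score`,
#'   `label`.
#' @export
cohort_table <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    sex = vapply(cohort, `[[`, character(1), "sex"),
    age = vapply(cohort, `[[`, numeric(1), "age"),
    syntax_score = vapply(cohort, `[[`, numeric(1), "syntax_score"),
    label = vapply(cohort, `[[`, logical(1), "label"),
    stringsAsFactors = FALSE)
}
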