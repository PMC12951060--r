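#' Harmonic decomposition of a single pulse beat
#'
#' Decomposes one fixed-length beat into harmonic orders 0--11 of the beat
#' fundamental, in the convention
#' \deqn{f(x) = A_0 + \sum_{n=1}^{11} A_n \cos(2\pi n x / L - \theta_n),}
#' so that \eqn{A_0} is the beat mean and each \eqn{\theta_n} acts as a
#' delay. Energy fractions use Parseval's theorem on the discrete
#' spectrum: the order-0 energy is \eqn{A_0^2}, order \eqn{n \ge 1}
#' energy is \eqn{A_n^2/2}, each divided by the total power
#' \eqn{\mathrm{mean}(f^2)}.
#'
#' @param beat numeric vector, one beat resampled onto a uniform grid
#'   covering exactly one period; length `L >= 24`.
#' @param n_orders highest harmonic order retained (default 11).
#' @return list with `A` (length `n_orders + 1`, orders 0..n_orders),
#'   `theta` (same length; `theta[1]`, i.e. order 0, is always 0), `E`
#'   (energy fractions per order), `degenerate` (TRUE for a constant
#'   beat, where phases are reported as 0).
#' @export
beat_harmonics <- function(beat, n_orders = 11L) {
  if (!is.numeric(beat) || anyNA(beat))
    stop("beat must be a numeric vector without missing values")
  L <- length(beat)
  if (L < 24L) stop(sprintf("beat length %d < 24", L))
  if (n_orders >= L / 2)
    stop(sprintf("n_orders = %d requires beat length > %d", n_orders,
                 2L * n_orders))

  F <- stats::fft(beat)
  A0 <- Re(F[1L]) / L
  n <- seq_len(n_orders)
  # f = A cos(2*pi*n*x/L - theta) has DFT bin n equal to (A*L/2) e^{-i theta}
  A <- c(A0, 2 * Mod(F[n + 1L]) / L)
  theta <- c(0, wrap_pi(-Arg(F[n + 1L])))

  total_power <- mean(beat^2)
  degenerate <- max(A[-1L]) < 1e-12 * max(abs(A0), 1e-300)
  if (degenerate) theta[] <- 0
  if (total_power < 1e-300) {
    E <- rep(0, n_orders + 1L)
  } else {
    E <- c(A0^2, A[-1L]^2 / 2) / total_power
  }
  list(A = A, theta = theta, E = E, degenerate = degenerate)
}

#' Full-spectrum per-order energy fractions of a beat
#'
#' Parseval decomposition of the complete discrete spectrum of one beat:
#' for a beat of length L, orders 0..floor(L/2) carry all the signal
#' power, and the returned fractions sum to 1 exactly. Used to check how
#' much energy the orders 0--11 truncation retains.
#'
#' @param beat numeric vector (one period on a uniform grid).
#' @return numeric vector of energy fractions, names `"0"`, `"1"`, ...,
#'   `"floor(L/2)"`.
#' @export
beat_energy_spectrum <- function(beat) {
  L <- length(beat)
  F <- stats::fft(beat) / L
  half <- floor(L / 2)
  pw <- numeric(half + 1L)
  pw[1L] <- Mod(F[1L])^2
  if (half >= 1L) {
    n <- seq_len(half)
    pw[n + 1L] <- 2 * Mod(F[n + 1L])^2
    if (L %% 2L == 0L) pw[half + 1L] <- Mod(F[half + 1L])^2  # Nyquist bin
  }
  tot <- mean(beat^2)
  names(pw) <- as.character(0:half)
  if (tot < 1e-300) return(pw * 0)
  pw / tot
}

#' Per-beat harmonic matrix of a waveform record
#'
#' Segments a record into beats, resamples each accepted beat onto a
#' fixed-length grid and decomposes it into harmonics, yielding the
#' amplitude/phase/energy matrices that record-level indices summarize.
#'
#' @param record a `waveform_record`.
#' @param beat_length points per resampled beat (default 256).
#' @param min_beats minimum accepted beats required (default 5).
#' @param n_orders highest harmonic order (default 11).
#' @param resample_method `"fourier"` (band-limited) or `"spline"`.
#' @return object of class `harmonic_beat_matrix`: list with `A`, `theta`,
#'   `E` (matrices `(n_orders+1) x M`, rows named `"0"`.. and columns per
#'   accepted beat), `M` (accepted beat count), `periods` (seconds).
#' @export
harmonic_beat_matrix <- function(record, beat_length = 256L, min_beats = 5L,
                                 n_orders = 11L,
                                 resample_method = c("fourier", "spline")) {
  resample_method <- match.arg(resample_method)
  beats <- segment_beats(record, min_beats = min_beats)
  acc <- which(beats$quality_flags)
  M <- length(acc)
  A <- theta <- E <- matrix(NA_real_, n_orders + 1L, M,
                            dimnames = list(as.character(0:n_orders), NULL))
  for (j in seq_along(acc)) {
    b <- resample_beat(beats$beats[[acc[j]]], beat_length,
                       method = resample_method)
    h <- beat_harmonics(b, n_orders = n_orders)
    A[, j] <- h$A
    theta[, j] <- h$theta
    E[, j] <- h$E
  }
  structure(list(A = A, theta = theta, E = E, M = M,
                 periods = beats$periods[acc],
                 subject_id = record$subject_id, hand = record$hand),
            class = "harmonic_beat_matrix")
}

#' Record-level harmonic indices Cn, Pn, Dn and their CVs
#'
#' Summarizes a per-beat harmonic matrix into the record-level indices:
#' per beat m the amplitudes are normalized by the beat mean,
#' `a(n,m) = A(n,m)/A(0,m)`, making the indices dimensionless and
#' insensitive to sensor gain. Then
#' * `C[n]` = mean over beats of `a(n, .)` (so `C[0] = 1` by construction),
#' * `P[n]` = circular mean over beats of `theta(n, .)`,
#' * `D[n]` = mean over beats of the energy fraction `E(n, .)`,
#' * `C_cv[n]`, `D_cv[n]` = sample SD / mean of the per-beat series,
#' * `P_cv[n]` = sample SD / |circular mean| after re-branching each phase
#'   to within `pi` of the circular mean (a plain linear CV is ill-defined
#'   for circular data).
#'
#' @param mat a `harmonic_beat_matrix` with at least 5 accepted beats.
#' @return object of class `harmonic_summary`: list of numeric vectors
#'   `C`, `P`, `D`, `C_cv`, `P_cv`, `D_cv` (named by order 0..n), plus
#'   `M`, `subject_id`, `hand`, and `p_cv_flags` marking orders where the
#'   circular-mean denominator of `P_cv` is numerically zero.
#' @export
summarize_record <- function(mat) {
  stopifnot(inherits(mat, "harmonic_beat_matrix"))
  if (mat$M < 5L)
    stop(sprintf("need >= 5 accepted beats to summarize, got %d", mat$M))
  if (any(mat$A["0", ] <= 0))
    stop("non-physiological record: some beat mean A(0,m) <= 0")

  a <- sweep(mat$A, 2L, mat$A["0", ], "/")
  n_all <- nrow(mat$A)
  orders <- rownames(mat$A)

  cv_lin <- function(x) {
    m <- mean(x)
    if (abs(m) < 1e-12) return(if (stats::sd(x) < 1e-12) 0 else NA_real_)
    stats::sd(x) / abs(m)
  }

  C <- apply(a, 1L, mean)
  D <- apply(mat$E, 1L, mean)
  C_cv <- apply(a, 1L, cv_lin)
  D_cv <- apply(mat$E, 1L, cv_lin)

  P <- numeric(n_all)
  P_cv <- numeric(n_all)
  p_flag <- logical(n_all)
  for (i in seq_len(n_all)) {
    if (orders[i] == "0") { P[i] <- 0; P_cv[i] <- 0; next }
    th <- mat$theta[i, ]
    mu <- circular_mean(th)
    P[i] <- mu
    # re-branch each phase to within pi of the circular mean, then linear CV
    reb <- mu + wrap_pi(th - mu)
    if (abs(mu) < 1e-6) {
      p_flag[i] <- TRUE
      P_cv[i] <- if (stats::sd(reb) < 1e-12) 0 else stats::sd(reb) / 1e-6
    } else {
      P_cv[i] <- stats::sd(reb) / abs(mu)
    }
  }
  nm <- function(x) stats::setNames(x, orders)
  structure(list(C = nm(C), P = nm(P), D = nm(D),
                 C_cv = nm(C_cv), P_cv = nm(P_cv), D_cv = nm(D_cv),
                 p_cv_flags = nm(p_flag), M = mat$M,
                 subject_id = mat$subject_id, hand = mat$hand),
            class = "harmonic_summary")
}

#' Signed and absolute inter-hand harmonic differences
#'
#' Left-minus-right differences of every record-level index, the feature
#' set used to predict lesion severity. Phase differences are wrapped to
#' the principal branch `(-pi, pi]` before the absolute value is taken,
#' so hands whose phases straddle the branch cut (+3.0 vs -3.0 rad)
#' yield the short-way difference.
#'
#' @param left,right `harmonic_summary` objects for the two hands of the
#'   same subject.
#' @return object of class `feature_vector`: list with signed components
#'   `dC`, `dP`, `dD`, `dC_cv`, `dP_cv`, `dD_cv` and absolute
#'   counterparts `abs_dC`, ... (each named by harmonic order), plus
#'   `subject_id`.
#' @export
inter_hand_differences <- function(left, right) {
  stopifnot(inherits(left, "harmonic_summary"),
            inherits(right, "harmonic_summary"))
  if (!is.null(left$subject_id) && !is.null(right$subject_id) &&
      !identical(left$subject_id, right$subject_id))
    stop(sprintf("mismatched subject ids: '%s' vs '%s'",
                 left$subject_id, right$subject_id))

  out <- list(
    dC = left$C - right$C,
    dP = wrap_pi(left$P - right$P),
    dD = left$D - right$D,
    dC_cv = left$C_cv - right$C_cv,
    dP_cv = left$P_cv - right$P_cv,
    dD_cv = left$D_cv - right$D_cv
  )
  abs_out <- lapply(out, abs)
  names(abs_out) <- paste0("abs_", names(out))
  structure(c(out, abs_out, list(subject_id = left$subject_id)),
            class = "feature_vector")
}

#' Flatten a feature vector to a named one-row data frame
#'
#' Column names follow the portable scheme used throughout: the Greek
#' difference symbol maps to a `d` prefix and the absolute value to
#' `absd`, e.g. `dC6` for the signed order-6 amplitude difference,
#' `absdC9CV` for the absolute order-9 amplitude-CV difference. Order 0
#' amplitude and phase columns are omitted (C0 is 1 and P0 is 0 by
#' construction, so their differences carry no information); the order-0
#' energy column `dD0` is kept.
#'
#' @param fv a `feature_vector`.
#' @param include_dcv include the energy-CV (`DnCV`) columns (default TRUE).
#' @return one-row `data.frame` with a leading `subject_id` column.
#' @export
feature_row <- function(fv, include_dcv = TRUE) {
  stopifnot(inherits(fv, "feature_vector"))
  pick <- function(x, base, suffix = "", drop0 = TRUE) {
    ord <- names(x)
    if (drop0) { keep <- ord != "0"; x <- x[keep]; ord <- ord[keep] }
    stats::setNames(as.list(unname(x)), paste0(base, ord, suffix))
  }
  cols <- c(
    pick(fv$dC, "dC"), pick(fv$dP, "dP"), pick(fv$dD, "dD", drop0 = FALSE),
    pick(fv$dC_cv, "dC", "CV"), pick(fv$dP_cv, "dP", "CV"),
    if (include_dcv) pick(fv$dD_cv, "dD", "CV", drop0 = FALSE),
    pick(fv$abs_dC, "absdC"), pick(fv$abs_dP, "absdP"),
    pick(fv$abs_dD, "absdD", drop0 = FALSE),
    pick(fv$abs_dC_cv, "absdC", "CV"), pick(fv$abs_dP_cv, "absdP", "CV"),
    if (include_dcv) pick(fv$abs_dD_cv, "absdD", "CV", drop0 = FALSE)
  )
  cbind(data.frame(subject_id = fv$subject_id %||% NA_character_,
                   stringsAsFactors = FALSE),
        as.data.frame(cols, check.names = FALSE))
}

#' Extract inter-hand harmonic features for one subject
#'
#' Convenience wrapper: per-beat harmonic matrices and record summaries
#' for both hands, then their inter-hand differences.
#'
#' @param left,right `waveform_record`s for the two hands.
#' @inheritParams harmonic_beat_matrix
#' @return a `feature_vector`.
#' @export
extract_features <- function(left, right, beat_length = 256L,
                             min_beats = 5L, n_orders = 11L,
                             resample_method = "fourier") {
  sl <- summarize_record(harmonic_beat_matrix(
    left, beat_length, min_beats, n_orders, resample_method))
  sr <- summarize_record(harmonic_beat_matrix(
    right, beat_length, min_beats, n_orders, resample_method))
  inter_hand_differences(sl, sr)
}
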