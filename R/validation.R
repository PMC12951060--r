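#' ROC curve points
#'
#' Empirical ROC: one `(FPR, TPR)` point per distinct score threshold,
#' from `(0, 0)` to `(1, 1)`, monotone nondecreasing in both coordinates.
#' Tied scores collapse onto a single point, so trapezoidal integration
#' of this curve handles ties exactly like pairwise concordance with
#' half-credit.
#'
#' @param scores numeric predictions (higher = more event-like).
#' @param labels logical or 0/1 outcomes, both classes present.
#' @return data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, labels) {
  y <- as.numeric(labels)
  if (anyNA(scores) || anyNA(y)) stop("scores/labels must not contain NA")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  # cumulative counts at each distinct threshold (descending)
  last <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
             threshold = c(Inf, s[last]))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the empirical ROC curve, which equals the
#' Mann-Whitney pairwise concordance (ties between an event and a
#' non-event score counting 1/2).
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are ranked by predicted probability into `n_groups`
#' equal-count groups (ties assigned to the lower group); the statistic is
#' \deqn{\sum_g (O_g - E_g)^2 / (n_g \bar\pi_g (1 - \bar\pi_g))}
#' with `O_g` observed events, `E_g = n_g * mean predicted`, referred to a
#' chi-square with `n_groups - 2` degrees of freedom (in-sample
#' convention).
#'
#' @param probabilities predicted event probabilities in `[0, 1]`.
#' @param labels logical or 0/1 outcomes.
#' @param n_groups number of risk groups (default 10); requires
#'   `n >= 2 * n_groups`.
#' @return list with `statistic`, `df`, `p`, `groups` (per-group summary
#'   data frame) and `flagged_groups` (groups whose mean probability hit
#'   0 or 1 and were guarded with eps = 1e-10).
#' @export
hosmer_lemeshow <- function(probabilities, labels, n_groups = 10L) {
  y <- as.numeric(labels)
  p <- as.numeric(probabilities)
  n <- length(p)
  if (n != length(y)) stop("probabilities and labels differ in length")
  if (n < 2L * n_groups)
    stop(sprintf("need n >= %d for %d groups, got %d", 2L * n_groups,
                 n_groups, n))
  # rank into equal-count groups; ties go to the lower group via first-rank
  r <- rank(p, ties.method = "first")
  g <- ceiling(r * n_groups / n)
  eps <- 1e-10
  tab <- do.call(rbind, lapply(seq_len(n_groups), function(j) {
    idx <- g == j
    pi_bar <- mean(p[idx])
    data.frame(group = j, n = sum(idx), observed = sum(y[idx]),
               expected = sum(p[idx]), pi_bar = pi_bar)
  }))
  flagged <- tab$group[tab$pi_bar <= 0 | tab$pi_bar >= 1]
  denom <- tab$n * pmin(pmax(tab$pi_bar, eps), 1 - eps) *
    (1 - pmin(pmax(tab$pi_bar, eps), 1 - eps))
  statistic <- sum((tab$observed - tab$expected)^2 / denom)
  df <- n_groups - 2L
  list(statistic = statistic, df = df,
       p = stats::pchisq(statistic, df, lower.tail = FALSE),
       groups = tab, flagged_groups = flagged)
}

#' Calibration curve by predicted-risk deciles
#'
#' @inheritParams hosmer_lemeshow
#' @param n_bins number of groups (default 10).
#' @return data frame with one row per non-empty group: `predicted` (mean
#'   predicted probability) and `observed` (event rate).
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10L) {
  y <- as.numeric(labels)
  p <- as.numeric(probabilities)
  n <- length(p)
  r <- rank(p, ties.method = "first")
  g <- ceiling(r * n_bins / n)
  out <- do.call(rbind, lapply(sort(unique(g)), function(j) {
    idx <- g == j
    data.frame(bin = j, n = sum(idx), predicted = mean(p[idx]),
               observed = mean(y[idx]))
  }))
  # constant predictions collapse to a single point
  unique_p <- length(unique(p)) == 1L
  if (unique_p) out <- data.frame(bin = 1L, n = n, predicted = p[1L],
                                  observed = mean(y))
  out
}

#' Bootstrap internal validation of a selected model
#'
#' For each resample: draw `n` subjects with replacement, refit the
#' coefficients on the fixed selected-variable set, and score the
#' original sample, recording the AUC. Resamples containing a single
#' outcome class are redrawn (and counted); separated resample fits are
#' used with capped coefficients rather than discarded. Reports the mean
#' resample AUC and the 2.5/97.5 percentile interval. Deterministic
#' given `seed`.
#'
#' @param features data frame with the selected predictor columns.
#' @param labels logical or 0/1 outcomes.
#' @param selected_variables character vector of predictor names (fixed;
#'   no re-selection inside resamples).
#' @param n_resamples number of bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return list with `mean_auc`, `ci` (percentile 95% interval),
#'   `n_resamples`, `aucs`, `n_redrawn`, `n_separated`; warns when more
#'   than 10% of resamples were degenerate (redrawn).
#' @export
bootstrap_validate <- function(features, labels, selected_variables,
                               n_resamples = 2000L, seed = 1L) {
  y <- as.numeric(labels)
  n <- length(y)
  X <- features[, selected_variables, drop = FALSE]
  set.seed(seed)
  aucs <- numeric(n_resamples)
  n_redrawn <- 0L
  n_separated <- 0L
  for (b in seq_len(n_resamples)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    fit <- fit_logistic(X[idx, , drop = FALSE], y[idx],
                        on_separation = "warn")
    if (fit$separation) n_separated <- n_separated + 1L
    eta <- fit$coefficients[1L] +
      drop(as.matrix(X) %*% fit$coefficients[-1L])
    aucs[b] <- auc(eta, y)
  }
  if (n_redrawn > 0.1 * n_resamples)
    warning(sprintf("%d degenerate resamples redrawn (> 10%% of %d)",
                    n_redrawn, n_resamples), call. = FALSE)
  list(mean_auc = mean(aucs),
       ci = stats::quantile(aucs, c(0.025, 0.975), names = FALSE),
       n_resamples = n_resamples, aucs = aucs,
       n_redrawn = n_redrawn, n_separated = n_separated)
}

#' Full validation report for a fitted model
#'
#' Discrimination (apparent AUC with ROC points), calibration
#' (Hosmer-Lemeshow and the decile calibration curve) and bootstrap
#' internal validation in one object.
#'
#' @param model a `fitted_model`.
#' @param features data frame containing the model's predictor columns.
#' @param labels outcomes used to fit the model.
#' @param n_resamples bootstrap resamples (default 2000).
#' @param n_groups Hosmer-Lemeshow / calibration groups (default 10).
#' @param seed integer seed for the bootstrap.
#' @return object of class `validation_report`.
#' @export
validate_model <- function(model, features, labels, n_resamples = 2000L,
                           n_groups = 10L, seed = 1L) {
  stopifnot(inherits(model, "fitted_model"))
  X <- features[, model$variables, drop = FALSE]
  eta <- model$coefficients[1L] +
    (if (length(model$variables))
       drop(as.matrix(X) %*% model$coefficients[-1L]) else 0)
  prob <- stats::plogis(eta)
  roc <- roc_points(prob, labels)
  boot <- bootstrap_validate(features, labels, model$variables,
                             n_resamples = n_resamples, seed = seed)
  hl <- hosmer_lemeshow(prob, labels, n_groups = n_groups)
  structure(list(
    auc = auc(prob, labels), roc_points = roc,
    hl_statistic = hl$statistic, hl_df = hl$df, hl_p = hl$p,
    bootstrap_mean_auc = boot$mean_auc, bootstrap_ci = boot$ci,
    n_resamples = boot$n_resamples,
    n_redrawn = boot$n_redrawn, n_separated = boot$n_separated,
    calibration_points = calibration_curve(prob, labels, n_bins = n_groups)),
    class = "validation_report")
}
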