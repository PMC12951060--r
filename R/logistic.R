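#' Fit a logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm.fit`)
#' with an intercept, returning the coefficient table the study reports:
#' coefficient, standard error, Wald t statistic and two-sided normal P
#' value per term, plus the log-likelihood and AIC (`2k - 2*logLik`, k
#' counting the intercept). Complete separation is detected explicitly
#' (the fitted linear predictor perfectly ranks events above non-events
#' while probabilities saturate) rather than left as a silent divergence,
#' and a rank-deficient design is an error naming the collinear columns.
#'
#' @param features data frame or numeric matrix of predictors (no
#'   missing values); an intercept is always added.
#' @param labels logical or 0/1 vector with at least one event and one
#'   non-event.
#' @param on_separation `"error"` (default) to stop on complete
#'   separation, or `"warn"` to return the capped IRLS fit with a
#'   `separation` flag.
#' @return object of class `fitted_model`: list with `coefficients`,
#'   `standard_errors`, `t_statistics`, `p_values` (named vectors with
#'   `(Intercept)` first), `log_likelihood`, `aic`, `k`, `n`, `n_events`,
#'   `converged`, `separation`, `variables`.
#' @export
fit_logistic <- function(features, labels,
                         on_separation = c("error", "warn")) {
  on_separation <- match.arg(on_separation)
  y <- as.numeric(labels)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("labels must be logical or 0/1 with no missing values")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one event and one non-event")

  if (is.null(features) || (is.data.frame(features) && ncol(features) == 0L)) {
    X <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xv <- as.matrix(features)
    if (!is.numeric(Xv) || anyNA(Xv))
      stop("features must be numeric with no missing values")
    if (nrow(Xv) != length(y)) stop("features and labels differ in length")
    X <- cbind(`(Intercept)` = 1, Xv)
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("singular design: collinear columns %s",
                 paste(aliased, collapse = ", ")))
  }

  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100L)))
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)

  # separation: if the fitted linear predictor strictly ranks every event
  # above every non-event, rescaling the coefficients increases the
  # likelihood without bound, so the ML estimate does not exist
  separated <- min(eta[y == 1]) > max(eta[y == 0])
  if (separated && on_separation == "error")
    stop("separation: a linear combination of predictors perfectly separates events from non-events")

  eps <- 1e-12
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  W <- p * (1 - p)
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  })
  se <- sqrt(diag(cov))
  t_stat <- beta / se
  p_val <- 2 * stats::pnorm(-abs(t_stat))
  k <- ncol(X)

  structure(list(
    coefficients = beta, standard_errors = se, t_statistics = t_stat,
    p_values = p_val, log_likelihood = ll, aic = 2 * k - 2 * ll, k = k,
    n = length(y), n_events = sum(y),
    converged = fit$converged && !separated, separation = separated,
    variables = setdiff(colnames(X), "(Intercept)")),
    class = "fitted_model")
}

#' AIC of a fitted model
#'
#' `2k - 2 * logLik`, with k the number of estimated parameters including
#' the intercept. Verifies the stored AIC is consistent with the stored
#' log-likelihood before returning it.
#'
#' @param model a `fitted_model`.
#' @return the AIC.
#' @export
aic_of <- function(model) {
  stopifnot(inherits(model, "fitted_model"))
  expect <- 2 * model$k - 2 * model$log_likelihood
  if (abs(expect - model$aic) > 1e-8)
    stop("inconsistent model: stored AIC does not match 2k - 2*logLik")
  model$aic
}

#' Events-per-variable adequacy advisory
#'
#' The conventional 1:10 rule for logistic regression: flags (but never
#' blocks) models estimating more than one parameter per ten outcome
#' events.
#'
#' @param n_events number of outcome events.
#' @param n_params number of candidate/estimated parameters (excluding
#'   the intercept).
#' @return list with `ok` (logical) and `message`; emits a warning when
#'   not ok.
#' @export
epv_check <- function(n_events, n_params) {
  if (n_events <= 0) {
    msg <- "no events in stratum; events-per-variable undefined"
    warning(msg, call. = FALSE)
    return(list(ok = FALSE, message = msg, epv = NA_real_))
  }
  epv <- n_events / max(n_params, 1)
  if (n_params > n_events / 10) {
    msg <- sprintf(
      "events-per-variable advisory: %d parameters exceed %d events / 10 = %.1f (EPV = %.1f < 10)",
      n_params, n_events, n_events / 10, epv)
    warning(msg, call. = FALSE)
    list(ok = FALSE, message = msg, epv = epv)
  } else {
    list(ok = TRUE,
         message = sprintf("events-per-variable adequate (EPV = %.1f)", epv),
         epv = epv)
  }
}

#' Simulate a logistic-model cohort with known coefficients
#'
#' Direct feature-level simulation used for selection and coverage
#' studies: standard-normal predictors and Bernoulli labels from a known
#' linear predictor.
#'
#' @param n subjects.
#' @param beta named numeric vector of true coefficients (per SD of the
#'   predictor, since predictors are standard normal).
#' @param intercept true intercept.
#' @param n_null additional independent null predictors appended after
#'   the true ones.
#' @param seed integer seed.
#' @return list with `features` (data frame) and `labels` (0/1 vector).
#' @export
simulate_logistic_cohort <- function(n, beta, intercept = 0, n_null = 0L,
                                     seed = 1L) {
  set.seed(seed)
  p_true <- length(beta)
  X <- matrix(stats::rnorm(n * (p_true + n_null)), n)
  nm <- c(names(beta) %||% paste0("x", seq_len(p_true)),
          if (n_null > 0L) paste0("null", seq_len(n_null)))
  colnames(X) <- nm
  eta <- intercept + drop(X[, seq_len(p_true), drop = FALSE] %*% beta)
  y <- as.numeric(stats::runif(n) < stats::plogis(eta))
  list(features = as.data.frame(X), labels = y)
}
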