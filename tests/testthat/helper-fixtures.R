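# shared fixtures: everything is generated in code, no stored data

# a clean subject: default template, optional overrides
template_subject <- function(id = "T001", sex = "male", syntax = 10, ...) {
  tm <- default_beat_template()
  subject_truth(id, sex, 60, syntax, tm$A, tm$theta, ...)
}

# short acquisition used throughout the unit tests to keep runtimes low
test_acq <- function(duration = 15, heart_rate = 70, sampling_rate = 200) {
  acquisition_config(sampling_rate = sampling_rate, duration = duration,
                     heart_rate = heart_rate)
}

# brute-force pairwise-concordance AUC (independent oracle)
auc_brute <- function(scores, labels) {
  y <- as.numeric(labels)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# direct numerical maximization of the written logistic log-likelihood
# (independent of the IRLS path in fit_logistic)
logistic_ml_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    -sum(y * stats::plogis(eta, log.p = TRUE) +
           (1 - y) * stats::plogis(-eta, log.p = TRUE))
  }
  stats::optim(numeric(ncol(X1)), nll, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))$par
}

# a harmonic_beat_matrix built directly from per-beat A/theta/E values
manual_beat_matrix <- function(A, theta = NULL, E = NULL) {
  M <- ncol(A)
  if (is.null(theta)) theta <- matrix(0, nrow(A), M)
  if (is.null(E)) E <- matrix(0, nrow(A), M)
  rownames(A) <- rownames(theta) <- rownames(E) <- 0:(nrow(A) - 1L)
  structure(list(A = A, theta = theta, E = E, M = M,
                 periods = rep(1, M), subject_id = "M001", hand = "left"),
            class = "harmonic_beat_matrix")
}
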