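test_that("logistic fits match closed forms and the likelihood oracle", {
  # intercept-only closed forms: log(p / (1 - p))
  expect_equal(unname(fit_logistic(NULL, c(1, 0, 1, 0))$coefficients), 0,
               tolerance = 1e-8)
  expect_equal(unname(fit_logistic(NULL, c(1, 1, 1, 0))$coefficients),
               log(3), tolerance = 1e-8)
  f <- fit_logistic(NULL, c(1, 0))
  expect_equal(f$log_likelihood, 2 * log(0.5), tolerance = 1e-10)
  expect_equal(f$aic, 2 - 4 * log(0.5), tolerance = 1e-10)

  # coefficients match direct numerical likelihood maximization
  for (seed in 1:5) {
    d <- simulate_logistic_cohort(250, c(a = 0.8, b = -0.5),
                                  intercept = 0.3, seed = seed)
    fit <- fit_logistic(d$features, d$labels)
    oracle <- logistic_ml_oracle(d$features, d$labels)
    expect_lt(max(abs(fit$coefficients - oracle)), 1e-6)
  }
})

test_that("separation and singular designs fail loudly", {
  expect_error(fit_logistic(data.frame(x = c(-2, -1, 1, 2)), c(0, 0, 1, 1)),
               "separation")
  expect_error(fit_logistic(data.frame(a = 1:8, b = 2 * (1:8)),
                            rep(c(0, 1), 4)),
               "collinear columns b")
  expect_error(fit_logistic(NULL, c(1, 1, 1)), "non-event")
  # capped fit is returned when asked to warn
  fit <- fit_logistic(data.frame(x = c(-2, -1, 1, 2)), c(0, 0, 1, 1),
                      on_separation = "warn")
  expect_true(fit$separation)
})

test_that("aic_of validates the 2k - 2*logLik identity", {
  d <- simulate_logistic_cohort(120, c(x1 = 1), seed = 3)
  fit <- fit_logistic(d$features, d$labels)
  expect_equal(aic_of(fit), 2 * fit$k - 2 * fit$log_likelihood,
               tolerance = 1e-12)
  broken <- fit
  broken$log_likelihood <- fit$log_likelihood + 0.01
  expect_error(aic_of(broken), "inconsistent")
})

test_that("events-per-variable advisory warns without blocking", {
  expect_warning(res <- epv_check(32, 8), "32 events")
  expect_false(res$ok)
  expect_silent(res2 <- epv_check(100, 10))
  expect_true(res2$ok)
  expect_warning(res3 <- epv_check(0, 2), "no events")
  expect_false(res3$ok)
})

test_that("greedy searches find a strong predictor and drop nulls", {
  d <- simulate_logistic_cohort(300, c(x1 = 2), intercept = -1, n_null = 5,
                                seed = 19)
  res <- run_searches(prepare_candidates(d$features, quiet = TRUE),
                      d$labels)
  for (m in names(res)) {
    expect_true("x1" %in% res[[m]]$selected)
    # AIC strictly decreases along every accepted move
    expect_true(all(diff(res[[m]]$trajectory$aic) < 0))
  }
  # empty candidate set: intercept-only model
  empty <- forward_select(d$features[, 0, drop = FALSE], d$labels)
  expect_equal(length(empty$selected), 0)
  expect_equal(empty$model$k, 1)
})

test_that("stepwise matches the exhaustive best subset on small pools", {
  d <- simulate_logistic_cohort(300, c(x1 = 1.5, x2 = -1), intercept = -0.5,
                                n_null = 4, seed = 23)
  vars <- colnames(d$features)
  all_aic <- unlist(lapply(0:length(vars), function(k) {
    sets <- utils::combn(vars, k, simplify = FALSE)
    vapply(sets, function(v)
      tryCatch(fit_logistic(d$features[, v, drop = FALSE], d$labels)$aic,
               error = function(e) Inf), numeric(1))
  }))
  sw <- stepwise_select(d$features, d$labels)
  expect_gte(sw$model$aic, min(all_aic) - 1e-9)
  # with orthogonal independent predictors, greedy attains the optimum
  expect_equal(sw$model$aic, min(all_aic), tolerance = 1e-6)
})

test_that("backward elimination falls back to forward when the full model is unfittable", {
  # more candidates than observations: full design is singular
  d <- simulate_logistic_cohort(40, c(x1 = 2), n_null = 45, seed = 7)
  expect_warning(res <- backward_eliminate(d$features, d$labels),
                 "falling back")
  expect_true(res$fallback)
  expect_identical(res$method, "backward")
})

test_that("select_best minimizes AIC with the documented tie-breaks", {
  d <- simulate_logistic_cohort(200, c(x1 = 1.5), n_null = 2, seed = 31)
  f_small <- forward_select(d$features[, "x1", drop = FALSE], d$labels)
  f_large <- forward_select(d$features, d$labels)
  pick <- select_best(list(f_large, f_small))
  expect_lte(pick$model$aic, min(f_small$model$aic, f_large$model$aic))
  # exact tie with different k: fewer parameters wins
  a <- f_small; b <- f_small
  b$selected <- c(b$selected, "pad"); b$model$k <- b$model$k + 1
  b$model$aic <- a$model$aic
  b$model$log_likelihood <- (2 * b$model$k - b$model$aic) / 2
  expect_identical(select_best(list(b, a)), a)
  expect_identical(select_best(list(a)), a)
  expect_error(select_best(list()), "no converged fits")
})

test_that("zero-variance and order-0 candidates are dropped up front", {
  df <- data.frame(dC1 = rnorm(30), dC0 = rnorm(30), flat = rep(1, 30),
                   absdP0 = rnorm(30))
  expect_message(out <- prepare_candidates(df), "dropping")
  expect_identical(names(out), "dC1")
})
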