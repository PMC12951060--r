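test_that("AUC equals pairwise concordance, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(auc(c(0.2, 0.8, 0.5, 0.4, 0.1), c(0, 1, 0, 1, 0)), 5 / 6)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(55)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    s <- sample(c(rnorm(n), round(rnorm(n), 1)), n)  # mix in ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), auc_brute(s, y), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auc(exp(2 * s), y), auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established external implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  s <- rnorm(80); y <- rbinom(80, 1, plogis(s))
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(13)
  r <- roc_points(rnorm(50), rbinom(50, 1, 0.3))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("Hosmer-Lemeshow reproduces the direct group-sum formula", {
  hl <- hosmer_lemeshow(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), n_groups = 2)
  # hand computation: groups {.1,.2} and {.8,.9}
  hand <- (0 - 0.3)^2 / (2 * 0.15 * 0.85) + (2 - 1.7)^2 / (2 * 0.85 * 0.15)
  expect_equal(hl$statistic, hand, tolerance = 1e-12)
  expect_equal(hl$df, 0)

  # permutation invariance
  set.seed(3)
  p <- runif(200); y <- rbinom(200, 1, p)
  h1 <- hosmer_lemeshow(p, y)
  perm <- sample(200)
  h2 <- hosmer_lemeshow(p[perm], y[perm])
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-12)
  expect_equal(h1$df, 8)

  # gross miscalibration: p ~ 0
  p3 <- rep(c(0.999, 0.001), each = 50)
  y3 <- rep(c(0, 1), each = 50)
  h3 <- hosmer_lemeshow(p3, y3)
  expect_lt(h3$p, 1e-10)

  expect_error(hosmer_lemeshow(runif(15), rbinom(15, 1, 0.5)), "n >= 20")
})

test_that("calibration curve reports decile means and edge cases", {
  set.seed(9)
  p <- runif(500); y <- as.numeric(runif(500) < p)
  cc <- calibration_curve(p, y)
  expect_equal(nrow(cc), 10)
  # well-calibrated: points near the diagonal (binomial noise)
  expect_lt(max(abs(cc$predicted - cc$observed)), 0.2)

  one <- calibration_curve(rep(0.3, 40), rep(c(1, 0, 0, 0), 10))
  expect_equal(nrow(one), 1)
  expect_equal(one$predicted, 0.3)
  expect_equal(one$observed, 0.25)

  worst <- calibration_curve(rep(1.0, 30), rep(0, 30))
  expect_equal(c(worst$predicted, worst$observed), c(1, 0))
})

test_that("bootstrap validation is seeded and handles separable data", {
  d <- simulate_logistic_cohort(120, c(x1 = 1.2), intercept = -1, seed = 44)
  b1 <- bootstrap_validate(d$features, d$labels, "x1", n_resamples = 50,
                           seed = 99)
  b2 <- bootstrap_validate(d$features, d$labels, "x1", n_resamples = 50,
                           seed = 99)
  expect_identical(b1, b2)
  expect_true(b1$ci[1] <= b1$ci[2])

  # perfectly separable data: every resample scores AUC 1 via capped fits
  sep <- data.frame(x1 = c(rnorm(30, -3), rnorm(30, 3)))
  ysep <- rep(c(0, 1), each = 30)
  bs <- bootstrap_validate(sep, ysep, "x1", n_resamples = 25, seed = 1)
  expect_equal(bs$mean_auc, 1.0)
  expect_gt(bs$n_separated, 0)
})

test_that("validate_model assembles a coherent report", {
  d <- simulate_logistic_cohort(250, c(x1 = 1.5, x2 = -0.8),
                                intercept = -1.5, seed = 60)
  fit <- fit_logistic(d$features, d$labels)
  rep <- validate_model(fit, d$features, d$labels, n_resamples = 60,
                        seed = 8)
  expect_s3_class(rep, "validation_report")
  expect_gt(rep$auc, 0.5)
  expect_true(rep$hl_p >= 0 && rep$hl_p <= 1)
  expect_true(rep$bootstrap_ci[1] <= rep$bootstrap_ci[2])
  expect_equal(nrow(rep$calibration_points), 10)
  # apparent AUC recomputable from the model and features
  eta <- fit$coefficients[1] +
    as.matrix(d$features[, fit$variables]) %*% fit$coefficients[-1]
  expect_equal(rep$auc, auc(drop(eta), d$labels), tolerance = 1e-12)
})
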