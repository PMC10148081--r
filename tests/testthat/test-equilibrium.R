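test_that("stepwise ratios follow the count-ratio definition", {
  d <- new_formula_dist(c(0, 0, 0, 0, 10, 20, 40))
  r <- stepwise_ratios(d)
  expect_equal(r$ratio[5:6], c(2, 2))
  expect_false(any(r$defined[1:4]))
  expect_true(all(is.na(r$ratio[1:4])))

  uni <- new_formula_dist(rep(100, 7))
  expect_equal(stepwise_ratios(uni)$ratio, rep(1, 6))

  expect_error(stepwise_ratios(d, pseudocount = -1), "nonnegative")
  # pseudocount makes all ratios defined
  rp <- stepwise_ratios(d, pseudocount = 0.5)
  expect_true(all(rp$defined))
  expect_equal(rp$ratio[6], 40.5 / 20.5)
})

test_that("binomial distributions give the statistical-factor ratio sequence", {
  # closed-form limit: counts prop. to Binomial(6, p) => r_n = ((6-n)/(n+1)) * odds
  for (p in c(0.3, 0.5, 0.8)) {
    d <- binom_dist(p)
    r <- stepwise_ratios(d)
    expect_true(all(r$defined))
    expect_equal(r$ratio, independent_site_ratios(p / (1 - p)), tolerance = 1e-12)
  }
  expect_equal(independent_site_ratios(1),
               c(6, 2.5, 4 / 3, 0.75, 0.4, 1 / 6), tolerance = 1e-15)
  expect_equal(independent_site_ratios(2), 2 * independent_site_ratios(1))
  for (theta in c(0.1, 1, 5)) {
    expect_true(all(diff(independent_site_ratios(theta)) < 0))
  }
  expect_error(independent_site_ratios(0), "positive")
})

test_that("exponential fit recovers exact log-linear input", {
  r <- 4 * exp(-0.5 * (0:5))
  fit <- fit_exponential_decay(r)
  expect_equal(fit$fit_A, 4, tolerance = 1e-10)
  expect_equal(fit$fit_lambda, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- fit_exponential_decay(rep(1, 6))
  expect_equal(flat$fit_lambda, 0, tolerance = 1e-12)

  # statistical-factor sequence at theta = 1: frozen OLS oracle values
  # slope = sum((n - 2.5) * log r_n) / sum((n - 2.5)^2) = -0.68545...
  sf <- independent_site_ratios(1)
  n <- 0:5
  oracle_lambda <- -sum((n - mean(n)) * log(sf)) / sum((n - mean(n))^2)
  fit_sf <- fit_exponential_decay(sf)
  expect_equal(fit_sf$fit_lambda, oracle_lambda, tolerance = 1e-12)
  expect_gt(fit_sf$fit_lambda, 0.6)
  expect_lt(fit_sf$fit_lambda, 0.8)
  expect_gt(fit_sf$r_squared, 0.97)
})

test_that("fit rejects sparse or non-positive ratio sets", {
  expect_error(fit_exponential_decay(c(2, rep(NA, 5))), "at least 2")
  expect_error(fit_exponential_decay(c(2, 0, 1, NA, NA, NA)), "non-positive")
  # two points suffice
  fit <- fit_exponential_decay(c(4, 2, rep(NA, 4)))
  expect_equal(fit$fit_lambda, log(2), tolerance = 1e-12)
})

test_that("theta estimation is the binomial MLE with a logit-scale CI", {
  d <- new_formula_dist(c(0, 0, 0, 500, 0, 0, 0))  # all alpha_3 beta_6
  est <- estimate_theta(d)
  expect_equal(est$p_hat, 0.5)
  expect_equal(est$theta_hat, 1)
  expect_lt(est$theta_ci[1], 1)
  expect_gt(est$theta_ci[2], 1)

  expect_error(estimate_theta(new_formula_dist(c(0, 0, 0, 0, 0, 0, 100))),
               "unbounded")
  expect_error(estimate_theta(new_formula_dist(c(100, 0, 0, 0, 0, 0, 0))),
               "unbounded")
})

test_that("theta CI covers the generating odds in a noiseless pipeline", {
  tr <- sample_true_occupancy(binding_model(p = 0.8), 60000, seed = 3)
  rec <- apply_classification_error(tr, error_model(), seed = 4)
  d <- formula_distribution(count_missing_per_particle(rec))
  est <- estimate_theta(d)
  expect_gt(4, est$theta_ci[1])
  expect_lt(4, est$theta_ci[2])
  expect_equal(est$theta_hat, 4, tolerance = 0.05)
})

test_that("equilibrium_analysis assembles a coherent report", {
  d <- binom_dist(0.6, 50000)
  res <- equilibrium_analysis(d)
  expect_s3_class(res, "pcc_equilibrium")
  expect_equal(res$theta$theta_hat, 1.5, tolerance = 1e-9)
  expect_equal(res$expected_ratios, res$ratios$ratio, tolerance = 1e-9)
  expect_gt(res$fit$fit_lambda, 0)
  out <- capture.output(print(res))
  expect_true(any(grepl("lambda", out)))
})
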