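test_that("binding and error model constructors validate their inputs", {
  expect_error(binding_model(), "exactly one")
  expect_error(binding_model(p = 0.5, weights = rep(1, 7)), "exactly one")
  expect_error(binding_model(p = 1.2), "probability")
  expect_error(binding_model(weights = rep(1, 6)), "7 nonnegative")
  expect_error(binding_model(weights = c(-1, rep(1, 6))), "7 nonnegative")
  expect_error(error_model(eps_fn = 1.5), "\\[0, 1\\]")
  expect_error(error_model(eps_fp = -0.1), "\\[0, 1\\]")
  m <- binding_model(weights = c(0, 0, 0, 0, 1, 2, 4))
  expect_equal(sum(m$weights), 1)  # normalised
})

test_that("boundary occupancy probabilities give degenerate truths", {
  all_on <- sample_true_occupancy(binding_model(p = 1), 100, seed = 5)
  expect_true(all(all_on$bits == "111111"))
  all_off <- sample_true_occupancy(binding_model(p = 0), 100, seed = 5)
  expect_true(all(all_off$bits == "000000"))
  expect_equal(all_on$particle_id, 0:99)
  expect_error(sample_true_occupancy(binding_model(p = 0.5), 0, seed = 1),
               "positive integer")
})

test_that("independent-site occupancy matches the binomial law", {
  tr <- sample_true_occupancy(binding_model(p = 0.5), 60000, seed = 1)
  n_alpha <- vapply(strsplit(tr$bits, ""), function(x) sum(as.integer(x)), integer(1))
  frac3 <- mean(n_alpha == 3)
  p3 <- choose(6, 3) / 64  # 0.3125, closed-form binomial pmf
  se <- sqrt(p3 * (1 - p3) / 60000)
  expect_lt(abs(frac3 - p3), 3 * se)
})

test_that("explicit-distribution mode respects formula weights", {
  w <- c(0, 0, 0, 0, 0.2, 0.3, 0.5)
  tr <- sample_true_occupancy(binding_model(weights = w), 20000, seed = 11)
  h <- truth_histogram(tr) / 20000
  expect_equal(sum(h[1:4]), 0)
  expect_lt(max(abs(h[5:7] - w[5:7])), 0.02)
  # configurations within a formula are spread across sites, not fixed
  sub <- tr$bits[substr(tr$bits, 1, 1) == "0"]
  expect_gt(length(unique(sub)), 1)
})

test_that("empirical formula distribution passes a binomial goodness-of-fit", {
  p <- 0.35
  for (seed in 1:3) {
    tr <- sample_true_occupancy(binding_model(p = p), 50000, seed = seed)
    obs <- truth_histogram(tr)
    gof <- suppressWarnings(stats::chisq.test(obs, p = stats::dbinom(0:6, 6, p)))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("expansion emits 6 records per particle with faithful noiseless labels", {
  tr <- sample_true_occupancy(binding_model(p = 0.6), 500, seed = 3)
  rec <- apply_classification_error(tr, error_model(), seed = 4)
  expect_equal(nrow(rec), 3000L)
  expect_equal(unname(table(rec$particle_id)), rep(6L, 500), ignore_attr = TRUE)
  per_particle <- split(rec$copy_index, rec$particle_id)
  expect_true(all(vapply(per_particle, function(x) setequal(x, 0:5), logical(1))))
  # noiseless round trip: labels mirror true occupancy bit-for-bit
  rebuilt <- vapply(split(rec, rec$particle_id), function(d) {
    paste(as.integer(d$class_label[order(d$copy_index)] == "present"), collapse = "")
  }, character(1))
  expect_equal(unname(rebuilt[as.character(tr$particle_id)]), tr$bits)
})

test_that("classification error flips labels at the stated rates", {
  tr <- sample_true_occupancy(binding_model(p = 1), 50000, seed = 9)
  rec <- apply_classification_error(tr, error_model(eps_fn = 0.1), seed = 10)
  k_missing <- rowsum(as.integer(rec$class_label == "missing"), rec$particle_id)
  frac_clean <- mean(k_missing == 0)
  p_clean <- 0.9^6  # 0.531441, closed-form oracle
  se <- sqrt(p_clean * (1 - p_clean) / 50000)
  expect_lt(abs(frac_clean - p_clean), 3 * se)

  # total false negative: everything flips
  rec2 <- apply_classification_error(
    sample_true_occupancy(binding_model(p = 1), 20, seed = 1),
    error_model(eps_fn = 1), seed = 2)
  expect_true(all(rec2$class_label == "missing"))
})

test_that("generation is deterministic given the seed", {
  a <- sample_true_occupancy(binding_model(p = 0.4), 1000, seed = 42)
  b <- sample_true_occupancy(binding_model(p = 0.4), 1000, seed = 42)
  expect_identical(a, b)
  ra <- apply_classification_error(a, error_model(0.1, 0.05), seed = 7)
  rb <- apply_classification_error(b, error_model(0.1, 0.05), seed = 7)
  expect_identical(ra, rb)
  c_ <- sample_true_occupancy(binding_model(p = 0.4), 1000, seed = 43)
  expect_false(identical(a$bits, c_$bits))
})
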