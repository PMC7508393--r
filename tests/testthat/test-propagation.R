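test_that("the five-boundary worked example reproduces every tabulated cell", {
  d <- propagate(worked_example_series())

  expect_equal(d[[1]]$t_min, 0L)
  expect_equal(d[[1]]$probs, 1)
  expect_equal(d[[2]]$t_min, 0L)
  expect_equal(d[[2]]$probs, c(0.3, 0.7))
  expect_equal(d[[3]]$t_min, 1L)          # P = 1 shifts the support
  expect_equal(d[[3]]$probs, c(0.3, 0.7))
  expect_equal(d[[4]]$t_min, 1L)
  expect_equal(d[[4]]$probs, c(0.24, 0.62, 0.14), tolerance = 1e-12)
  expect_equal(d[[5]]$t_min, 1L)
  expect_equal(d[[5]]$probs, c(0.024, 0.278, 0.572, 0.126), tolerance = 1e-12)

  expect_equal(mean_age(d[[4]]), 1.9, tolerance = 1e-12)
  expect_equal(variance_age(d[[4]]), 0.37, tolerance = 1e-12)
  expect_equal(sd_age(d[[4]]), sqrt(0.37), tolerance = 1e-12)
})

test_that("certain boundaries give a point mass at the boundary number", {
  for (n in c(1, 5, 30)) {
    d <- propagate(ring_series(rep(1, n + 1)))
    final <- d[[n + 1]]
    expect_equal(final$t_min, n)
    expect_equal(final$probs, 1)
    expect_equal(mean_age(final), n)
    expect_equal(variance_age(final), 0)
  }
})

test_that("propagation agrees with exhaustive subset enumeration", {
  for (seed in 1:8) {
    s <- random_test_series(sample(3:12, 1), seed = seed)
    got <- propagate(s)
    want <- brute_force_distributions(s)
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$t_min, want[[i]]$t_min)
      expect_equal(got[[i]]$probs, want[[i]]$probs, tolerance = 1e-12)
    }
  }
})

test_that("binomial_ages is the closed form for equal probabilities", {
  # three uncertain boundaries at 0.83 on top of one certain year
  b <- binomial_ages(3, 0.83, base_age = 1)
  expect_equal(ages(b), 1:4)
  expect_equal(round(b$probs, 3), c(0.005, 0.072, 0.351, 0.572))

  expect_equal(binomial_ages(0, 0.5, base_age = 7)$probs, 1)
  expect_equal(ages(binomial_ages(0, 0.5, base_age = 7)), 7L)
  # p = 1 collapses to a point mass at base_age + n
  expect_equal(ages(binomial_ages(5, 1, base_age = 2)), 7L)

  # equivalence with the general recursion on the case-study structure
  d48 <- propagate(case_study_series())[[49]]
  b48 <- binomial_ages(48, 0.83, base_age = 0)
  overlap <- match(ages(d48), ages(b48))
  expect_equal(d48$probs, b48$probs[overlap] / sum(b48$probs[overlap]),
               tolerance = 1e-12)
  expect_equal(mean_age(d48), mean_age(b48), tolerance = 1e-9)
  expect_equal(sd_age(d48), sqrt(48 * 0.83 * 0.17), tolerance = 1e-9)
})

test_that("expected ages advance by the input probabilities (cumulative identity)", {
  for (seed in 1:25) {
    s <- random_test_series(sample(2:40, 1), seed = 100 + seed)
    d <- propagate(s)
    means <- vapply(d, mean_age, numeric(1))
    expect_equal(means, cumsum(boundary_probs(s)) - 1, tolerance = 1e-9)
    # variance is the sum of independent Bernoulli variances
    p <- boundary_probs(s)[-1]
    expect_equal(variance_age(d[[length(d)]]), sum(p * (1 - p)),
                 tolerance = 1e-9)
  }
})

test_that("every propagated distribution is a trimmed simplex over valid ages", {
  for (seed in 1:10) {
    s <- random_test_series(sample(2:30, 1), seed = 200 + seed)
    for (d in propagate(s)) {
      expect_equal(sum(d$probs), 1, tolerance = 1e-9)
      expect_true(all(d$probs > 0))
      expect_gte(d$probs[1], 1e-15)
      expect_gte(d$probs[length(d$probs)], 1e-15)
      expect_lte(d$t_min + length(d$probs) - 1L, d$boundary_index)
      expect_gte(d$t_min, 0L)
    }
  }
})

test_that("support grows by one age per uncertain boundary and shifts per certain one", {
  s <- random_test_series(12, seed = 42)
  p <- boundary_probs(s)
  d <- propagate(s)
  for (i in 2:length(d)) {
    if (p[i] < 1) {
      expect_equal(length(d[[i]]$probs), length(d[[i - 1]]$probs) + 1L)
      expect_equal(d[[i]]$t_min, d[[i - 1]]$t_min)
    } else {
      expect_equal(length(d[[i]]$probs), length(d[[i - 1]]$probs))
      expect_equal(d[[i]]$t_min, d[[i - 1]]$t_min + 1L)
    }
  }
})

test_that("one-step variance responds to P as 1 - 2P (decreasing in P)", {
  # finite-difference derivative of the final variance w.r.t. the last
  # boundary's probability matches the Bernoulli-increment identity
  dvar <- function(p_last, base) {
    h <- 1e-6
    v <- function(p) {
      s <- ring_series(c(boundary_probs(base), p))
      variance_age(propagate(s)[[n_boundaries(base) + 1L]])
    }
    (v(p_last + h) - v(p_last - h)) / (2 * h)
  }
  base <- random_test_series(8, seed = 9)
  grads <- vapply(c(0.2, 0.4, 0.5, 0.6, 0.9), dvar, numeric(1), base = base)
  expect_equal(grads, 1 - 2 * c(0.2, 0.4, 0.5, 0.6, 0.9), tolerance = 1e-4)
  expect_true(all(diff(grads) < 0))
})

test_that("age_distribution rejects invalid probability vectors", {
  expect_error(age_distribution(c(0.5, 0.4)), "sum to 1")
  expect_error(age_distribution(c(1.2, -0.2)), "non-negative")
  expect_error(age_distribution(numeric(0)), "empty")
  # tiny leading/trailing mass is trimmed and renormalized
  d <- age_distribution(c(1e-16, 0.5, 0.5 - 1e-16, 1e-16), t_min = 3)
  expect_equal(d$t_min, 4L)
  expect_equal(d$probs, c(0.5, 0.5), tolerance = 1e-12)
})
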