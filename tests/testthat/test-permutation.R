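test_that("identical groups give observed statistic 0 and p = 1", {
  r <- permutation_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$observed_stat, 0)
  expect_equal(r$p_value, 1)
})

test_that("exact enumeration matches hand counting on {1,2} vs {3,4}", {
  r <- exact_permutation_test(c(1, 2), c(3, 4))
  expect_equal(r$n_iterations, 6L)  # choose(4, 2) splits
  expect_equal(r$p_value, 1 / 3)    # 2 of 6 splits reach |mean diff| = 2
  expect_equal(r$backend, "exact")
  # the auto-switch picks the exact backend for small groups
  auto <- permutation_test(c(1, 2), c(3, 4), n_iterations = 20000)
  expect_equal(auto$backend, "exact")
  expect_equal(auto$p_value, 1 / 3)
})

test_that("enumeration cap triggers a redirect to Monte-Carlo", {
  expect_error(exact_permutation_test(rnorm(20), rnorm(20), max_splits = 1e4),
               "Monte-Carlo")
})

test_that("Monte-Carlo agrees with exact enumeration", {
  set.seed(9)
  cases <- list(list(a = c(1, 2, 3), b = c(4, 5, 6)),
                list(a = rnorm(4), b = rnorm(5) + 1),
                list(a = runif(5), b = runif(4)))
  for (cs in cases) {
    pe <- exact_permutation_test(cs$a, cs$b)$p_value
    for (s in 1:5) {
      pm <- permutation_test(cs$a, cs$b, n_iterations = 20000, seed = s,
                             exact_threshold = 0)$p_value
      expect_lt(abs(pm - pe), 0.01)
    }
  }
})

test_that("p-values are invariant to label swap and location shift", {
  set.seed(12)
  a <- rnorm(8)
  b <- rnorm(9) + 0.5
  p1 <- permutation_test(a, b, seed = 4, exact_threshold = 0,
                         n_iterations = 2000)$p_value
  p2 <- permutation_test(b, a, seed = 4, exact_threshold = 0,
                         n_iterations = 2000)$p_value
  expect_equal(p1, p2)
  p3 <- permutation_test(a + 100, b + 100, seed = 4, exact_threshold = 0,
                         n_iterations = 2000)$p_value
  expect_equal(p1, p3)
  pe <- exact_permutation_test(a, b)
  expect_equal(pe$p_value, exact_permutation_test(a + 100, b + 100)$p_value)
})

test_that("smoothed Monte-Carlo p never reaches zero", {
  set.seed(13)
  r <- permutation_test(rnorm(30), rnorm(30) + 10, n_iterations = 2000,
                        seed = 1)
  expect_gte(r$p_value, 1 / 2001)
  expect_lt(r$p_value, 0.0001 * 10)  # overwhelming effect, tiny p
})

test_that("clear separation is detected across seeds", {
  for (s in 1:10) {
    set.seed(s)
    a <- rnorm(200)
    b <- rnorm(200) + 1
    expect_lt(permutation_test(a, b, n_iterations = 1000, seed = s)$p_value,
              0.05)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
  expect_error(permutation_test(c(1, NA), 1:3), "finite")
  expect_error(permutation_test(1, 2), "at least 3")
})

test_that("calibration harness reports null rejection and power", {
  cs <- calibration_study(n_reps = 200, group_sizes = c(15, 15), seed = 2,
                          effects = c(0, 2), n_iterations = 400)
  null_rate <- cs$rejection_rate[cs$effect == 0]
  expect_gte(null_rate, 0.01)
  expect_lte(null_rate, 0.10)
  expect_gt(cs$rejection_rate[cs$effect == 2], 0.99)
  # identical constant groups can never reject
  const <- calibration_study(n_reps = 100, group_sizes = c(10, 10), seed = 3,
                             n_iterations = 200,
                             sampler = function(n) rep(5, n))
  expect_equal(const$rejection_rate, 0)
})
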