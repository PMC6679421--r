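test_that("the statistic is the product of its two factors", {
  set.seed(51)
  for (variant in c("bias-corrected", "v-statistic")) {
    dx <- random_euclidean_dm(12); dm <- random_euclidean_dm(12)
    dy <- random_euclidean_dm(12)
    s <- modima_statistic(dx, dm, dy, variant = variant)
    expect_equal(s$statistic, s$factor_xm * s$factor_my_given_x,
                 tolerance = 1e-12)
  }
})

test_that("the two variants use the intended first factor", {
  set.seed(52)
  dx <- random_euclidean_dm(10); dm <- random_euclidean_dm(10)
  dy <- random_euclidean_dm(10)
  expect_equal(modima_statistic(dx, dm, dy, variant = "v-statistic")$factor_xm,
               dcor(dx, dm), tolerance = 1e-12)
  expect_equal(modima_statistic(dx, dm, dy)$factor_xm, bcdcor(dx, dm),
               tolerance = 1e-12)
  # partial factor equals pdcor(M, Y; X) in both variants
  expect_equal(modima_statistic(dx, dm, dy)$factor_my_given_x,
               pdcor(dm, dy, dx), tolerance = 1e-12)
})

test_that("identical matrices give a zero statistic by the pdcor convention", {
  set.seed(53)
  d <- random_euclidean_dm(9)
  s <- modima_statistic(d, d, d)
  expect_equal(s$factor_my_given_x, 0)
  expect_equal(s$statistic, 0)
})

test_that("the statistic is invariant to a common sample relabeling", {
  set.seed(54)
  dx <- random_euclidean_dm(11); dm <- random_euclidean_dm(11)
  dy <- random_euclidean_dm(11)
  p <- sample(11)
  s0 <- modima_statistic(dx, dm, dy)
  s1 <- modima_statistic(permute_dist_matrix(dx, p),
                         permute_dist_matrix(dm, p),
                         permute_dist_matrix(dy, p))
  expect_equal(s1$statistic, s0$statistic, tolerance = 1e-12)
})

test_that("an independent mediator drives the first factor toward zero", {
  set.seed(55)
  x <- rnorm(150); m <- rnorm(150); y <- m + rnorm(150)
  s <- modima_statistic(dist_euclidean(x), dist_euclidean(m),
                        dist_euclidean(y))
  expect_lt(abs(s$factor_xm), 0.1)
  expect_lt(abs(s$statistic), 0.05)
})

test_that("modima_test is deterministic and records a coherent result", {
  set.seed(56)
  x <- rnorm(30); m <- x + rnorm(30); y <- m + rnorm(30)
  dx <- dist_euclidean(x); dm <- dist_euclidean(m); dy <- dist_euclidean(y)
  f1 <- modima_test(dx, dm, dy, q = 99, seed = 7)
  f2 <- modima_test(dx, dm, dy, q = 99, seed = 7)
  expect_identical(f1, f2)
  expect_length(f1$permuted_statistics, 99)
  # recorded p-value reproduces the stated frequency formula exactly
  expect_identical(f1$p_value,
                   sum(f1$permuted_statistics >= f1$statistic) / 99)
  expect_identical(
    modima_test(dx, dm, dy, q = 99, seed = 7, positive_p = TRUE)$p_value,
    (1 + sum(f1$permuted_statistics >= f1$statistic)) / 100)
  expect_error(modima_test(dx, dm, dy, q = 0), "positive integer")
})

test_that("the adaptive rule permutes the weaker link", {
  set.seed(57)
  # strong X-M, weak M-Y|X: response is permuted
  x <- rnorm(40); m <- x + rnorm(40, sd = 0.1); y <- rnorm(40)
  f <- modima_test(dist_euclidean(x), dist_euclidean(m), dist_euclidean(y),
                   q = 19, seed = 1)
  expect_gt(abs(f$factor_xm), abs(f$factor_my_given_x))
  expect_identical(f$permuted_term, "response")
  # weak X-M, strong M-Y|X: exposure is permuted
  x <- rnorm(40); m <- rnorm(40); y <- m + rnorm(40, sd = 0.1)
  f <- modima_test(dist_euclidean(x), dist_euclidean(m), dist_euclidean(y),
                   q = 19, seed = 1)
  expect_lt(abs(f$factor_xm), abs(f$factor_my_given_x))
  expect_identical(f$permuted_term, "exposure")
})

test_that("strong simulated mediation is detected", {
  # alpha = 1, beta = 1, gamma = 0.25, n = 100: reject in the large majority
  # of replicates
  ps <- vapply(1:20, function(i) {
    d <- simulate_smm(smm_params(alpha = 1, beta = 1, gamma = 0.25), 100,
                      seed = 500 + i)
    modima_test(dist_euclidean(d$x), dist_euclidean(d$m), dist_euclidean(d$y),
                q = 199, seed = 600 + i)$p_value
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0.95)
})

test_that("smm_statistic matches the residual-regression oracle", {
  set.seed(58)
  for (rep in 1:10) {
    x <- rnorm(12); m <- rnorm(12); y <- rnorm(12)
    expect_equal(smm_statistic(x, m, y),
                 cor(x, m) * oracle_partial_residuals(m, y, x),
                 tolerance = 1e-10)
  }
  x <- rnorm(10)
  expect_warning(out <- smm_statistic(x, x, rnorm(10)), "convention")
  expect_equal(out, 0)
  expect_error(smm_statistic(rep(2, 5), rnorm(5), rnorm(5)), "constant")
})

test_that("smm_statistic vanishes under full independence", {
  set.seed(59)
  x <- rnorm(2000); m <- rnorm(2000); y <- rnorm(2000)
  expect_lt(abs(smm_statistic(x, m, y)), 0.05)
})

test_that("smm_test is deterministic, adaptive, and formula-faithful", {
  set.seed(60)
  x <- rnorm(30); m <- x + rnorm(30); y <- m + rnorm(30)
  f1 <- smm_test(x, m, y, q = 99, seed = 3)
  expect_identical(f1, smm_test(x, m, y, q = 99, seed = 3))
  expect_identical(f1$p_value,
                   sum(f1$permuted_statistics >= f1$statistic) / 99)
  # strong mediation with no direct path: rejected in most replicates
  ps <- vapply(1:20, function(i) {
    d <- simulate_smm(smm_params(alpha = 1, beta = 1, gamma = 0), 100,
                      seed = 700 + i)
    smm_test(d$x, d$m, d$y, q = 199, seed = 800 + i)$p_value
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0.9)
})

test_that("tidy and glance summarize test objects", {
  set.seed(61)
  x <- rnorm(20); m <- x + rnorm(20); y <- m + rnorm(20)
  f <- modima_test(dist_euclidean(x), dist_euclidean(m), dist_euclidean(y),
                   q = 49, seed = 2)
  td <- tidy(f)
  expect_identical(td$term, c("dcor_xm", "pdcor_my_given_x", "modima"))
  expect_equal(td$estimate[3], f$statistic)
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$p.value, f$p_value)
  s <- smm_test(x, m, y, q = 49, seed = 2)
  expect_identical(nrow(glance(s)), 1L)
  expect_identical(tidy(s)$estimate[3], s$statistic)
})
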