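test_that("Spearman correlation is the Pearson correlation of mid-ranks", {
  expect_equal(spearman_rho(1:6, c(2, 4, 8, 16, 32, 64)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(1:5, c(1, 3, 2, 5, 4)), 0.8)
  # ties: cross-check the mid-rank route explicitly
  x <- c(1, 2, 2, 3, 5, 5, 7)
  y <- c(2, 1, 4, 4, 6, 8, 8)
  expect_equal(spearman_rho(x, y), stats::cor(rank(x), rank(y)))
  expect_error(spearman_rho(rep(3, 5), 1:5), "zero rank variance")
  expect_error(spearman_rho(1:2, 1:2), "length >= 3")
})

test_that("Bland-Altman reports bias, SD, and 1.96-SD limits", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(same$sd_bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  expect_equal(same$n_outside, 0)

  offset <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(offset$bias, 2)
  expect_equal(offset$sd_bias, 0)

  ba <- bland_altman(c(10, 20, 30), c(12, 18, 33))
  expect_equal(ba$bias, -1)
  expect_equal(ba$sd_bias, sqrt(7), tolerance = 1e-9)  # sd of (-2, 2, -3)
  expect_equal(ba$loa_low, -1 - 1.96 * sqrt(7), tolerance = 1e-9)
  expect_equal(ba$loa_high, -1 + 1.96 * sqrt(7), tolerance = 1e-9)
  expect_error(bland_altman(1:3, 1:4), "paired")
})

test_that("few normal differences fall outside the limits of agreement", {
  # ~4.6% of normal differences lie outside 1.96-SD limits; the count is
  # binomial per table, so assert the sanity band on the replicate mean
  set.seed(31)
  n <- 100
  outside <- replicate(10, {
    a <- rnorm(n, 50, 10)
    b <- a + rnorm(n, 2, 3)
    bland_altman(a, b)$n_outside
  })
  expect_lte(mean(outside), ceiling(0.05 * n) + 2)
})

test_that("perfect agreement gives ICC 1 in every form", {
  m <- cbind(c(7, 5, 2, 9), c(7, 5, 2, 9), c(7, 5, 2, 9))
  for (type in c("absolute_agreement", "consistency")) {
    for (unit in c("single", "average")) {
      expect_equal(icc_two_way(m, type, unit)$icc, 1)
    }
  }
})

test_that("rater columns unrelated to subjects give ICC near zero", {
  set.seed(32)
  m <- matrix(rnorm(500 * 3), 500, 3)  # no subject effect at all
  r <- icc_two_way(m, "absolute_agreement", "single")
  expect_lt(abs(r$icc), 0.1)
  expect_false(r$significant && r$icc > 0.1)
})

test_that("all ICC forms match the aov-based oracle on a toy table", {
  m <- rbind(c(7, 8, 9), c(5, 5, 6), c(2, 3, 2), c(9, 9, 10))
  o <- oracle_icc(m)
  expect_equal(icc_two_way(m, "consistency", "single")$icc,
               o[["consistency_single"]], tolerance = 1e-9)
  expect_equal(icc_two_way(m, "consistency", "average")$icc,
               o[["consistency_average"]], tolerance = 1e-9)
  expect_equal(icc_two_way(m, "absolute_agreement", "single")$icc,
               o[["absolute_single"]], tolerance = 1e-9)
  expect_equal(icc_two_way(m, "absolute_agreement", "average")$icc,
               o[["absolute_average"]], tolerance = 1e-9)
})

test_that("ICC forms match the oracle across many small random tables", {
  set.seed(33)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    k <- sample(2:4, 1)
    m <- matrix(sample(0:10, n * k, replace = TRUE), n, k)
    if (stats::var(rowMeans(m)) == 0) next  # degenerate case tested below
    o <- oracle_icc(m)
    expect_equal(icc_two_way(m, "consistency", "single")$icc,
                 o[["consistency_single"]], tolerance = 1e-9)
    expect_equal(icc_two_way(m, "consistency", "average")$icc,
                 o[["consistency_average"]], tolerance = 1e-9)
    expect_equal(icc_two_way(m, "absolute_agreement", "single")$icc,
                 o[["absolute_single"]], tolerance = 1e-9)
    expect_equal(icc_two_way(m, "absolute_agreement", "average")$icc,
                 o[["absolute_average"]], tolerance = 1e-9)
  }
})

test_that("Cronbach alpha equals the consistency average-measures ICC", {
  m <- rbind(c(7, 8, 9), c(5, 5, 6), c(2, 3, 2), c(9, 9, 10))
  expect_equal(cronbach_alpha(m),
               icc_two_way(m, "consistency", "average")$icc,
               tolerance = 1e-9)
  set.seed(34)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 50, 10), n, k) +
      rnorm(n, 0, 8)  # shared subject effect recycled down the rows
    expect_equal(cronbach_alpha(m),
                 icc_two_way(m, "consistency", "average")$icc,
                 tolerance = 1e-9)
  }
})

test_that("uncorrelated columns give alpha near zero", {
  set.seed(35)
  m <- matrix(rnorm(2000), 1000, 2)
  expect_lt(abs(cronbach_alpha(m)), 0.1)
})

test_that("degenerate tables are flagged instead of reported as reliable", {
  flat <- matrix(5, 4, 3)  # no between-subject variance at all
  r <- icc_two_way(flat, "absolute_agreement", "average")
  expect_true(r$degenerate)
  expect_equal(r$icc, 0)
  expect_error(cronbach_alpha(flat), "zero total variance")
})

test_that("ICC recovery from planted variance components is unbiased", {
  # two-way model with known components; the mean estimate over many
  # seeded replicates must sit within 0.02 of the population ICC
  reps <- 500
  est <- matrix(NA_real_, reps, 2)
  pop <- NULL
  for (i in seq_len(reps)) {
    sim <- simulate_rater_table(n = 30, k = 3, sigma_subject = 15,
                                sigma_rater = 3, sigma_error = 5,
                                seed = 5000 + i)
    pop <- sim$population_icc
    est[i, 1] <- icc_two_way(sim$table, "consistency", "average")$icc
    est[i, 2] <- icc_two_way(sim$table, "absolute_agreement", "average")$icc
  }
  expect_lt(abs(mean(est[, 1]) - pop[["consistency_average"]]), 0.02)
  expect_lt(abs(mean(est[, 2]) - pop[["absolute_average"]]), 0.02)
})

test_that("classification bins follow the published cut points", {
  expect_equal(classify_icc(0.828), "excellent")
  expect_equal(classify_icc(0.75), "excellent")
  expect_equal(classify_icc(0.74), "good")
  expect_equal(classify_icc(0.6), "good")
  expect_equal(classify_icc(0.59), "fair")
  expect_equal(classify_icc(0.4), "fair")
  expect_equal(classify_icc(0.39), "unacceptable")
  expect_equal(classify_alpha(0.95), "excellent")
  expect_equal(classify_alpha(0.9), "excellent")
  expect_equal(classify_alpha(0.89), "good")
  expect_equal(classify_alpha(0.8), "good")
  expect_equal(classify_alpha(0.79), "fair")
  expect_equal(classify_alpha(0.7), "fair")
  expect_equal(classify_alpha(0.69), "unacceptable")
})

test_that("the Shapiro-Wilk gate picks the paired test", {
  set.seed(36)
  pre <- rnorm(30, 50, 10)
  post <- pre + rnorm(30, 5, 3)          # normal differences
  r <- paired_change_test(pre, post)
  expect_equal(r$test_used, "paired t test")
  expect_lt(r$p_value, 0.001)

  skew_post <- pre + rexp(30, 1 / 10)^2 / 20  # heavily skewed differences
  r2 <- paired_change_test(pre, skew_post)
  expect_equal(r2$test_used, "Wilcoxon matched-pairs signed-rank test")

  expect_error(paired_change_test(pre, pre), "degenerate differences")
})
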