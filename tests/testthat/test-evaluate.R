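test_that("Dice follows 2|P&T|/(|P|+|T|) with the documented edge cases", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- TRUE            # |P| = 2
  b[1, 1, 1] <- TRUE              # |T| = 1, overlap 1
  expect_equal(dice(a, b), 2 / 3)
  expect_equal(dice(a, a), 1.0)
  d <- array(FALSE, c(4, 4, 4)); d[4, 4, 4] <- TRUE
  expect_equal(dice(a, d), 0.0)
  expect_true(is.na(dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2)))))
  expect_equal(dice(a, b), dice(b, a))                 # symmetry
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "shape")
})

test_that("MAPE matches its definition and an independent one-liner", {
  m <- mape(c(0.30, 0.20), c(0.33, 0.18))
  expect_equal(unname(m["mean"]), 10.0)
  expect_equal(unname(mape(c(1, 2, 3), c(1, 2, 3))["mean"]), 0)
  set.seed(20)
  for (i in 1:20) {
    ref <- runif(15, 0.1, 2); test <- ref + rnorm(15, 0, 0.2)
    m <- mape(ref, test)
    v <- 100 * abs(test - ref) / ref                   # oracle
    expect_equal(unname(m["mean"]), mean(v), tolerance = 1e-12)
    expect_equal(unname(m["sd"]), sd(v), tolerance = 1e-12)
  }
  expect_error(mape(c(0, 1), c(1, 1)), "positive")
})

test_that("two-way ICC reproduces the classic 6x4 inter-rater example", {
  # Shrout & Fleiss' six targets rated by four judges; the single-measure
  # absolute-agreement ICC of the two-way random model is 0.29.
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  r <- icc_two_way(m)
  expect_equal(r$icc, 0.2897638, tolerance = 1e-6)
  expect_lt(r$ci["lower"], r$icc)
  expect_gt(r$ci["upper"], r$icc)
})

test_that("ICC agrees with an aov-based two-way decomposition on random tables", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 10, 2), n, k) +
      matrix(rep(rnorm(n, 0, 3), k), n, k)
    r <- icc_two_way(m)
    df <- data.frame(y = as.vector(m), s = factor(rep(seq_len(n), k)),
                     rt = factor(rep(seq_len(k), each = n)))
    a <- anova(stats::aov(y ~ s + rt, df))
    MSR <- a["s", "Mean Sq"]; MSC <- a["rt", "Mean Sq"]
    MSE <- a["Residuals", "Mean Sq"]
    oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    expect_equal(r$icc, oracle, tolerance = 1e-10)
  }
})

test_that("ICC model behaviour: identical raters, biased raters, degenerate", {
  x <- c(3, 7, 5, 9, 4, 6)
  expect_equal(icc_two_way(cbind(x, x))$icc, 1.0)
  r <- icc_two_way(cbind(x, x + 2))
  expect_lt(r$icc, 1.0)           # absolute agreement penalises bias
  expect_gt(r$icc, 0.5)
  expect_error(icc_two_way(matrix(5, 4, 2)), "degenerate")
  expect_error(icc_two_way(matrix(c(1, 2, NA, 4), 2, 2)), "complete")
})

test_that("Bland-Altman bias and limits match the formula", {
  x <- c(1, 2, 3)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  ba <- bland_altman(c(1, 1), c(1 - 0.5, 1 + 0.5))  # d = +c, -c
  expect_equal(ba$bias, 0)
  expect_equal(unname(ba$loa[2]), -unname(ba$loa[1]))
  set.seed(22)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    ba <- bland_altman(a, b)
    d <- a - b                                        # oracle
    expect_equal(ba$bias, mean(d), tolerance = 1e-12)
    expect_equal(unname(ba$loa),
                 c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)),
                 tolerance = 1e-12)
  }
})

test_that("paired t matches the closed form and is antisymmetric", {
  a <- c(0.31, 0.28, 0.35, 0.40, 0.22, 0.30, 0.27, 0.36, 0.33, 0.25)
  b <- c(0.29, 0.30, 0.33, 0.38, 0.24, 0.28, 0.26, 0.34, 0.35, 0.24)
  r <- paired_t(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))     # textbook formula
  p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
  expect_equal(r$t, t_oracle, tolerance = 1e-10)
  expect_equal(r$p, p_oracle, tolerance = 1e-10)
  r2 <- paired_t(b, a)
  expect_equal(r2$t, -r$t, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  expect_error(paired_t(a, a), "degenerate")
})

test_that("R squared is the squared Pearson correlation", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(a, 2 * a + 1), 1.0)
  set.seed(23)
  a <- rnorm(8); b <- rnorm(8)
  oracle <- (sum((a - mean(a)) * (b - mean(b))) /
               sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
  expect_equal(r_squared(a, b), oracle, tolerance = 1e-12)
  big_a <- rnorm(2000); big_b <- rnorm(2000)
  expect_lt(r_squared(big_a, big_b), 0.01)
  expect_error(r_squared(a, rep(1, 8)), "constant")
})

test_that("comparing a segmentation source against itself is perfect agreement", {
  cohort <- generate_cohort(tiny_spec(seed = 12), 2)
  rep_ <- compare_segmentations(cohort, "truth", "truth")
  expect_equal(unname(rep_$dsc["mean"]), 1.0)
  expect_equal(unname(rep_$mape["mean"]), 0.0)
  expect_equal(rep_$bland_altman$bias, 0.0)
  expect_equal(nrow(rep_$per_gland), 2 * 4)  # studies x glands present
})
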