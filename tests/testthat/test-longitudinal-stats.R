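test_that("unit sum-of-squares normalization matches its closed form", {
  expect_equal(normalize_sum_squares(c(3, 4)), c(0.6, 0.8))
  expect_equal(normalize_sum_squares(c(1, 0, 0)), c(1, 0, 0))
  set.seed(1)
  v <- rnorm(20)
  expect_equal(sum(normalize_sum_squares(v)^2), 1, tolerance = 1e-12)
  expect_error(normalize_sum_squares(c(0, 0)),
               class = "corrtf_degenerate_error")
})

test_that("the paired t-test reproduces hand-computed and stats:: results", {
  r <- paired_ttest(c(1, 2, 4), c(2, 4, 5))
  expect_equal(r$t, 4)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-4, 2), tolerance = 1e-12)
  ref <- stats::t.test(c(2, 4, 5), c(1, 2, 4), paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  z <- paired_ttest(c(0, 0), c(1, -1))
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)),
               class = "corrtf_degenerate_error")
  expect_error(paired_ttest(1:3, 1:4), class = "corrtf_argument_error")

  set.seed(2)
  for (k in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    mine <- paired_ttest(a, b)
    ref <- stats::t.test(b, a, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the one-way ANOVA reproduces hand-computed and stats:: results", {
  r <- oneway_anova(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(r$f, 16)              # SSB = 16, SSW = 1.5, df (2, 3)
  expect_equal(c(r$df1, r$df2), c(2, 3))
  expect_equal(r$p, stats::pf(16, 2, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  flat <- oneway_anova(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(flat$f, 0); expect_equal(flat$p, 1)
  expect_error(oneway_anova(c(1, 1), c(1, 1), c(1, 1)),
               class = "corrtf_degenerate_error")
  set.seed(3)
  for (k in 1:10) {
    g <- list(rnorm(8), rnorm(8, 0.5), rnorm(8))
    mine <- oneway_anova(g[[1]], g[[2]], g[[3]])
    ref <- stats::oneway.test(
      y ~ grp, data.frame(y = unlist(g), grp = factor(rep(1:3, each = 8))),
      var.equal = TRUE)
    expect_equal(mine$f, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the Welch test agrees with stats::t.test", {
  set.seed(4)
  a <- rnorm(10); b <- rnorm(12, 0.8)
  mine <- welch_ttest(a, b)
  ref <- stats::t.test(b, a)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("sign patterns follow the transition signs with zero conventions", {
  expect_equal(classify_sign_pattern(2.5, -3.1), "positive_to_negative")
  expect_equal(classify_sign_pattern(-2.0, 2.0), "negative_to_positive")
  expect_equal(classify_sign_pattern(1.0, 2.0), "same_sign_positive")
  expect_equal(classify_sign_pattern(-1.0, -0.5), "same_sign_negative")
  expect_equal(classify_sign_pattern(0, -2), "same_sign_negative")
  expect_equal(classify_sign_pattern(3, 0), "same_sign_positive")
  expect_equal(classify_sign_pattern(0, 0), "same_sign_positive")
  expect_error(classify_sign_pattern(Inf, 1), class = "corrtf_argument_error")
})

test_that("the screen flags exactly the all-three-below-alpha connections", {
  set.seed(5)
  n <- 15; C <- 120
  v0 <- matrix(rnorm(n * C), n, C)
  v1 <- matrix(rnorm(n * C), n, C)
  v2 <- matrix(rnorm(n * C), n, C)
  v1[, 1:10] <- v1[, 1:10] + 2    # strong planted shifts on 10 columns
  v2[, 1:10] <- v2[, 1:10] - 1
  res <- screen_visits(v0, v1, v2, alpha = 0.05)
  expect_identical(res$significant,
                   res$p1 < 0.05 & res$p2 < 0.05 & res$p_anova < 0.05 &
                     !res$degenerate)
  expect_true(all(res$significant[1:10]))
})

test_that("the vectorized screen agrees with per-connection recomputation", {
  set.seed(6)
  n <- 12; C <- 40
  v0 <- matrix(rexp(n * C), n, C)
  v1 <- matrix(rexp(n * C), n, C)
  v2 <- matrix(rexp(n * C), n, C)
  res <- screen_visits(v0, v1, v2, normalize = "none")
  for (j in sample(C, 20)) {
    t1 <- paired_ttest(v0[, j], v1[, j])
    t2 <- paired_ttest(v1[, j], v2[, j])
    fa <- oneway_anova(v0[, j], v1[, j], v2[, j])
    expect_equal(res$t1[j], t1$t, tolerance = 1e-10)
    expect_equal(res$p1[j], t1$p, tolerance = 1e-10)
    expect_equal(res$t2[j], t2$t, tolerance = 1e-10)
    expect_equal(res$p2[j], t2$p, tolerance = 1e-10)
    expect_equal(res$f_anova[j], fa$f, tolerance = 1e-10)
    expect_equal(res$p_anova[j], fa$p, tolerance = 1e-10)
    ref <- stats::t.test(v1[, j], v0[, j], paired = TRUE)
    expect_equal(res$t1[j], unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("lowering alpha never grows the significant set", {
  set.seed(7)
  n <- 10; C <- 200
  v0 <- matrix(rnorm(n * C), n, C)
  v1 <- matrix(rnorm(n * C, 0.3), n, C)
  v2 <- matrix(rnorm(n * C, 0.6), n, C)
  sets <- lapply(c(0.05, 0.01, 0.001), function(a) {
    which(screen_visits(v0, v1, v2, alpha = a)$significant)
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("degenerate connections are flagged and retained, never dropped", {
  set.seed(8)
  n <- 8
  v0 <- cbind(rnorm(n), rep(1, n))
  v1 <- cbind(rnorm(n), rep(2, n))   # constant differences: degenerate
  v2 <- cbind(rnorm(n), rep(3, n))
  res <- screen_visits(v0, v1, v2, normalize = "none")
  expect_equal(nrow(res), 2)
  expect_false(res$degenerate[1])
  expect_true(res$degenerate[2])
  expect_false(res$significant[2])
  expect_true(is.na(res$t1[2]))
})

test_that("sample-based screening validates input and returns full records", {
  set.seed(9)
  samples <- lapply(1:5, function(k) {
    group_connection_sample("EMCI", c(k, k + 1), matrix(rnorm(30), 10, 3))
  })
  res <- find_significant_connections(samples)
  expect_equal(nrow(res), 5)
  expect_equal(res$source, 1:5)
  expect_equal(res$target, 2:6)
  expect_true(all(c("t1", "p1", "t2", "p2", "f_anova", "p_anova",
                    "significant", "sign_pattern", "degenerate")
                  %in% names(res)))
  expect_error(find_significant_connections(list()),
               class = "corrtf_argument_error")
  expect_error(find_significant_connections(samples, alpha = 2),
               class = "corrtf_argument_error")
  expect_error(group_connection_sample("A", c(1, 2), matrix(1:3, 1, 3)),
               class = "corrtf_argument_error")
})

test_that("Benjamini-Hochberg thresholding only shrinks the flagged set", {
  set.seed(10)
  n <- 12; C <- 80
  v0 <- matrix(rnorm(n * C), n, C)
  v1 <- matrix(rnorm(n * C), n, C); v1[, 1:5] <- v1[, 1:5] + 3
  v2 <- matrix(rnorm(n * C), n, C); v2[, 1:5] <- v2[, 1:5] - 3
  raw <- screen_visits(v0, v1, v2, correction = "none")
  bh <- screen_visits(v0, v1, v2, correction = "BH")
  expect_true(all(which(bh$significant) %in% which(raw$significant)))
  expect_equal(bh$p1, raw$p1)   # reported p-values stay unadjusted
})
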