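band_signal <- function(seed = 1, n = 130, tr = 3) {
  set.seed(seed)
  t <- (seq_len(n) - 1) * tr
  f <- runif(4, 0.015, 0.075)
  drop(runif(4, 0.5, 1) %*% sin(outer(2 * pi * f, t) + runif(4, 0, 2 * pi)))
}

test_that("the transfer-function spectrum obeys identity and linearity", {
  x <- band_signal(1)
  sp <- corrtf_spectrum(x, x)
  ok <- sp$mag_y > 1e-9
  expect_equal(sp$ratios[ok], rep(1, sum(ok)))
  sp2 <- corrtf_spectrum(2 * x, x)
  expect_equal(sp2$ratios[ok], rep(2, sum(ok)))
  expect_error(corrtf_spectrum(x, x[-1]), class = "corrtf_argument_error")
})

test_that("a sinusoid pair shows its amplitude ratio at the matching bin", {
  t <- default_time()
  y <- sin(2 * pi * 0.05 * t)
  sp <- corrtf_spectrum(3 * y, y)
  k <- which.min(abs(sp$frequencies - 0.05))
  expect_equal(sp$ratios[k], 3, tolerance = 1e-9)
})

test_that("the scalar CorrTF obeys the scale law", {
  x <- band_signal(2)
  expect_equal(corrtf_value(x, x), 1, tolerance = 1e-12)
  for (c in c(0.5, 2, -3)) {
    expect_equal(corrtf_value(c * x, x), abs(c), tolerance = 1e-12)
  }
})

test_that("the scalar CorrTF matches a brute-force direct-summation DFT", {
  set.seed(3)
  x <- rnorm(130); y <- rnorm(130)
  expect_equal(corrtf_value(x, y), naive_corrtf(x, y), tolerance = 1e-9)
  # and on band-limited signals
  a <- band_signal(4); b <- band_signal(5)
  expect_equal(corrtf_value(a, b), naive_corrtf(a, b), tolerance = 1e-9)
})

test_that("directed spectra are reciprocal bin by bin", {
  a <- band_signal(6); b <- band_signal(7)
  sa <- corrtf_spectrum(a, b)
  sb <- corrtf_spectrum(b, a)
  ok <- sa$mag_x > 1e-9 & sa$mag_y > 1e-9
  expect_equal(sa$ratios[ok] * sb$ratios[ok], rep(1, sum(ok)),
               tolerance = 1e-9)
})

test_that("the CorrTF matrix equals the naive oracle on a 5 x 32 series", {
  set.seed(8)
  series <- matrix(rnorm(5 * 32), 5, 32)
  m <- corrtf_matrix(series, tr_seconds = 3)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) {
      expect_true(is.na(m[i, j]))
    } else {
      expect_equal(m[i, j], naive_corrtf(series[i, ], series[j, ], tr = 3),
                   tolerance = 1e-9)
    }
  }
})

test_that("a full atlas matrix defines all 13,340 directed connections", {
  cfg <- cohort_config(group_sizes = c(A = 1), seed = 9)
  sv <- generate_cohort(cfg)[[1]]
  m <- corrtf_matrix(sv)
  expect_equal(dim(m), c(116, 116))
  expect_equal(sum(!is.na(m)), 116 * 115)
  expect_true(all(m[!is.na(m)] >= 0))
  expect_equal(nrow(connectivity_edges(m)), 13340)
})

test_that("duplicated regions produce a unit directed connection", {
  series <- rbind(band_signal(10), band_signal(11), band_signal(10))
  m <- corrtf_matrix(series, tr_seconds = 3)
  expect_equal(m[1, 3], 1, tolerance = 1e-12)
  expect_equal(m[3, 1], 1, tolerance = 1e-12)
})

test_that("aggregation rules and band validation behave as configured", {
  a <- band_signal(12); b <- band_signal(13)
  sp <- corrtf_spectrum(a, b)
  sel <- sp$frequencies >= 0.01 & sp$frequencies <= 0.08 & sp$frequencies > 0
  keep <- sp$mag_y[sel] > 1e-12 * max(sp$mag_y[sel])
  r <- (sp$mag_x[sel] / sp$mag_y[sel])[keep]
  expect_equal(corrtf_value(a, b, aggregate = "median"), stats::median(r))
  expect_equal(corrtf_value(a, b, aggregate = "max"), max(r))
  expect_error(corrtf_value(a, b, band = c(0.2, 0.3)),
               class = "corrtf_config_error")
  # a band so narrow that no discrete bin falls inside it
  expect_error(corrtf_value(a, b, band = c(0.0301, 0.0302)),
               class = "corrtf_degenerate_error")
})

test_that("Pearson matrices match the direct covariance formula", {
  set.seed(14)
  series <- matrix(rnorm(4 * 60), 4, 60)
  series[3, ] <- -series[1, ] + rnorm(60, sd = 1e-6)
  m <- pearson_matrix(series)
  expect_true(isSymmetric(unclass(m)))
  for (i in 1:3) for (j in (i + 1):4) {
    a <- series[i, ]; b <- series[j, ]
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(m[i, j], r, tolerance = 1e-12)
  }
  expect_lt(m[1, 3], -0.999)
  flat <- series; flat[2, ] <- 5
  expect_error(pearson_matrix(flat), class = "corrtf_degenerate_error")
})

test_that("the Fisher transform matches its closed form and guards |r| = 1", {
  set.seed(15)
  series <- matrix(rnorm(3 * 40), 3, 40)
  pm <- pearson_matrix(series)
  fz <- fisher_z(pm)
  expect_equal(fz[1, 2], 0.5 * log((1 + pm[1, 2]) / (1 - pm[1, 2])),
               tolerance = 1e-12)
  expect_equal(attr(fz, "kind"), "fisher_z")
  exact <- pearson_matrix(rbind(series, series[1, ] * 2))  # r = 1 pair
  expect_error(fisher_z(exact), class = "corrtf_degenerate_error")
  expect_error(fisher_z(matrix(0, 2, 2)), class = "corrtf_argument_error")
})
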