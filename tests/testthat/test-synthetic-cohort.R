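test_that("the default configuration reproduces the study layout", {
  cfg <- cohort_config()
  expect_equal(sum(cfg$group_sizes), 99)
  expect_equal(cfg$group_sizes[["NC"]], 29)
  expect_equal(cfg$group_sizes[["EMCI"]], 23)
  expect_equal(cfg$group_sizes[["LMCI"]], 24)
  expect_equal(cfg$group_sizes[["AD"]], 23)
  expect_equal(cfg$n_regions, 116L)
  expect_equal(cfg$n_timepoints, 130L)
  expect_equal(cfg$tr_seconds, 3)
  expect_equal(cfg$signal_band, c(0.01, 0.08))
})

test_that("generation yields one finite series per subject per visit", {
  cfg <- cohort_config(group_sizes = c(A = 3, B = 2), n_regions = 6,
                       n_timepoints = 50, seed = 11)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 5 * 3)
  for (sv in cohort) {
    expect_equal(dim(sv$series), c(6, 50))
    expect_true(all(is.finite(sv$series)))
  }
  expect_setequal(unique(vapply(cohort, function(x) x$group, "")), c("A", "B"))
  expect_setequal(unique(vapply(cohort, function(x) x$visit, 0L)), 0:2)
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  cfg <- cohort_config(group_sizes = c(A = 2), n_regions = 5,
                       n_timepoints = 40, seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  cfg2 <- cfg; cfg2$seed <- 6L
  c3 <- generate_cohort(cfg2)
  expect_false(identical(c1[[1]]$series, c3[[1]]$series))
})

test_that("noise-free series concentrate their power inside the band", {
  cfg <- cohort_config(group_sizes = c(A = 3), n_regions = 8,
                       n_timepoints = 130, noise_sd = 0, seed = 21)
  cohort <- generate_cohort(cfg)
  for (sv in cohort[1:3]) {
    for (r in seq_len(nrow(sv$series))) {
      x <- sv$series[r, ] - mean(sv$series[r, ])
      p <- Mod(stats::fft(x))^2
      n <- length(x)
      freqs <- (seq_len(n) - 1) / (n * sv$tr_seconds)
      inband <- freqs >= 0.01 & freqs <= 0.08 |
                (1 / sv$tr_seconds - freqs) >= 0.01 &
                (1 / sv$tr_seconds - freqs) <= 0.08
      expect_gt(sum(p[inband]) / sum(p), 0.95)
    }
  }
})

test_that("injected visit gains raise the pair's Pearson correlation monotonically", {
  # Monte-Carlo over replicate subjects: gains (0, 1.5, 3) on pair 2 -> 5
  cfg <- cohort_config(group_sizes = c(A = 200), n_regions = 6,
                       n_timepoints = 130, seed = 31,
                       effects = list(effect_spec("A", 2, 5, c(0, 1.5, 3))))
  cohort <- generate_cohort(cfg)
  visit <- vapply(cohort, function(x) x$visit, 0L)
  mean_r <- vapply(0:2, function(v) {
    mean(vapply(cohort[visit == v], function(sv) {
      stats::cor(sv$series[2, ], sv$series[5, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(mean_r[1] < mean_r[2])
  expect_true(mean_r[2] < mean_r[3])
})

test_that("invalid configurations and effects are rejected", {
  expect_error(cohort_config(group_sizes = c(3, 2)),
               class = "corrtf_config_error")   # unnamed
  expect_error(cohort_config(signal_band = c(0.01, 0.2)),
               class = "corrtf_config_error")   # above Nyquist at TR 3
  expect_error(effect_spec("A", 3, 3, c(0, 1, 2)),
               class = "corrtf_config_error")   # source == target
  expect_error(
    cohort_config(group_sizes = c(A = 2), n_regions = 4, n_timepoints = 40,
                  effects = list(effect_spec("B", 1, 2, c(0, 1, 2)))),
    class = "corrtf_config_error")              # unknown group
  expect_error(
    cohort_config(group_sizes = c(A = 2), n_regions = 4, n_timepoints = 40,
                  effects = list(effect_spec("A", 1, 9, c(0, 1, 2)))),
    class = "corrtf_config_error")              # region out of range
  expect_error(
    cohort_config(group_sizes = c(A = 2), n_regions = 4, n_timepoints = 40,
                  effects = list(effect_spec("A", 1, 2, c(0, 1)))),
    class = "corrtf_config_error")              # gains length != visits
})

test_that("labeled volume fixtures reproduce their ground truth exactly", {
  fx <- generate_labeled_volume_fixture(3, c(6, 6, 6), 25, seed = 41)
  expect_setequal(unique(as.integer(fx$labels)), 0:3)
  rec <- extract_roi_means(fx$volumes, fx$labels, data.frame(index = 1:3))
  expect_equal(rec, fx$truth, tolerance = 1e-12)
  # background voxels (label 0) carry no signal and are excluded
  expect_true(all(fx$volumes[, , , 1][fx$labels == 0] == 0))
  expect_error(generate_labeled_volume_fixture(100, c(2, 2, 2), 5),
               class = "corrtf_argument_error")
})

test_that("cohorts round-trip through the TSV manifest format", {
  cfg <- cohort_config(group_sizes = c(A = 2), n_regions = 4,
                       n_timepoints = 30, seed = 51)
  cohort <- generate_cohort(cfg)
  dir <- file.path(tempfile(), "cohort")
  manifest <- write_cohort(cohort, dir)
  back <- read_cohort(manifest)
  expect_length(back, length(cohort))
  for (i in seq_along(cohort)) {
    expect_equal(back[[i]]$subject_id, cohort[[i]]$subject_id)
    expect_equal(back[[i]]$visit, cohort[[i]]$visit)
    expect_equal(unname(back[[i]]$series), unname(cohort[[i]]$series),
                 tolerance = 1e-8)
  }
})
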