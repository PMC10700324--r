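# Independent oracles and small fixtures used across test files.

# Direct-summation DFT magnitude (O(T^2)), independent of stats::fft.
naive_dft_mag <- function(x) {
  n <- length(x)
  vapply(0:(n %/% 2), function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# Brute-force scalar CorrTF via the naive DFT, mirroring the documented
# reduction: mean in-band ratio, DC excluded, denominator floor relative to
# the in-band maximum.
naive_corrtf <- function(x, y, band = c(0.01, 0.08), tr = 3,
                         eps_rel = 1e-12) {
  n <- length(x)
  freqs <- (0:(n %/% 2)) / (n * tr)
  mx <- naive_dft_mag(x)
  my <- naive_dft_mag(y)
  sel <- freqs >= band[1] & freqs <= band[2] & freqs > 0
  my_in <- my[sel]
  keep <- my_in > eps_rel * max(my_in)
  mean(mx[sel][keep] / my_in[keep])
}

# Amplitude of a roughly sinusoidal series from its RMS.
rms_amplitude <- function(x) sqrt(2 * mean(x^2))

# Small prepared cohort: generates, band-pass filters, and returns the
# per-visit value matrices (subjects x directed connections) of the CorrTF
# matrices, plus the directed edge index.
prepared_group_values <- function(n_subjects, n_regions, seed,
                                  effects = list(), n_timepoints = 130,
                                  group = "G") {
  sizes <- stats::setNames(n_subjects, group)
  cfg <- cohort_config(group_sizes = sizes, n_regions = n_regions,
                       n_timepoints = n_timepoints, seed = seed,
                       effects = effects)
  cohort <- generate_cohort(cfg)
  for (i in seq_along(cohort)) {
    cohort[[i]]$series <- bandpass_filter(cohort[[i]]$series, 0.01, 0.08, 3)
  }
  mats <- lapply(cohort, function(sv) {
    unclass(corrtf_matrix(sv$series, tr_seconds = 3))
  })
  visit <- vapply(cohort, function(x) x$visit, 0L)
  idx <- which(row(diag(n_regions)) != col(diag(n_regions)))
  getv <- function(v) {
    t(vapply(which(visit == v), function(j) mats[[j]][idx],
             numeric(length(idx))))
  }
  list(v0 = getv(0), v1 = getv(1), v2 = getv(2),
       source = col(diag(n_regions))[idx],
       target = row(diag(n_regions))[idx])
}

# Band-limited test signal over the default acquisition grid.
default_time <- function(n = 130, tr = 3) (seq_len(n) - 1) * tr
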