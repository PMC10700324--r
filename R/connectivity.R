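#' Correlation transfer function spectrum of a series pair
#'
#' Per one-sided DFT bin, the magnitude ratio |X(f)| / max(|Y(f)|, eps),
#' where X and Y are the discrete Fourier transforms of `x` and `y`. The
#' ratio at each frequency is the magnitude of the empirical transfer
#' function treating `y` as the input and `x` as the output of a linear
#' system (Y(f) relation X(f) = Y(f) H(f) solved for |H|).
#'
#' @param x,y numeric time series of equal length (output and input).
#' @param tr_seconds sampling interval in seconds (gives the bin
#'   frequencies).
#' @param eps small positive floor applied to the denominator magnitude.
#' @return list of class `corrtf_spectrum` with fields `frequencies` (Hz),
#'   `ratios`, and the raw magnitudes `mag_x`, `mag_y`.
#' @examples
#' t <- (0:129) * 3
#' s <- sin(2 * pi * 0.05 * t)
#' sp <- corrtf_spectrum(3 * s, s)
#' sp$ratios[which.min(abs(sp$frequencies - 0.05))]  # about 3
#' @export
corrtf_spectrum <- function(x, y, tr_seconds = 3, eps = .Machine$double.xmin) {
  if (length(x) != length(y)) argument_error("x and y must have equal length")
  n <- length(x)
  if (n < 2L) argument_error("series must have length >= 2")
  if (!is_scalar_number(eps) || eps <= 0) argument_error("eps must be positive")
  half <- 0:(n %/% 2)
  mag_x <- Mod(stats::fft(x))[half + 1L]
  mag_y <- Mod(stats::fft(y))[half + 1L]
  structure(list(frequencies = half / (n * tr_seconds),
                 ratios = mag_x / pmax(mag_y, eps),
                 mag_x = mag_x, mag_y = mag_y),
            class = "corrtf_spectrum")
}

#' Scalar CorrTF connectivity of a series pair
#'
#' Reduces the per-bin transfer-function magnitudes to one scalar per
#' directed pair: by default the mean ratio over the one-sided DFT bins
#' falling inside `band` (DC always excluded). Bins whose denominator
#' magnitude is at or below `eps_rel` times the largest in-band denominator
#' magnitude are excluded rather than clipped, to avoid inflating ratios.
#'
#' @inheritParams corrtf_spectrum
#' @param band length-2 numeric, frequency band in Hz over which ratios are
#'   aggregated (must lie inside (0, Nyquist)).
#' @param eps_rel relative denominator floor (fraction of the in-band
#'   maximum denominator magnitude).
#' @param aggregate aggregation rule over in-band bins: "mean" (default),
#'   "median" or "max".
#' @return non-negative scalar.
#' @examples
#' t <- (0:129) * 3
#' s <- sin(2 * pi * 0.05 * t) + sin(2 * pi * 0.03 * t)
#' corrtf_value(2 * s, s)  # 2
#' @export
corrtf_value <- function(x, y, band = c(0.01, 0.08), tr_seconds = 3,
                         eps_rel = 1e-12,
                         aggregate = c("mean", "median", "max")) {
  aggregate <- match.arg(aggregate)
  check_band(band[1], band[2], tr_seconds)
  sp <- corrtf_spectrum(x, y, tr_seconds)
  sel <- sp$frequencies >= band[1] & sp$frequencies <= band[2] &
         sp$frequencies > 0
  if (!any(sel)) {
    degenerate_error(sprintf("no DFT bins fall in band [%g, %g] Hz",
                             band[1], band[2]))
  }
  my <- sp$mag_y[sel]
  keep <- my > eps_rel * max(my)
  if (!any(keep)) {
    degenerate_error("all in-band denominator bins are below the floor")
  }
  r <- sp$mag_x[sel][keep] / my[keep]
  switch(aggregate, mean = mean(r), median = stats::median(r), max = max(r))
}

new_connectivity_matrix <- function(values, kind) {
  diag(values) <- NA_real_
  structure(values, kind = kind, class = c("connectivity_matrix", "matrix"))
}

#' Directed CorrTF connectivity matrix
#'
#' Entry (i, j) is [corrtf_value()] of region i over region j: the in-band
#' aggregated magnitude of the transfer function with region j as input
#' (denominator) and region i as output. The matrix is therefore generally
#' asymmetric; entry (i, j) describes the directed connection j to i. The
#' diagonal is masked as `NA`.
#'
#' @param series a subject-visit series object from [generate_cohort()] /
#'   [read_cohort()], or a regions x time numeric matrix.
#' @inheritParams corrtf_value
#' @return R x R matrix of class `connectivity_matrix` with attribute
#'   `kind = "corrtf"`.
#' @export
corrtf_matrix <- function(series, band = c(0.01, 0.08), tr_seconds = NULL,
                          eps_rel = 1e-12,
                          aggregate = c("mean", "median", "max")) {
  aggregate <- match.arg(aggregate)
  if (inherits(series, "subject_visit_series")) {
    if (is.null(tr_seconds)) tr_seconds <- series$tr_seconds
    series <- series$series
  }
  if (is.null(tr_seconds)) tr_seconds <- 3
  if (!is.matrix(series) || !all(is.finite(series))) {
    argument_error("series must be a finite regions x time matrix")
  }
  check_band(band[1], band[2], tr_seconds)
  R <- nrow(series); n <- ncol(series)
  half <- 0:(n %/% 2)
  freqs <- half / (n * tr_seconds)
  sel <- freqs >= band[1] & freqs <= band[2] & freqs > 0
  if (!any(sel)) {
    degenerate_error(sprintf("no DFT bins fall in band [%g, %g] Hz",
                             band[1], band[2]))
  }
  mags <- Mod(stats::mvfft(t(series)))[half + 1L, , drop = FALSE][sel, ,
                                                                  drop = FALSE]
  V <- matrix(NA_real_, R, R)
  for (j in seq_len(R)) {
    mj <- mags[, j]
    keep <- mj > eps_rel * max(mj)
    if (!any(keep)) {
      degenerate_error(sprintf(
        "all in-band bins of region %d are below the denominator floor", j))
    }
    ratios <- mags[keep, , drop = FALSE] / mj[keep]
    V[, j] <- switch(aggregate,
                     mean = colMeans(ratios),
                     median = apply(ratios, 2L, stats::median),
                     max = apply(ratios, 2L, max))
  }
  new_connectivity_matrix(V, "corrtf")
}

#' Pearson correlation connectivity matrix
#'
#' Symmetric Pearson correlation between all region pairs; diagonal masked.
#'
#' @param series subject-visit series object or regions x time matrix.
#' @return R x R `connectivity_matrix` with `kind = "pearson"`.
#' @export
pearson_matrix <- function(series) {
  if (inherits(series, "subject_visit_series")) series <- series$series
  if (!is.matrix(series) || !all(is.finite(series))) {
    argument_error("series must be a finite regions x time matrix")
  }
  v <- apply(series, 1L, stats::var)
  if (any(v == 0)) {
    degenerate_error(sprintf("region(s) with zero variance: %s",
                             paste(which(v == 0), collapse = ", ")))
  }
  new_connectivity_matrix(stats::cor(t(series)), "pearson")
}

#' Fisher z-transform of a Pearson connectivity matrix
#'
#' Entrywise inverse hyperbolic tangent, the variance-stabilizing transform
#' of the correlation coefficient.
#'
#' @param values `connectivity_matrix` of kind "pearson".
#' @return `connectivity_matrix` with `kind = "fisher_z"`.
#' @export
fisher_z <- function(values) {
  if (!inherits(values, "connectivity_matrix") ||
      !identical(attr(values, "kind"), "pearson")) {
    argument_error("fisher_z expects a pearson connectivity matrix")
  }
  off <- values[!is.na(values)]
  if (any(abs(off) >= 1)) {
    bad <- which(abs(values) >= 1, arr.ind = TRUE)[1, ]
    degenerate_error(sprintf("|r| = 1 for pair (%d, %d); atanh undefined",
                             bad[1], bad[2]))
  }
  new_connectivity_matrix(atanh(unclass(values)), "fisher_z")
}

#' Long-format edge list of a connectivity matrix
#'
#' For directed (corrtf) matrices, `source` is the denominator/input region
#' (matrix column) and `target` the numerator/output region (matrix row);
#' every ordered pair appears once. For symmetric kinds each unordered pair
#' appears once with `source < target`.
#'
#' @param mat a `connectivity_matrix`.
#' @return data.frame with columns `source`, `target`, `value`.
#' @export
connectivity_edges <- function(mat) {
  stopifnot(inherits(mat, "connectivity_matrix"))
  R <- nrow(mat)
  if (identical(attr(mat, "kind"), "corrtf")) {
    idx <- which(row(mat) != col(mat))
    data.frame(source = col(mat)[idx], target = row(mat)[idx],
               value = unclass(mat)[idx])
  } else {
    idx <- which(upper.tri(mat))
    data.frame(source = row(mat)[idx], target = col(mat)[idx],
               value = unclass(mat)[idx])
  }
}

#' Write a connectivity matrix as TSV
#'
#' Row and column headers are region abbreviations when a region table of
#' matching size is supplied (default for 116 regions).
#'
#' @param mat `connectivity_matrix`.
#' @param path output path.
#' @param table optional region table for labels.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(mat, path, table = NULL) {
  m <- unclass(mat)
  labels <- if (!is.null(table) && nrow(table) == nrow(m)) table$abbreviation
            else sprintf("R%03d", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
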