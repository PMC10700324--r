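#' Discard initial volumes
#'
#' Removes the first `n_discard` time points (magnetization-equilibrium
#' dummies). Accepts a 4D array (time last) or a regions x time matrix.
#'
#' @param volumes 4D array (x, y, z, t) or matrix (regions x time).
#' @param n_discard number of leading time points to drop (default 10).
#' @return the input with the first `n_discard` time points removed.
#' @examples
#' m <- matrix(rnorm(5 * 140), 5, 140)
#' dim(discard_initial_volumes(m))  # 5 x 130
#' @export
discard_initial_volumes <- function(volumes, n_discard = 10L) {
  if (!is.numeric(n_discard) || length(n_discard) != 1L || n_discard < 0 ||
      n_discard != round(n_discard)) {
    argument_error("n_discard must be a non-negative integer")
  }
  nd <- length(dim(volumes))
  nt <- if (nd == 4L) dim(volumes)[4] else if (is.matrix(volumes)) ncol(volumes)
        else argument_error("volumes must be a 4D array or a matrix")
  if (nt <= n_discard) {
    argument_error(sprintf("series has %d time points, cannot discard %d",
                           nt, n_discard))
  }
  if (n_discard == 0L) return(volumes)
  keep <- (n_discard + 1L):nt
  if (nd == 4L) volumes[, , , keep, drop = FALSE] else volumes[, keep, drop = FALSE]
}

#' Extract ROI mean time series
#'
#' Row r of the output is the arithmetic mean, per time point, over all
#' voxels with label r; label 0 (background) is ignored. Every region index
#' in `table` must be present in the label volume.
#'
#' @param volumes 4D array (x, y, z, t).
#' @param labels 3D integer array with the same spatial dimensions; values
#'   0..R where positive values are region indices of `table`.
#' @param table region table ([load_region_table()]) or a data.frame with an
#'   `index` column naming the regions to extract, in output row order.
#' @return regions x time matrix, rows ordered as `table$index`.
#' @export
extract_roi_means <- function(volumes, labels, table = load_region_table()) {
  if (length(dim(volumes)) != 4L) argument_error("volumes must be 4D")
  if (!identical(dim(volumes)[1:3], dim(labels)[1:3])) {
    argument_error("volumes and labels must share spatial dimensions")
  }
  nt <- dim(volumes)[4]
  lab <- as.integer(labels)
  keep <- lab > 0L
  vmat <- matrix(volumes, ncol = nt)[keep, , drop = FALSE]
  lab <- lab[keep]
  sums <- rowsum(vmat, lab)
  counts <- as.vector(table(lab))
  means <- sums / counts
  have <- as.integer(rownames(sums))
  missing <- setdiff(table$index, have)
  if (length(missing)) {
    nm <- if ("abbreviation" %in% names(table)) {
      table$abbreviation[match(missing, table$index)]
    } else as.character(missing)
    argument_error(sprintf("region(s) absent from label volume: %s",
                           paste(nm, collapse = ", ")))
  }
  out <- means[match(table$index, have), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each row independently with a Butterworth band-pass applied
#' forward and backward (zero phase). Series are extended by odd reflection
#' at both ends before filtering to suppress edge transients, then cropped
#' back, so output dimensions equal input dimensions.
#'
#' @param series regions x time matrix (a plain vector is treated as one row).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   0 < low < high < Nyquist.
#' @param tr_seconds sampling interval in seconds.
#' @param order Butterworth design order per band edge (default 4; the
#'   forward-backward pass doubles the effective order).
#' @return filtered matrix with the same dimensions as the input.
#' @examples
#' t <- (0:129) * 3
#' x <- sin(2 * pi * 0.04 * t)                 # in band: retained
#' y <- bandpass_filter(rbind(x), 0.01, 0.08, 3)
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.08,
                            tr_seconds = 3, order = 4L) {
  vec <- is.null(dim(series))
  if (vec) series <- matrix(series, nrow = 1L)
  check_band(low_hz, high_hz, tr_seconds)
  if (!is_count(order)) config_error("filter order must be a positive integer")
  nyq <- 1 / (2 * tr_seconds)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  n <- ncol(series)
  pad <- 3L * max(length(bf$b), length(bf$a))
  if (n < 3L * order) {
    argument_error(sprintf("series too short (%d points) for order-%d filter",
                           n, order))
  }
  pad <- min(pad, n - 1L)
  out <- t(apply(series, 1L, filtfilt_padded, bf = bf, pad = pad))
  if (vec) drop(out) else out
}

# Forward-backward IIR filtering with odd-reflection end padding. Each pass
# starts from the DC steady state of the padded edge sample (past inputs at
# that level, past outputs zero -- the band-pass has zero DC gain), so a
# constant offset produces no step transient.
filtfilt_padded <- function(x, bf, pad) {
  n <- length(x)
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  run <- function(v) {
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], length(bf$b) - 1L),
                              init = rep(0, length(bf$a) - 1L)))
  }
  y <- rev(run(rev(run(ext))))
  y[(pad + 1L):(pad + n)]
}

#' One-call preparation of a raw 4D acquisition
#'
#' Convenience wrapper: discard leading volumes, extract ROI means, band-pass
#' filter. A 140-volume input with the defaults yields a 116 x 130 matrix.
#'
#' @inheritParams extract_roi_means
#' @inheritParams bandpass_filter
#' @param n_discard leading volumes to drop.
#' @return regions x time matrix of band-limited ROI mean series.
#' @export
prep_volumes <- function(volumes, labels, table = load_region_table(),
                         n_discard = 10L, low_hz = 0.01, high_hz = 0.08,
                         tr_seconds = 3, order = 4L) {
  volumes <- discard_initial_volumes(volumes, n_discard)
  series <- extract_roi_means(volumes, labels, table)
  bandpass_filter(series, low_hz, high_hz, tr_seconds, order)
}
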