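#' Normalize a vector to unit sum of squares
#'
#' Divides by the Euclidean norm so the sum of squares equals one.
#'
#' @param values numeric vector with at least one nonzero element.
#' @return rescaled vector.
#' @examples
#' normalize_sum_squares(c(3, 4))  # 0.6 0.8
#' @export
normalize_sum_squares <- function(values) {
  if (!is.numeric(values) || !all(is.finite(values))) {
    argument_error("values must be finite numbers")
  }
  nrm <- sqrt(sum(values^2))
  if (nrm == 0) degenerate_error("cannot normalize an all-zero vector")
  values / nrm
}

#' Paired t-test (closed form)
#'
#' Classical paired t on the differences `b - a`, with n - 1 degrees of
#' freedom and a two-sided p-value.
#'
#' @param a,b numeric vectors of equal length (>= 2), same subjects in the
#'   same order.
#' @return list with `t`, `p`, `df`.
#' @examples
#' paired_ttest(c(1, 2, 4), c(2, 4, 5))$t  # 4
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) argument_error("a and b must have equal length")
  if (length(a) < 2L) argument_error("need at least 2 paired observations")
  d <- b - a
  m <- mean(d)
  s2 <- sum((d - m)^2) / (length(d) - 1L)
  if (s2 == 0) degenerate_error("paired differences have zero variance")
  t <- m / sqrt(s2 / length(d))
  df <- length(d) - 1L
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Independent two-sample t-test (Welch, closed form)
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `t`, `p`, `df`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    argument_error("need at least 2 observations per sample")
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) degenerate_error("both samples have zero variance")
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' One-way ANOVA over three visits (closed form)
#'
#' Classical one-way F test treating the three visit samples as groups.
#'
#' @param v0,v1,v2 numeric vectors (each length >= 2).
#' @return list with `f`, `p`, `df1`, `df2`.
#' @examples
#' oneway_anova(c(1, 2), c(3, 4), c(5, 6))$f  # 16
#' @export
oneway_anova <- function(v0, v1, v2) {
  groups <- list(v0, v1, v2)
  if (any(vapply(groups, length, 1L) < 2L)) {
    argument_error("each visit sample needs at least 2 values")
  }
  ns <- vapply(groups, length, 1L)
  ms <- vapply(groups, mean, 1)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  grand <- sum(ns * ms) / sum(ns)
  ssb <- sum(ns * (ms - grand)^2)
  df1 <- 2L; df2 <- sum(ns) - 3L
  if (ssw == 0) degenerate_error("zero within-visit variance in every visit")
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Classify the temporal sign pattern of the two transition t statistics
#'
#' `t1` is the t statistic for baseline to visit 1, `t2` for visit 1 to
#' visit 2. An exact zero takes the sign of the nonzero partner; a double
#' zero is classified `same_sign_positive` by convention.
#'
#' @param t1,t2 finite t statistics.
#' @return one of `"positive_to_negative"`, `"negative_to_positive"`,
#'   `"same_sign_positive"`, `"same_sign_negative"`.
#' @examples
#' classify_sign_pattern(2.5, -3.1)  # positive_to_negative
#' @export
classify_sign_pattern <- function(t1, t2) {
  if (!is_scalar_number(t1) || !is_scalar_number(t2)) {
    argument_error("t statistics must be finite numbers")
  }
  sign_pattern_vec(t1, t2)
}

normalize_axis <- function(normalize) {
  if (isTRUE(normalize)) return("subject")
  if (isFALSE(normalize)) return("none")
  match.arg(normalize, c("none", "subject", "connection"))
}

sign_pattern_vec <- function(t1, t2) {
  s1 <- sign(t1); s2 <- sign(t2)
  s1[s1 == 0] <- s2[s1 == 0]
  s2[s2 == 0] <- s1[s2 == 0]
  out <- ifelse(s1 > 0 & s2 < 0, "positive_to_negative",
         ifelse(s1 < 0 & s2 > 0, "negative_to_positive",
         ifelse(s1 < 0 & s2 < 0, "same_sign_negative", "same_sign_positive")))
  out[is.na(t1) | is.na(t2)] <- NA_character_
  out
}

#' Build a per-connection longitudinal sample
#'
#' @param group group label.
#' @param connection length-2 integer vector `(source, target)`.
#' @param values subjects x visits numeric matrix of connection scalars
#'   (same subject order in every column; 3 visits).
#' @return list of class `group_connection_sample`.
#' @export
group_connection_sample <- function(group, connection, values) {
  if (length(connection) != 2L) argument_error("connection must be (source, target)")
  if (!is.matrix(values) || ncol(values) != 3L) {
    argument_error("values must be a subjects x 3-visit matrix")
  }
  if (nrow(values) < 2L) argument_error("need at least 2 subjects")
  structure(list(group = as.character(group),
                 connection = as.integer(connection), values = values),
            class = "group_connection_sample")
}

#' Vectorized longitudinal screen over many connections
#'
#' Matrix-level form of [find_significant_connections()]: the three visit
#' samples are given as subjects x connections matrices (same subject order
#' in each), and every column is screened at once with closed-form t and F
#' statistics. This is the routine the pipeline runs over the 13,340
#' directed connections; its output is asserted to agree with per-connection
#' recomputation by [paired_ttest()] / [oneway_anova()] and with
#' `stats::t.test` / `stats::oneway.test`.
#'
#' @param v0,v1,v2 subjects x connections matrices for baseline, visit 1 and
#'   visit 2.
#' @inheritParams find_significant_connections
#' @return data.frame with one row per connection (columns `t1`, `p1`, `t2`,
#'   `p2`, `f_anova`, `p_anova`, `significant`, `sign_pattern`,
#'   `degenerate`). Degenerate connections carry NA statistics and
#'   `significant = FALSE`; they are flagged, never dropped.
#' @export
screen_visits <- function(v0, v1, v2, alpha = 0.05, paired = TRUE,
                          normalize = c("none", "subject", "connection"),
                          correction = c("none", "BH")) {
  correction <- match.arg(correction)
  normalize <- normalize_axis(normalize)
  n <- nrow(v0)
  stopifnot(nrow(v1) == n, nrow(v2) == n, n >= 2L)
  zero_col <- rep(FALSE, ncol(v0))
  if (normalize == "subject") {
    # each subject-visit's vector over the supplied connections -> unit SS
    unitize <- function(v) {
      nrm <- sqrt(rowSums(v^2))
      nrm[nrm == 0] <- 1
      v / nrm
    }
    v0 <- unitize(v0); v1 <- unitize(v1); v2 <- unitize(v2)
  } else if (normalize == "connection") {
    # each visit's cross-subject vector per connection -> unit SS
    unitize <- function(v) {
      nrm <- sqrt(colSums(v^2))
      nrm[nrm == 0] <- 1     # all-zero columns flagged degenerate below
      sweep(v, 2L, nrm, "/")
    }
    zero_col <- colSums(v0^2) == 0 | colSums(v1^2) == 0 | colSums(v2^2) == 0
    v0 <- unitize(v0); v1 <- unitize(v1); v2 <- unitize(v2)
  }
  tstat <- function(a, b) {
    if (paired) {
      d <- b - a
      m <- colMeans(d)
      s2 <- colSums(sweep(d, 2L, m)^2) / (n - 1L)
      deg <- s2 == 0
      t <- ifelse(deg, 0, m / sqrt(s2 / n))
      list(t = t, p = 2 * stats::pt(-abs(t), n - 1L), deg = deg)
    } else {
      va <- colSums(sweep(a, 2L, colMeans(a))^2) / (n - 1L)
      vb <- colSums(sweep(b, 2L, colMeans(b))^2) / (n - 1L)
      se2 <- va / n + vb / n
      deg <- se2 == 0
      t <- ifelse(deg, 0, (colMeans(b) - colMeans(a)) / sqrt(se2))
      df <- ifelse(deg, n - 1L,
                   se2^2 / ((va / n)^2 / (n - 1L) + (vb / n)^2 / (n - 1L)))
      list(t = t, p = ifelse(deg, 1, 2 * stats::pt(-abs(t), df)), deg = deg)
    }
  }
  t1 <- tstat(v0, v1)
  t2 <- tstat(v1, v2)
  m0 <- colMeans(v0); m1 <- colMeans(v1); m2 <- colMeans(v2)
  ssw <- colSums(sweep(v0, 2L, m0)^2) + colSums(sweep(v1, 2L, m1)^2) +
         colSums(sweep(v2, 2L, m2)^2)
  grand <- (m0 + m1 + m2) / 3
  ssb <- n * ((m0 - grand)^2 + (m1 - grand)^2 + (m2 - grand)^2)
  df2 <- 3L * n - 3L
  fdeg <- ssw == 0
  f <- ifelse(fdeg, 0, (ssb / 2) / (ssw / df2))
  pf <- stats::pf(f, 2L, df2, lower.tail = FALSE)
  degenerate <- zero_col | t1$deg | t2$deg | fdeg
  p1a <- t1$p; p2a <- t2$p; pfa <- pf
  if (correction == "BH") {
    p1a <- stats::p.adjust(p1a, "BH")
    p2a <- stats::p.adjust(p2a, "BH")
    pfa <- stats::p.adjust(pfa, "BH")
  }
  significant <- !degenerate & p1a < alpha & p2a < alpha & pfa < alpha
  out <- data.frame(
    t1 = t1$t, p1 = t1$p, t2 = t2$t, p2 = t2$p, f_anova = f, p_anova = pf,
    significant = significant,
    sign_pattern = sign_pattern_vec(t1$t, t2$t),
    degenerate = degenerate, stringsAsFactors = FALSE)
  out$t1[degenerate] <- NA_real_; out$p1[degenerate] <- NA_real_
  out$t2[degenerate] <- NA_real_; out$p2[degenerate] <- NA_real_
  out$f_anova[degenerate] <- NA_real_; out$p_anova[degenerate] <- NA_real_
  out$sign_pattern[degenerate] <- NA_character_
  out
}

#' Screen connections for longitudinal significance
#'
#' The two-stage longitudinal procedure, applied per connection: (optional)
#' sum-of-squares normalization of each visit's cross-subject vector, a
#' paired t-test on each visit transition (baseline to visit 1, visit 1 to
#' visit 2), and a one-way ANOVA over the three visits. A connection is
#' significant when all three p-values fall below `alpha`. All statistics
#' are reported regardless of significance; connections with degenerate data
#' (zero-variance differences or all-zero visit vectors) are reported as
#' non-significant with `degenerate = TRUE`, never dropped.
#'
#' @param samples list of [group_connection_sample()] objects.
#' @param alpha significance level (default 0.05, uncorrected, matching the
#'   screening design; see `correction`).
#' @param paired use the paired t-test (default) or Welch's independent test.
#' @param normalize sum-of-squares normalization applied before testing:
#'   `"none"` (default) tests the connection values as supplied;
#'   `"subject"` scales each subject-visit's vector over the supplied
#'   connections to unit sum of squares (useful on real data to remove
#'   session-scale amplitude differences, but it couples all connections
#'   through the shared norm, so a strong change in a few connections
#'   perturbs the rest — keep the batch large); `"connection"` scales each
#'   visit's cross-subject vector per connection to unit sum of squares
#'   (this removes exactly the cross-visit rescaling the screen is meant to
#'   detect, leaving only coefficient-of-variation changes detectable, and
#'   is provided for completeness). `TRUE`/`FALSE` are accepted as aliases
#'   for `"subject"`/`"none"`.
#' @param correction "none" (default) or "BH" for Benjamini-Hochberg
#'   adjustment of each of the three p-value families before thresholding;
#'   reported p-values stay unadjusted.
#' @return data.frame with one row per connection: `group`, `source`,
#'   `target`, `t1`, `p1`, `t2`, `p2`, `f_anova`, `p_anova`, `significant`,
#'   `sign_pattern`, `degenerate`.
#' @export
find_significant_connections <- function(samples, alpha = 0.05,
                                         paired = TRUE,
                                         normalize = c("none", "subject",
                                                       "connection"),
                                         correction = c("none", "BH")) {
  correction <- match.arg(correction)
  normalize <- normalize_axis(normalize)
  if (!is.list(samples) || length(samples) == 0L) {
    argument_error("samples must be a non-empty list")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    argument_error("alpha must be in (0, 1)")
  }
  for (s in samples) {
    if (!inherits(s, "group_connection_sample")) {
      argument_error("each sample must be a group_connection_sample")
    }
  }
  ns <- vapply(samples, function(s) nrow(s$values), 1L)
  out <- vector("list", length(samples))
  for (n in unique(ns)) {
    idx <- which(ns == n)
    v0 <- vapply(samples[idx], function(s) s$values[, 1L], numeric(n))
    v1 <- vapply(samples[idx], function(s) s$values[, 2L], numeric(n))
    v2 <- vapply(samples[idx], function(s) s$values[, 3L], numeric(n))
    if (n == 1L) argument_error("need at least 2 subjects per sample")
    stats_df <- screen_visits(as.matrix(v0), as.matrix(v1), as.matrix(v2),
                              alpha = alpha, paired = paired,
                              normalize = normalize, correction = correction)
    for (k in seq_along(idx)) {
      s <- samples[[idx[k]]]
      out[[idx[k]]] <- cbind(
        data.frame(group = s$group, source = s$connection[1],
                   target = s$connection[2], stringsAsFactors = FALSE),
        stats_df[k, , drop = FALSE])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
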