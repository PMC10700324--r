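significant_rows <- function(results) {
  need <- c("source", "target", "significant")
  if (!is.data.frame(results) || !all(need %in% names(results))) {
    argument_error("results must be a data.frame with source, target, significant")
  }
  results[results$significant %in% TRUE, , drop = FALSE]
}

#' Count significant connections by source region
#'
#' For directed results restricted to one group: number of significant
#' connections originating at each source region. The counts sum to the
#' total number of significant connections.
#'
#' @param results screen results ([find_significant_connections()]); only
#'   rows with `significant == TRUE` are counted.
#' @param table optional region table to attach abbreviations.
#' @return data.frame with columns `source`, `abbreviation` (if a table is
#'   given) and `count`, sorted by decreasing count; zero rows when no
#'   connection is significant.
#' @export
count_by_source_region <- function(results, table = NULL) {
  sig <- significant_rows(results)
  if (nrow(sig) == 0L) {
    out <- data.frame(source = integer(0), count = integer(0))
  } else {
    tab <- table(sig$source)
    out <- data.frame(source = as.integer(names(tab)),
                      count = as.integer(tab))
    out <- out[order(-out$count, out$source), , drop = FALSE]
  }
  if (!is.null(table)) {
    out$abbreviation <- table$abbreviation[match(out$source, table$index)]
    out <- out[, c("source", "abbreviation", "count")]
  }
  rownames(out) <- NULL
  out
}

#' Count significant connections by unordered network pair
#'
#' Each significant connection increments the cell of the unordered pair
#' {network(source), network(target)}; direction is ignored, so connections
#' i to j and j to i land in the same cell. Within-network connections land
#' on the diagonal.
#'
#' @param results screen results; only significant rows are counted.
#' @param table region table mapping region indices to networks.
#' @return 6 x 6 symmetric integer matrix over [NETWORKS]; the sum of the
#'   upper triangle plus diagonal equals the number of significant
#'   connections.
#' @export
count_network_pairs <- function(results, table = load_region_table()) {
  sig <- significant_rows(results)
  counts <- matrix(0L, length(NETWORKS), length(NETWORKS),
                   dimnames = list(NETWORKS, NETWORKS))
  if (nrow(sig)) {
    if (any(!sig$source %in% table$index) || any(!sig$target %in% table$index)) {
      argument_error("results reference a region index absent from the table")
    }
    ns <- table$network[match(sig$source, table$index)]
    nt <- table$network[match(sig$target, table$index)]
    a <- pmin(match(ns, NETWORKS), match(nt, NETWORKS))
    b <- pmax(match(ns, NETWORKS), match(nt, NETWORKS))
    for (k in seq_along(a)) {
      counts[a[k], b[k]] <- counts[a[k], b[k]] + 1L
    }
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  }
  counts
}

#' Per-network percentage contribution
#'
#' A network's contributing regions are the distinct regions of that network
#' appearing as source or target of any significant connection; the
#' percentage is taken on the common denominator of all distinct significant
#' regions (so percentages sum to 100 up to rounding). Setting
#' `denominator = "endpoints"` counts connection endpoints (region
#' instances) instead of distinct regions.
#'
#' @param results screen results; only significant rows contribute.
#' @param table region table.
#' @param denominator "regions" (distinct regions, default) or "endpoints".
#' @return data.frame with columns `network`, `n_regions`, `percent`; all
#'   zero when no connection is significant.
#' @export
percent_contribution <- function(results, table = load_region_table(),
                                 denominator = c("regions", "endpoints")) {
  denominator <- match.arg(denominator)
  sig <- significant_rows(results)
  out <- data.frame(network = NETWORKS, n_regions = 0L, percent = 0,
                    stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(out)
  if (denominator == "regions") {
    regions <- unique(c(sig$source, sig$target))
    nets <- table$network[match(regions, table$index)]
  } else {
    endpoints <- c(sig$source, sig$target)
    nets <- table$network[match(endpoints, table$index)]
  }
  if (anyNA(nets)) argument_error("results reference a region index absent from the table")
  tab <- table(factor(nets, levels = NETWORKS))
  out$n_regions <- as.integer(tab)
  out$percent <- 100 * out$n_regions / sum(out$n_regions)
  out
}

#' Compare per-network contribution between two connectivity methods
#'
#' Pairs the percentage-contribution tables of the CorrTF arm and the
#' Pearson arm per network and reports their difference. No statistical test
#' is attached; the comparison is descriptive.
#'
#' @param corrtf_table,pearson_table outputs of [percent_contribution()]
#'   over the same six networks.
#' @return data.frame with `network`, `corrtf_percent`, `pearson_percent`,
#'   `difference` (corrtf minus pearson).
#' @export
compare_methods <- function(corrtf_table, pearson_table) {
  if (!setequal(corrtf_table$network, pearson_table$network)) {
    argument_error("the two tables must cover the same networks")
  }
  m <- match(corrtf_table$network, pearson_table$network)
  data.frame(network = corrtf_table$network,
             corrtf_percent = corrtf_table$percent,
             pearson_percent = pearson_table$percent[m],
             difference = corrtf_table$percent - pearson_table$percent[m],
             stringsAsFactors = FALSE)
}

#' Write a CIRCOS-tableviewer-compatible count table
#'
#' Writes the network-pair count matrix as a labeled tab-separated table the
#' CIRCOS online tableviewer accepts for chord plotting.
#'
#' @param counts matrix from [count_network_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circos_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
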