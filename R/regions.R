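#' The six functional network labels
#'
#' Closed vocabulary used to group the 116 AAL regions: sensorimotor cortex
#' (SMC), executive attention network (EAN), visual cortex (VC), cerebellum
#' (Cereb), default-mode network (DMN) and subcortical nuclei (SN).
#'
#' @export
NETWORKS <- c("SMC", "EAN", "VC", "Cereb", "DMN", "SN")

#' Load the AAL-116 region table
#'
#' Returns the packaged table of the 116 AAL regions (index, name,
#' abbreviation, hemisphere, functional network). Paired cerebral regions
#' follow the standard AAL ordering (odd index = left, even = right); the
#' eight vermis subdivisions are midline. The region-to-network assignment is
#' a documented reconstruction of conventional AAL network groupings and can
#' be overridden per region.
#'
#' @param mapping_override optional path to a YAML or TSV file reassigning
#'   networks. YAML: a mapping from region index or abbreviation to a network
#'   label. TSV: two columns, `region` (index or abbreviation) and `network`.
#' @return a data.frame with columns `index`, `name`, `abbreviation`,
#'   `hemisphere` (`left`/`right`/`midline`) and `network` (one of
#'   [NETWORKS]), 116 rows in atlas order.
#' @examples
#' tab <- load_region_table()
#' nrow(tab)        # 116
#' table(tab$network)
#' @export
load_region_table <- function(mapping_override = NULL) {
  path <- system.file("extdata", "aal116_regions.tsv", package = "corrtf",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_region_table(tab)
  if (!is.null(mapping_override)) {
    ov <- read_network_override(mapping_override)
    for (k in seq_len(nrow(ov))) {
      key <- ov$region[k]
      net <- ov$network[k]
      if (!net %in% NETWORKS) {
        config_error(sprintf(
          "override assigns unknown network '%s' (must be one of %s)",
          net, paste(NETWORKS, collapse = ", ")))
      }
      idx <- suppressWarnings(as.integer(key))
      if (!is.na(idx)) {
        if (idx < 1L || idx > nrow(tab)) {
          config_error(sprintf("override names unknown region index %d", idx))
        }
        tab$network[idx] <- net
      } else {
        hit <- which(tab$abbreviation == key)
        if (length(hit) != 1L) {
          config_error(sprintf("override names unknown region '%s'", key))
        }
        tab$network[hit] <- net
      }
    }
  }
  tab
}

# Accepts YAML ('index-or-abbr: network' mapping) or two-column TSV.
read_network_override <- function(path) {
  if (!file.exists(path)) config_error(sprintf("override file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    if (!is.list(y) || is.null(names(y)) || any(names(y) == "")) {
      config_error("YAML override must be a mapping region -> network")
    }
    data.frame(region = names(y),
               network = vapply(y, as.character, character(1)),
               stringsAsFactors = FALSE)
  } else {
    ov <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("region", "network") %in% names(ov))) {
      config_error("TSV override needs columns 'region' and 'network'")
    }
    ov[, c("region", "network")]
  }
}

validate_region_table <- function(tab) {
  if (nrow(tab) != 116L || !identical(tab$index, 1:116)) {
    config_error("region table must have indices exactly 1..116 in order")
  }
  if (anyDuplicated(tab$abbreviation)) {
    config_error("region abbreviations must be unique")
  }
  if (!all(tab$network %in% NETWORKS)) {
    config_error("region table contains a network outside the six labels")
  }
  if (!all(tab$hemisphere %in% c("left", "right", "midline"))) {
    config_error("hemisphere must be left, right or midline")
  }
  invisible(tab)
}

#' Functional network of a region
#'
#' @param region_index integer region index in 1..116 (or 1..nrow(table)).
#' @param table region table from [load_region_table()].
#' @return the network label (one of [NETWORKS]).
#' @examples
#' network_of(110, load_region_table())  # Vermis_3 -> "Cereb"
#' @export
network_of <- function(region_index, table = load_region_table()) {
  if (!is_count(region_index) || region_index > nrow(table)) {
    argument_error(sprintf("region index must be in 1..%d", nrow(table)))
  }
  table$network[[region_index]]
}

#' Write a region table to TSV
#'
#' Round-trips through [utils::read.delim()]: writing and reloading yields an
#' identical table.
#'
#' @param table region table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(table, path) {
  validate_region_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
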