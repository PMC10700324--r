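#' Build a pipeline run configuration
#'
#' One configuration object drives the whole analysis; together with the
#' seed it fully determines every output file. Defaults reproduce the
#' standard screening conditions: 0.01-0.08 Hz band at TR = 3 s, scalar
#' CorrTF by in-band mean ratio, paired t-tests plus one-way ANOVA at
#' alpha = 0.05 on the raw connection values with no multiplicity
#' correction, both connectivity arms. Sum-of-squares normalization (subject
#' or connection axis) is selectable; see [screen_visits()] for why neither
#' is the default.
#'
#' @param mode "synthetic" (default) or "real".
#' @param cohort a [cohort_config()] for synthetic mode, or for real mode a
#'   list with `manifest` (path to a manifest TSV; see [read_cohort()]) and
#'   optionally `atlas` (path to a 3D integer-label NIfTI, required when the
#'   manifest lists 4D NIfTI files).
#' @param n_discard leading volumes dropped from NIfTI inputs (real mode).
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param filter_order Butterworth design order.
#' @param connectivity_kind "both" (default), "corrtf" or "pearson".
#' @param eps_rel relative denominator floor for CorrTF.
#' @param aggregate CorrTF in-band aggregation: "mean", "median" or "max".
#' @param alpha significance level.
#' @param paired paired (TRUE) or independent t-tests.
#' @param normalize sum-of-squares normalization axis: "none" (default),
#'   "subject" or "connection"; see [screen_visits()].
#' @param correction "none" or "BH".
#' @param seed integer seed driving all randomness (overrides the cohort
#'   config's seed so one value controls the run).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       cohort = cohort_config(effects = default_effects()),
                       n_discard = 10L,
                       low_hz = 0.01, high_hz = 0.08, filter_order = 4L,
                       connectivity_kind = c("both", "corrtf", "pearson"),
                       eps_rel = 1e-12,
                       aggregate = c("mean", "median", "max"),
                       alpha = 0.05, paired = TRUE,
                       normalize = c("none", "subject", "connection"),
                       correction = c("none", "BH"),
                       seed = 1L) {
  structure(list(
    mode = match.arg(mode), cohort = cohort,
    prep = list(n_discard = as.integer(n_discard), low_hz = low_hz,
                high_hz = high_hz, filter_order = as.integer(filter_order)),
    connectivity = list(kind = match.arg(connectivity_kind),
                        eps_rel = eps_rel, aggregate = match.arg(aggregate)),
    stats = list(alpha = alpha, paired = isTRUE(paired),
                 normalize = normalize_axis(normalize),
                 correction = match.arg(correction)),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `cohort` may carry
#' `group_sizes`, `n_visits`, `n_regions`, `n_timepoints`, `tr_seconds`,
#' `signal_band`, `noise_sd`, `n_components` and a list of `effects`
#' (each with `group`, `source_region`, `target_region`, `visit_gains`),
#' or `default_effects: true` to use [default_effects()].
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) argument_error(sprintf("config not found: %s", path))
  y <- tryCatch(yaml::read_yaml(path), error = function(e) {
    config_error(sprintf("cannot parse config %s: %s", path, conditionMessage(e)))
  })
  mode <- y$mode %||% "synthetic"
  cohort <- if (identical(mode, "real")) {
    y$cohort
  } else {
    cy <- y$cohort %||% list()
    effects <- list()
    if (isTRUE(cy$default_effects)) {
      effects <- default_effects()
    } else if (!is.null(cy$effects)) {
      effects <- lapply(cy$effects, function(e) {
        effect_spec(e$group, e$source_region, e$target_region,
                    unlist(e$visit_gains))
      })
    }
    cohort_config(
      group_sizes = unlist(cy$group_sizes %||%
                             list(NC = 29, EMCI = 23, LMCI = 24, AD = 23)),
      n_visits = cy$n_visits %||% 3, n_regions = cy$n_regions %||% 116,
      n_timepoints = cy$n_timepoints %||% 130,
      tr_seconds = cy$tr_seconds %||% 3,
      signal_band = unlist(cy$signal_band %||% c(0.01, 0.08)),
      noise_sd = cy$noise_sd %||% 0.5,
      n_components = cy$n_components %||% 5,
      effects = effects, seed = y$seed %||% 1L)
  }
  run_config(mode = mode, cohort = cohort,
             n_discard = y$prep$n_discard %||% 10L,
             low_hz = y$prep$low_hz %||% 0.01,
             high_hz = y$prep$high_hz %||% 0.08,
             filter_order = y$prep$filter_order %||% 4L,
             connectivity_kind = y$connectivity$kind %||% "both",
             eps_rel = y$connectivity$eps_rel %||% 1e-12,
             aggregate = y$connectivity$aggregate %||% "mean",
             alpha = y$stats$alpha %||% 0.05,
             paired = y$stats$paired %||% TRUE,
             normalize = y$stats$normalize %||% "none",
             correction = y$stats$correction %||% "none",
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration
#'
#' Returns findings instead of stopping: `error` rows for invariant
#' violations (for example a band edge at or above Nyquist), `warning` rows
#' for departures from the standard screening defaults (alpha other than
#' 0.05, multiplicity correction enabled, a band other than 0.01-0.08 Hz).
#'
#' @param config a `run_config`.
#' @return data.frame with columns `level` and `message`; zero rows for a
#'   default configuration.
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  tr <- if (config$mode == "synthetic") config$cohort$tr_seconds else 3
  nyq <- 1 / (2 * tr)
  p <- config$prep
  if (!(0 < p$low_hz && p$low_hz < p$high_hz)) {
    add("error", "band must satisfy 0 < low_hz < high_hz")
  }
  if (p$high_hz >= nyq) {
    add("error", sprintf("high_hz (%g) is at or above Nyquist (%g Hz) for TR %g s",
                         p$high_hz, nyq, tr))
  }
  if (p$n_discard < 0) add("error", "n_discard must be non-negative")
  s <- config$stats
  if (!(s$alpha > 0 && s$alpha < 1)) {
    add("error", "alpha must lie in (0, 1)")
  } else if (s$alpha != 0.05) {
    add("warning", sprintf("alpha = %g departs from the 0.05 screening default",
                           s$alpha))
  }
  if (s$correction != "none") {
    add("warning", "multiplicity correction enabled; the default screen is uncorrected")
  }
  if (p$low_hz != 0.01 || p$high_hz != 0.08) {
    add("warning", sprintf("band %g-%g Hz departs from the 0.01-0.08 Hz default",
                           p$low_hz, p$high_hz))
  }
  if (config$mode == "real") {
    if (is.null(config$cohort$manifest)) {
      add("error", "real mode requires cohort$manifest")
    } else if (!file.exists(config$cohort$manifest)) {
      add("error", sprintf("manifest not found: %s", config$cohort$manifest))
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(level = character(0), message = character(0)))
  }
  do.call(rbind, findings)
}

#' Run the end-to-end longitudinal connectivity pipeline
#'
#' Stages: cohort (simulate or ingest), band-pass preparation, per
#' subject-visit connectivity (CorrTF and/or Pearson + Fisher z), the
#' per-group longitudinal screen over every connection, and region/network
#' summaries. Every group is processed identically; an empty significant set
#' (the expected healthy-control outcome) is a data result, not a branch.
#' Identical config + seed produces byte-identical output files.
#'
#' @param config a `run_config`.
#' @param output_dir directory for result files (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `results` (per group, per arm screen
#'   data.frames), `summaries` (per group), `counts`, and `manifest` (path
#'   of the JSON run manifest).
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  findings <- validate_config(config)
  errs <- findings$message[findings$level == "error"]
  if (length(errs)) config_error(paste(errs, collapse = "; "))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  ## stage: cohort ----------------------------------------------------------
  if (config$mode == "synthetic") {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- config$seed
    cohort <- generate_cohort(cohort_cfg)
    tr <- cohort_cfg$tr_seconds
    table <- if (cohort_cfg$n_regions == 116L) load_region_table() else NULL
  } else {
    cohort <- ingest_real_cohort(config)
    tr <- cohort[[1]]$tr_seconds
    table <- if (nrow(cohort[[1]]$series) == 116L) load_region_table() else NULL
  }
  say("cohort: %d subject-visit series of %d regions x %d time points",
      length(cohort), nrow(cohort[[1]]$series), ncol(cohort[[1]]$series))

  ## stage: prep ------------------------------------------------------------
  p <- config$prep
  for (i in seq_along(cohort)) {
    cohort[[i]]$series <- bandpass_filter(cohort[[i]]$series, p$low_hz,
                                          p$high_hz, cohort[[i]]$tr_seconds,
                                          p$filter_order)
  }

  ## stage: connectivity ----------------------------------------------------
  kind <- config$connectivity$kind
  band <- c(p$low_hz, p$high_hz)
  do_corrtf <- kind %in% c("both", "corrtf")
  do_pearson <- kind %in% c("both", "pearson")
  conn <- lapply(cohort, function(sv) {
    out <- list()
    if (do_corrtf) {
      out$corrtf <- tryCatch(
        corrtf_matrix(sv$series, band, sv$tr_seconds,
                      config$connectivity$eps_rel,
                      config$connectivity$aggregate),
        corrtf_degenerate_error = function(e) {
          stop_corrtf(sprintf("connectivity stage, subject %s visit %d: %s",
                              sv$subject_id, sv$visit, conditionMessage(e)),
                      "corrtf_degenerate_error")
        })
    }
    if (do_pearson) out$fisher <- fisher_z(pearson_matrix(sv$series))
    out
  })
  say("connectivity: %s matrices for %d subject-visits", kind, length(conn))

  ## stage: stats + summaries, per group ------------------------------------
  meta <- data.frame(
    subject = vapply(cohort, function(x) x$subject_id, ""),
    group = vapply(cohort, function(x) x$group, ""),
    visit = vapply(cohort, function(x) x$visit, 0L))
  R <- nrow(cohort[[1]]$series)
  dir_idx <- which(row(diag(R)) != col(diag(R)))     # off-diagonal, col-major
  dir_edges <- data.frame(source = col(diag(R))[dir_idx],
                          target = row(diag(R))[dir_idx])
  ut_idx <- which(upper.tri(diag(R)))
  ut_edges <- data.frame(source = row(diag(R))[ut_idx],
                         target = col(diag(R))[ut_idx])
  groups <- unique(meta$group)
  s <- config$stats
  results <- list(); summaries <- list(); files <- character(0)
  n_sig <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    subjects <- sort(unique(meta$subject[meta$group == g]))
    visits <- sort(unique(meta$visit[meta$group == g]))
    if (length(visits) != 3L) {
      config_error(sprintf("group %s has %d visits; the screen needs 3",
                           g, length(visits)))
    }
    pick <- function(arm, idx) {
      vapply(visits, function(v) {
        vapply(subjects, function(sj) {
          k <- which(meta$subject == sj & meta$visit == v)
          if (length(k) != 1L) {
            config_error(sprintf("subject %s misses visit %d", sj, v))
          }
          unclass(conn[[k]][[arm]])[idx]
        }, numeric(length(idx)))
      }, matrix(0, length(idx), length(subjects)))
    }
    group_res <- list()
    if (do_corrtf) {
      vals <- pick("corrtf", dir_idx)  # connections x subjects x visits
      res <- screen_visits(t(vals[, , 1]), t(vals[, , 2]), t(vals[, , 3]),
                           alpha = s$alpha, paired = s$paired,
                           normalize = s$normalize, correction = s$correction)
      res <- cbind(data.frame(group = g, dir_edges), res)
      group_res$corrtf <- res
      n_sig[g] <- sum(res$significant)
    }
    if (do_pearson) {
      vals <- pick("fisher", ut_idx)
      res <- screen_visits(t(vals[, , 1]), t(vals[, , 2]), t(vals[, , 3]),
                           alpha = s$alpha, paired = s$paired,
                           normalize = s$normalize, correction = s$correction)
      group_res$pearson <- cbind(data.frame(group = g, ut_edges), res)
    }
    results[[g]] <- group_res
    summ <- list()
    tab <- table %||% data.frame(index = seq_len(R),
                                 abbreviation = sprintf("R%03d", seq_len(R)),
                                 network = rep(NETWORKS, length.out = R))
    if (do_corrtf) {
      summ$source_counts <- count_by_source_region(group_res$corrtf, tab)
      summ$network_pairs <- count_network_pairs(group_res$corrtf, tab)
      summ$contribution_corrtf <- percent_contribution(group_res$corrtf, tab)
    }
    if (do_pearson) {
      summ$contribution_pearson <- percent_contribution(group_res$pearson, tab)
    }
    if (do_corrtf && do_pearson) {
      summ$comparison <- compare_methods(summ$contribution_corrtf,
                                         summ$contribution_pearson)
    }
    summaries[[g]] <- summ
    files <- c(files, write_group_outputs(g, group_res, summ, output_dir))
    say("group %s: %s significant CorrTF connections",
        g, if (do_corrtf) n_sig[g] else "NA")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("corrtf")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, mode = config$mode,
    config = config_echo(config),
    n_subject_visits = length(cohort),
    n_regions = R,
    n_directed_connections = nrow(dir_edges),
    significant_corrtf = as.list(n_sig),
    files = files)
  mpath <- file.path(output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(results = results, summaries = summaries,
                 counts = n_sig, manifest = mpath, files = files))
}

write_group_outputs <- function(g, group_res, summ, output_dir) {
  files <- character(0)
  wcsv <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(group_res$corrtf)) {
    wcsv(group_res$corrtf, sprintf("results_corrtf_%s.csv", g))
    wcsv(summ$source_counts, sprintf("source_counts_%s.csv", g))
    write_circos_table(summ$network_pairs,
                       file.path(output_dir, sprintf("network_pairs_%s.tsv", g)))
    files <- c(files, sprintf("network_pairs_%s.tsv", g))
    wcsv(summ$contribution_corrtf, sprintf("contribution_corrtf_%s.csv", g))
  }
  if (!is.null(group_res$pearson)) {
    wcsv(group_res$pearson, sprintf("results_pearson_%s.csv", g))
    wcsv(summ$contribution_pearson, sprintf("contribution_pearson_%s.csv", g))
  }
  if (!is.null(summ$comparison)) {
    wcsv(summ$comparison, sprintf("method_comparison_%s.csv", g))
  }
  files
}

config_echo <- function(config) {
  out <- unclass(config)
  if (inherits(out$cohort, "cohort_config")) {
    ch <- unclass(out$cohort)
    ch$group_sizes <- as.list(ch$group_sizes)
    ch$effects <- lapply(ch$effects, unclass)
    out$cohort <- ch
  }
  out
}

# Real-data ingestion: TSV series are used as-is (assumed already trimmed);
# 4D NIfTI files get the leading-volume discard and ROI mean extraction
# against the label atlas.
ingest_real_cohort <- function(config) {
  manifest_path <- config$cohort$manifest
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "visit", "file", "tr")
  if (!all(need %in% names(manifest))) {
    config_error(sprintf("manifest must have columns %s",
                         paste(need, collapse = ", ")))
  }
  base <- dirname(manifest_path)
  is_nifti <- grepl("\\.nii(\\.gz)?$", manifest$file)
  labels <- NULL
  if (any(is_nifti)) {
    if (is.null(config$cohort$atlas)) {
      config_error("NIfTI inputs need cohort$atlas (label volume)")
    }
    labels <- array(as.integer(round(RNifti::readNifti(config$cohort$atlas))),
                    dim = dim(RNifti::readNifti(config$cohort$atlas)))
  }
  table <- load_region_table()
  lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(base, manifest$file[i])
    if (!file.exists(f)) argument_error(sprintf("input file not found: %s", f))
    series <- if (is_nifti[i]) {
      vol <- RNifti::readNifti(f)
      vol <- discard_initial_volumes(array(as.numeric(vol), dim = dim(vol)),
                                     config$prep$n_discard)
      tb <- if (max(labels) == 116L) table else
        data.frame(index = seq_len(max(labels)))
      extract_roi_means(vol, labels, tb)
    } else {
      t(as.matrix(utils::read.delim(f, check.names = FALSE)))
    }
    structure(list(subject_id = manifest$subject[i], group = manifest$group[i],
                   visit = manifest$visit[i], series = series,
                   tr_seconds = manifest$tr[i]),
              class = "subject_visit_series")
  })
}
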