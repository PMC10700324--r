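#' Cohort configuration for the synthetic generator
#'
#' Defaults reproduce the study layout the analysis expects: four groups
#' (NC 29, EMCI 23, LMCI 24, AD 23 subjects), three visits per subject, and a
#' 116-region by 130-time-point matrix per subject-visit sampled at TR = 3 s
#' with signal content confined to the 0.01–0.08 Hz BOLD band.
#'
#' @param group_sizes named integer vector, subjects per group.
#' @param n_visits visits per subject (visit 0 is baseline).
#' @param n_regions regions per series matrix.
#' @param n_timepoints time points per series.
#' @param tr_seconds sampling interval (repetition time), seconds.
#' @param signal_band length-2 numeric, low/high band edge in Hz; latent
#'   oscillation frequencies are drawn uniformly inside it.
#' @param noise_sd standard deviation of additive white noise, relative to the
#'   unit-SD latent signals.
#' @param n_components number of sinusoidal components per region latent.
#' @param effects list of [effect_spec()] objects to inject.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(NC = 29, EMCI = 23, LMCI = 24, AD = 23),
                          n_visits = 3,
                          n_regions = 116,
                          n_timepoints = 130,
                          tr_seconds = 3,
                          signal_band = c(0.01, 0.08),
                          noise_sd = 0.5,
                          n_components = 5,
                          effects = list(),
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    config_error("group_sizes must be a named vector")
  }
  if (!all(vapply(group_sizes, is_count, logical(1)))) {
    config_error("all group sizes must be positive integers")
  }
  for (arg in list(n_visits, n_regions, n_timepoints)) {
    if (!is_count(arg)) config_error("counts must be positive integers")
  }
  check_band(signal_band[1], signal_band[2], tr_seconds)
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    config_error("noise_sd must be a non-negative number")
  }
  if (!is_count(n_components)) config_error("n_components must be >= 1")
  cfg <- structure(list(
    group_sizes = group_sizes, n_visits = as.integer(n_visits),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, signal_band = as.numeric(signal_band),
    noise_sd = noise_sd, n_components = as.integer(n_components),
    effects = effects, seed = as.integer(seed)
  ), class = "cohort_config")
  for (e in effects) validate_effect(e, cfg)
  cfg
}

#' Injected longitudinal connectivity effect
#'
#' Couples the target region's latent signal to the source region's latent
#' signal with a visit-specific gain, so the directed connectivity of the
#' pair (source to target) changes across visits in expectation. Gains that
#' rise then fall produce the positive-to-negative t-sign pattern at the two
#' visit transitions; falling-then-rising gains produce the opposite.
#'
#' @param group group label the effect applies to.
#' @param source_region,target_region region indices (source feeds target).
#' @param visit_gains numeric vector of one coupling gain per visit.
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(group, source_region, target_region, visit_gains) {
  if (!is_count(source_region) || !is_count(target_region)) {
    config_error("effect regions must be positive integers")
  }
  if (source_region == target_region) {
    config_error("effect source and target must differ")
  }
  if (!is.numeric(visit_gains) || !all(is.finite(visit_gains))) {
    config_error("visit_gains must be finite numbers")
  }
  structure(list(group = as.character(group),
                 source_region = as.integer(source_region),
                 target_region = as.integer(target_region),
                 visit_gains = as.numeric(visit_gains)),
            class = "effect_spec")
}

validate_effect <- function(e, cfg) {
  if (!inherits(e, "effect_spec")) config_error("effects must be effect_spec objects")
  if (!e$group %in% names(cfg$group_sizes)) {
    config_error(sprintf("effect references unknown group '%s'", e$group))
  }
  if (e$source_region > cfg$n_regions || e$target_region > cfg$n_regions) {
    config_error("effect region index out of range")
  }
  if (length(e$visit_gains) != cfg$n_visits) {
    config_error(sprintf("visit_gains must have length n_visits (%d)",
                         cfg$n_visits))
  }
  invisible(e)
}

#' Default injected effects for the demonstration cohort
#'
#' A scaled-down longitudinal effect structure over the AAL-116 atlas: no
#' effects in NC; EMCI effects sourced mainly from Vermis_3 plus the left
#' calcarine; LMCI effects from the left Cerebelum_10 and right hippocampus;
#' AD effects from the left superior temporal pole (rise-then-fall gains,
#' giving the positive-to-negative t pattern) and one from the right superior
#' temporal gyrus with the opposite pattern. Effect counts decrease with
#' disease severity (EMCI > LMCI > AD > NC = 0).
#'
#' @return list of [effect_spec()] objects.
#' @export
default_effects <- function() {
  up_down <- c(0.5, 2.0, 0.5)     # rises baseline->v1, falls v1->v2
  down_up <- c(2.0, 0.5, 2.0)
  ef <- list()
  # EMCI: 10 from Vermis_3 (index 110), 2 from Calcarine_L (43)
  emci_targets <- c(1, 19, 43, 57, 69, 79, 81, 59, 91, 109)
  for (t in emci_targets) ef <- c(ef, list(effect_spec("EMCI", 110, t, up_down)))
  for (t in c(67, 85)) ef <- c(ef, list(effect_spec("EMCI", 43, t, up_down)))
  # LMCI: 6 from Cerebelum_10_L (107), 2 from Hippocampus_R (38)
  for (t in c(2, 20, 44, 58, 82, 110)) {
    ef <- c(ef, list(effect_spec("LMCI", 107, t, up_down)))
  }
  for (t in c(35, 67)) ef <- c(ef, list(effect_spec("LMCI", 38, t, up_down)))
  # AD: 4 from Temporal_Pole_Sup_L (83), 1 from Temporal_Sup_R (82)
  for (t in c(37, 61, 89, 107)) {
    ef <- c(ef, list(effect_spec("AD", 83, t, up_down)))
  }
  ef <- c(ef, list(effect_spec("AD", 82, 66, down_up)))
  ef
}

#' Generate a synthetic longitudinal cohort
#'
#' Each region's latent signal is a sum of `n_components` sinusoids with
#' frequencies drawn uniformly inside `signal_band`, random phases and
#' amplitudes, rescaled to unit standard deviation. Latents are drawn once
#' per subject and held fixed across visits; white noise of scale `noise_sd`
#' is redrawn per visit, so under no injected effects a connection's values
#' are exchangeable across visits. For each [effect_spec()], the target
#' region's observed series additionally receives the source region's latent
#' scaled by the visit's gain.
#'
#' @param config a [cohort_config()].
#' @return list of subject-visit series objects, each a list with fields
#'   `subject_id`, `group`, `visit` (0-based), `series` (regions x time
#'   matrix) and `tr_seconds`.
#' @examples
#' cfg <- cohort_config(group_sizes = c(NC = 2), n_regions = 4,
#'                      n_timepoints = 40, seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort)  # 2 subjects x 3 visits
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  for (e in config$effects) validate_effect(e, config)
  R <- config$n_regions; Tn <- config$n_timepoints
  tt <- (seq_len(Tn) - 1) * config$tr_seconds
  set.seed(config$seed)
  out <- vector("list", sum(config$group_sizes) * config$n_visits)
  k <- 0L
  for (g in names(config$group_sizes)) {
    g_effects <- Filter(function(e) e$group == g, config$effects)
    for (s in seq_len(config$group_sizes[[g]])) {
      latent <- draw_latent(R, tt, config$signal_band, config$n_components)
      for (v in seq_len(config$n_visits) - 1L) {
        series <- latent
        for (e in g_effects) {
          series[e$target_region, ] <- series[e$target_region, ] +
            e$visit_gains[v + 1L] * latent[e$source_region, ]
        }
        if (config$noise_sd > 0) {
          series <- series + matrix(stats::rnorm(R * Tn, sd = config$noise_sd),
                                    R, Tn)
        }
        k <- k + 1L
        out[[k]] <- structure(list(
          subject_id = sprintf("%s_%02d", g, s), group = g, visit = v,
          series = series, tr_seconds = config$tr_seconds
        ), class = "subject_visit_series")
      }
    }
  }
  out
}

# One unit-SD band-limited latent per region: rows regions, cols time.
draw_latent <- function(R, tt, band, K) {
  L <- matrix(0, R, length(tt))
  for (r in seq_len(R)) {
    f <- stats::runif(K, band[1], band[2])
    ph <- stats::runif(K, 0, 2 * pi)
    a <- stats::runif(K, 0.5, 1)
    x <- drop(a %*% sin(outer(2 * pi * f, tt) + ph))
    L[r, ] <- x / stats::sd(x)
  }
  L
}

#' Generate a labeled 4D volume fixture
#'
#' Builds a small 4D functional volume plus a 3D integer label volume in
#' which each region occupies a disjoint voxel block carrying that region's
#' ground-truth band-limited series (plus optional per-voxel noise).
#' Intended as an ingestion-test input for ROI mean extraction.
#'
#' @param n_regions number of regions to place.
#' @param shape length-3 integer vector of spatial dimensions.
#' @param n_volumes number of time points.
#' @param seed integer seed.
#' @param tr_seconds sampling interval for the ground-truth series.
#' @param signal_band frequency band of the ground-truth series (Hz).
#' @param voxel_noise_sd per-voxel additive noise SD (0 = exact recovery).
#' @return list with `volumes` (4D array), `labels` (3D integer array, 0 =
#'   background) and `truth` (n_regions x n_volumes matrix of region means).
#' @export
generate_labeled_volume_fixture <- function(n_regions, shape, n_volumes,
                                            seed = 1L, tr_seconds = 3,
                                            signal_band = c(0.01, 0.08),
                                            voxel_noise_sd = 0) {
  if (!is_count(n_regions) || !is_count(n_volumes)) {
    argument_error("n_regions and n_volumes must be positive integers")
  }
  if (length(shape) != 3L || !all(vapply(shape, is_count, logical(1)))) {
    argument_error("shape must be three positive integers")
  }
  shape <- as.integer(shape)
  # Blocks are laid out inside shape - 1 so a background slab (label 0)
  # always remains along each axis with extent > 1.
  extent <- pmax(shape - 1L, 1L)
  # Smallest block grid (nx, ny, nz) whose cell count reaches n_regions,
  # with every block at least one voxel in each dimension.
  grid <- block_grid(n_regions, extent)
  if (is.null(grid)) {
    argument_error(sprintf("cannot place %d regions in a %s grid", n_regions,
                           paste(shape, collapse = "x")))
  }
  set.seed(seed)
  tt <- (seq_len(n_volumes) - 1) * tr_seconds
  truth <- draw_latent(n_regions, tt, signal_band, 5L)
  labels <- array(0L, dim = shape)
  volumes <- array(0, dim = c(shape, n_volumes))
  bounds <- function(n_blocks, extent, i) {
    lo <- floor((i - 1) * extent / n_blocks) + 1L
    hi <- floor(i * extent / n_blocks)
    lo:hi
  }
  r <- 0L
  for (iz in seq_len(grid[3])) for (iy in seq_len(grid[2])) {
    for (ix in seq_len(grid[1])) {
      r <- r + 1L
      if (r > n_regions) break
      xs <- bounds(grid[1], extent[1], ix)
      ys <- bounds(grid[2], extent[2], iy)
      zs <- bounds(grid[3], extent[3], iz)
      labels[xs, ys, zs] <- r
      nv <- length(xs) * length(ys) * length(zs)
      block <- array(rep(truth[r, ], each = nv), dim = c(length(xs),
                     length(ys), length(zs), n_volumes))
      if (voxel_noise_sd > 0) {
        block <- block + array(stats::rnorm(length(block), sd = voxel_noise_sd),
                               dim = dim(block))
      }
      volumes[xs, ys, zs, ] <- block
    }
  }
  list(volumes = volumes, labels = labels, truth = truth)
}

block_grid <- function(n_regions, extent) {
  best <- NULL
  for (nx in seq_len(extent[1])) for (ny in seq_len(extent[2])) {
    nz <- ceiling(n_regions / (nx * ny))
    if (nz <= extent[3]) {
      cand <- c(nx, ny, nz)
      if (is.null(best) || prod(cand) < prod(best)) best <- cand
    }
  }
  best
}

#' Write a cohort to TSV files plus a manifest
#'
#' One TSV per subject-visit (time points x regions, header = region labels)
#' and a `manifest.tsv` with columns subject, group, visit, file, tr.
#'
#' @param cohort list of subject-visit series from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param region_labels optional character vector of column labels; defaults
#'   to the AAL abbreviations when the cohort has 116 regions, else R001...
#' @return path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, region_labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  R <- nrow(cohort[[1]]$series)
  if (is.null(region_labels)) {
    region_labels <- if (R == 116L) load_region_table()$abbreviation
                     else sprintf("R%03d", seq_len(R))
  }
  rows <- lapply(cohort, function(sv) {
    fn <- sprintf("%s_visit%d.tsv", sv$subject_id, sv$visit)
    m <- t(sv$series)
    colnames(m) <- region_labels
    utils::write.table(format(m, digits = 10, trim = TRUE),
                       file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.frame(subject = sv$subject_id, group = sv$group, visit = sv$visit,
               file = fn, tr = sv$tr_seconds, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' Reads the manifest written by [write_cohort()] (or a user-provided one with
#' the same columns) and loads each subject-visit TSV. Files may also be 4D
#' NIfTI volumes when an atlas is supplied; see [run_pipeline()] real mode.
#'
#' @param manifest_path path to a manifest TSV with columns subject, group,
#'   visit, file, tr.
#' @return list of subject-visit series objects.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    argument_error(sprintf("manifest not found: %s", manifest_path))
  }
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "visit", "file", "tr")
  if (!all(need %in% names(manifest))) {
    config_error(sprintf("manifest must have columns %s",
                         paste(need, collapse = ", ")))
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(base, manifest$file[i])
    if (!file.exists(f)) argument_error(sprintf("series file not found: %s", f))
    m <- as.matrix(utils::read.delim(f, check.names = FALSE))
    structure(list(subject_id = manifest$subject[i], group = manifest$group[i],
                   visit = manifest$visit[i], series = t(m),
                   tr_seconds = manifest$tr[i]),
              class = "subject_visit_series")
  })
}
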