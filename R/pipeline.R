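#' Build a pipeline run configuration
#'
#' Merges user settings over the package defaults. Settings may come
#' from a YAML (or JSON) file and/or from `...`; later sources win.
#' The effective configuration is serialized into the output directory
#' by [run_pipeline()] for provenance.
#'
#' @param file optional YAML or JSON config file.
#' @param ... named settings overriding file and defaults; nested
#'   lists are merged key-wise (e.g. `sim = list(n_subjects = 4)`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  defaults <- list(
    run_id = "run-01",
    rng_seed = 1L,
    out_dir = NULL,
    write_artifacts = FALSE,
    sim = list(
      n_subjects = 18L, n_conditions = 4L, n_frames = 197L,
      tr_seconds = 2.46, grid_dims = c(20L, 24L, 20L),
      voxel_mm = c(3, 3, 3), k_true = 8L, event_rate = 0.15,
      amplitude = 4, seed_amplitude = 4, baseline = 1000,
      physio_sd = 2, noise_sd = 1, drift_sd = 1,
      spike_rate = c(0.05, 0.03, 0.08, 0.01), seed_edge_mm = 6,
      gains = NULL
    ),
    preprocess = list(detrend_order = 2L, bandpass = c(0.005, 0.1),
                      fwhm_mm = 8,
                      nuisance_include = c("global", "motion")),
    qc = list(head_radius_mm = 50, fd_thresh = 0.5, dvars_thresh = 0.5,
              rule = "and", apply_censoring = TRUE),
    seed = list(center_mm = c(0, 0, 0), edge_mm = 6,
                space_tag = "synthetic"),
    select = list(threshold_sd = 1, sign = "positive",
                  peaks_only = FALSE),
    cluster = list(k = 8L, n_restarts = 10L, centroids_file = NULL),
    stats = list(weights = c(1.5, -0.5, -1.5, 0.5), q = 0.05)
  )
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- defaults
  if (!is.null(file)) {
    parsed <- if (grepl("\\.json$", file)) {
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(file)
    }
    cfg <- merge_lists(cfg, parsed)
  }
  dots <- list(...)
  if (length(dots)) cfg <- merge_lists(cfg, dots)
  structure(cfg, class = "run_config")
}

#' Per-subject, per-condition, per-CAP mean maps
#'
#' Assigns every session's supra-threshold frames to the fixed
#' centroids and averages each subject's frames within each CAP,
#' giving the subject-level maps that enter second-level inference.
#' Empty subject x condition x CAP cells are absent from the table
#' (and later excluded pairwise).
#'
#' @param pp_tbl tibble with columns `subject_id`, `condition_label`,
#'   `pp` (list of [select_frames()] results).
#' @param centroids a [fit_centroids()] result.
#' @return Tibble with `subject_id`, `condition_label`, `cap`,
#'   `n_frames_contributing`, `map` (list of numeric voxel vectors).
#' @export
subject_cap_maps <- function(pp_tbl, centroids) {
  purrr::pmap_dfr(pp_tbl, function(subject_id, condition_label, pp, ...) {
    if (!length(pp$event_indices)) return(NULL)
    labels <- assign_to_centroids(pp$frames, centroids)
    purrr::map_dfr(sort(unique(labels)), function(j) {
      memb <- labels == j
      tibble::tibble(
        subject_id = subject_id, condition_label = condition_label,
        cap = j, n_frames_contributing = sum(memb),
        map = list(colMeans(pp$frames[memb, , drop = FALSE]))
      )
    })
  })
}

# subjects x voxels matrix for one condition and one CAP; subjects
# without the cell get an NA row (excluded downstream)
maps_matrix <- function(maps_tbl, condition, cap, subjects, n_voxels) {
  out <- matrix(NA_real_, nrow = length(subjects), ncol = n_voxels)
  sel <- maps_tbl$condition_label == condition & maps_tbl$cap == cap
  sub <- maps_tbl[sel, ]
  for (i in seq_len(nrow(sub))) {
    out[match(sub$subject_id[i], subjects), ] <- sub$map[[i]]
  }
  out
}

#' Run the full CAP pipeline
#'
#' Executes simulate, preprocess, QC, frame extraction, clustering and
#' cross-condition comparison, and returns (and optionally writes) a
#' run manifest. Reference centroids are fitted once on the pooled
#' frames of the whole run (all conditions) — playing the role of an
#' independent reference cohort — and then kept fixed while each
#' condition's frames are assigned, so CAP indices are comparable
#' across conditions. With an `out_dir`, the effective config and the
#' manifest are serialized; an existing manifest is returned as-is
#' unless `force = TRUE` (stage resumability).
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built cohort from [generate_cohort()];
#'   when `NULL`, one is simulated from `config$sim`.
#' @param force recompute even if the output manifest exists.
#' @return The manifest: a list of per-stage summary tables (plain
#'   data, JSON-serializable) plus `results`, a list carrying the
#'   in-memory objects (`centroids`, `cap_sets`, `contrasts`,
#'   `subject_maps`, `qc`, `point_processes`).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mf_path <- file.path(out_dir, "manifest.json")
    if (file.exists(mf_path) && !force) {
      message("existing manifest found; returning it (use force = TRUE to rerun)")
      return(jsonlite::read_json(mf_path, simplifyVector = TRUE))
    }
    cfg_plain <- unclass(config)
    jsonlite::write_json(cfg_plain, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }

  # --- stage: simulate -------------------------------------------------
  if (is.null(cohort)) {
    sim <- config$sim
    params <- sim_params(
      n_subjects = sim$n_subjects, n_conditions = sim$n_conditions,
      n_frames = sim$n_frames, tr_seconds = sim$tr_seconds,
      grid_dims = sim$grid_dims, voxel_mm = sim$voxel_mm,
      k_true = sim$k_true, event_rate = sim$event_rate,
      amplitude = sim$amplitude, seed_amplitude = sim$seed_amplitude,
      baseline = sim$baseline, physio_sd = sim$physio_sd,
      noise_sd = sim$noise_sd,
      drift_sd = sim$drift_sd, spike_rate = sim$spike_rate,
      seed_edge_mm = sim$seed_edge_mm, rng_seed = config$rng_seed
    )
    cohort <- generate_cohort(params, gains = sim$gains)
    if (!is.null(out_dir) && isTRUE(config$write_artifacts)) {
      export_cohort(cohort, file.path(out_dir, "cohort"))
    }
  }
  sessions <- cohort$sessions
  conditions <- unique(sessions$condition_label)
  subjects <- unique(sessions$subject_id)

  # --- stages: QC (on raw data), preprocess, extract -------------------
  seed <- seed_spec(config$seed$center_mm, config$seed$edge_mm,
                    config$seed$space_tag)
  qc_list <- vector("list", nrow(sessions))
  pp_list <- vector("list", nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    ses <- sessions$session[[i]]
    qc <- motion_qc(ses, sessions$motion_params[[i]],
                    head_radius_mm = config$qc$head_radius_mm,
                    fd_thresh = config$qc$fd_thresh,
                    dvars_thresh = config$qc$dvars_thresh,
                    rule = config$qc$rule)
    qc_list[[i]] <- qc
    nuis <- build_nuisance(ses, motion_params = sessions$motion_params[[i]],
                           include = config$preprocess$nuisance_include)
    pre <- preprocess_session(
      ses, detrend_order = config$preprocess$detrend_order,
      bandpass = config$preprocess$bandpass, nuisance = nuis,
      fwhm_mm = config$preprocess$fwhm_mm
    )
    sv <- resolve_seed(seed, pre)
    tc <- seed_timecourse(pre, sv)
    keep <- if (isTRUE(config$qc$apply_censoring)) qc$kept else NULL
    pp_list[[i]] <- suppressWarnings(select_frames(
      pre, tc, threshold_sd = config$select$threshold_sd,
      sign = config$select$sign, keep_mask = keep,
      peaks_only = isTRUE(config$select$peaks_only)
    ))
  }
  qc_tbl <- dplyr::bind_rows(qc_list)
  class(qc_tbl) <- c("motion_qc", class(tibble::tibble()))
  pp_tbl <- tibble::tibble(
    subject_id = sessions$subject_id,
    condition_label = sessions$condition_label, pp = pp_list
  )
  pp_glance <- purrr::map_dfr(pp_list, glance)

  # --- stage: cluster --------------------------------------------------
  pooled <- do.call(rbind, purrr::map(pp_list, "frames"))
  if (is.null(pooled) || nrow(pooled) < config$cluster$k) {
    stop("stage 'cluster' failed: fewer pooled frames than clusters",
         call. = FALSE)
  }
  centroids <- if (!is.null(config$cluster$centroids_file)) {
    readRDS(config$cluster$centroids_file)
  } else {
    fit_centroids(pooled, k = config$cluster$k,
                  n_restarts = config$cluster$n_restarts,
                  rng_seed = config$rng_seed + 1L,
                  provenance = paste0(config$run_id, "/pooled-reference"))
  }
  cap_sets <- purrr::map(conditions, function(cond) {
    fr <- do.call(rbind, purrr::map(
      pp_list[sessions$condition_label == cond], "frames"))
    labels <- assign_to_centroids(fr, centroids)
    suppressWarnings(compute_caps(fr, labels, centroids$k,
                                  condition_label = cond))
  })
  names(cap_sets) <- conditions

  # --- stage: compare --------------------------------------------------
  similarity <- purrr::map_dfr(
    conditions[-1],
    function(cond) match_and_compare(cap_sets[[conditions[1]]],
                                     cap_sets[[cond]])
  )
  maps_tbl <- subject_cap_maps(pp_tbl, centroids)
  n_vox <- ncol(centroids$centroids)
  contrasts <- NULL
  contrast_glance <- NULL
  if (length(conditions) == length(config$stats$weights)) {
    contrasts <- purrr::map(seq_len(centroids$k), function(j) {
      mats <- purrr::map(conditions, ~ maps_matrix(maps_tbl, .x, j,
                                                   subjects, n_vox))
      names(mats) <- conditions
      # a CAP visited by < 3 complete subjects cannot be tested
      tryCatch(
        suppressMessages(linear_consciousness_contrast(
          mats, weights = config$stats$weights, q = config$stats$q)),
        error = function(e) NULL
      )
    })
    contrast_glance <- purrr::map_dfr(seq_along(contrasts), function(j) {
      if (is.null(contrasts[[j]])) {
        return(tibble::tibble(cap = j, n_voxels = n_vox,
                              n_subjects = NA_integer_,
                              n_significant = NA_integer_,
                              rejection_rate = NA_real_,
                              peak_t = NA_real_,
                              q_threshold = config$stats$q))
      }
      g <- glance(contrasts[[j]])
      g$cap <- j
      g
    })
  }

  manifest <- list(
    run_id = config$run_id, rng_seed = config$rng_seed,
    n_sessions = nrow(sessions), conditions = conditions,
    qc_summary = as.data.frame(glance.motion_qc(qc_tbl)),
    selection = as.data.frame(pp_glance),
    selected_fraction_overall =
      sum(pp_glance$n_events) / sum(pp_glance$n_frames_total),
    censored_fraction_by_condition = vapply(
      conditions, function(cc) {
        g <- glance.motion_qc(qc_tbl)
        mean(g$censored_fraction[g$condition_label == cc])
      }, numeric(1)),
    occupancy = as.data.frame(purrr::map_dfr(cap_sets, tidy)),
    similarity_vs_first = as.data.frame(similarity),
    contrast_summary = if (!is.null(contrast_glance)) {
      as.data.frame(contrast_glance)
    },
    results = list(centroids = centroids, cap_sets = cap_sets,
                   contrasts = contrasts, subject_maps = maps_tbl,
                   qc = qc_tbl, point_processes = pp_tbl)
  )
  if (!is.null(out_dir)) {
    mf_json <- manifest[setdiff(names(manifest), "results")]
    jsonlite::write_json(mf_json, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  manifest
}

#' Human-readable run report
#'
#' @param manifest a [run_pipeline()] manifest.
#' @return A list of class `cap_report` with tibbles `occupancy`
#'   (condition x CAP), `similarity` (vs the first condition),
#'   `contrast_peaks`, and `qc`; empty CAPs are flagged in
#'   `occupancy$empty`. Printed as aligned tables.
#' @export
cap_report <- function(manifest) {
  occ <- tibble::as_tibble(manifest$occupancy)
  occ$empty <- occ$occupancy == 0
  rep <- list(
    run_id = manifest$run_id,
    occupancy = occ,
    similarity = tibble::as_tibble(manifest$similarity_vs_first),
    contrast_peaks = if (!is.null(manifest$contrast_summary)) {
      tibble::as_tibble(manifest$contrast_summary)
    } else tibble::tibble(),
    qc = tibble::as_tibble(manifest$qc_summary)
  )
  structure(rep, class = "cap_report")
}

#' @export
print.cap_report <- function(x, ...) {
  cat("CAP pipeline report —", x$run_id, "\n\n")
  cat("Occupancy per CAP per condition:\n")
  print(x$occupancy, n = nrow(x$occupancy))
  if (any(x$occupancy$empty)) {
    cat("NOTE: empty CAP(s) flagged above.\n")
  }
  cat("\nSimilarity vs first condition:\n")
  print(x$similarity, n = nrow(x$similarity))
  if (nrow(x$contrast_peaks)) {
    cat("\nLinear contrast summary per CAP:\n")
    print(x$contrast_peaks, n = nrow(x$contrast_peaks))
  }
  cat("\nMotion QC summary:\n")
  print(x$qc, n = min(nrow(x$qc), 20))
  invisible(x)
}
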