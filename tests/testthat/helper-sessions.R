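# Fixtures built in code: small sessions and cohorts shared across tests.

# a bold_session whose in-mask voxel matrix equals `mat` (frames x voxels),
# on a 1-D strip grid with a full mask
session_from_matrix <- function(mat, tr_seconds = 2.46, voxel_mm = c(3, 3, 3),
                                standardized = FALSE) {
  nv <- ncol(mat)
  nt <- nrow(mat)
  data <- array(0, dim = c(nv, 1, 1, nt))
  data[, 1, 1, ] <- t(mat)
  ses <- bold_session(data, array(TRUE, dim = c(nv, 1, 1)), tr_seconds,
                      voxel_mm = voxel_mm)
  ses$standardized <- standardized
  ses
}

# small cubic session filled with N(0, 1) noise
noise_session <- function(n = 8L, nt = 60L, sd = 1, baseline = 0,
                          tr_seconds = 2.46, seed = 1L) {
  withr::with_seed(seed, {
    bold_session(
      array(stats::rnorm(n^3 * nt, mean = baseline, sd = sd),
            dim = c(n, n, n, nt)),
      array(TRUE, dim = c(n, n, n)), tr_seconds
    )
  })
}

# tiny cohort used by several suites (cheap: ~1 s)
tiny_cohort <- function(rng_seed = 5L, ...) {
  generate_cohort(sim_params(
    n_subjects = 2L, n_conditions = 2L, n_frames = 60L,
    grid_dims = c(12L, 12L, 12L), k_true = 3L, rng_seed = rng_seed, ...
  ))
}

# preprocess + extract one session of a cohort with the standard chain
extract_pp <- function(cohort, i, fwhm_mm = 6, censor = TRUE,
                       include = c("global", "motion"), ...) {
  ses <- cohort$sessions$session[[i]]
  mp <- cohort$sessions$motion_params[[i]]
  keep <- if (censor) motion_qc(ses, mp)$kept else NULL
  nuis <- build_nuisance(ses, mp, include = include)
  pre <- suppressWarnings(preprocess_session(ses, nuisance = nuis,
                                             fwhm_mm = fwhm_mm))
  sv <- resolve_seed(seed_spec(), pre)
  suppressWarnings(select_frames(pre, seed_timecourse(pre, sv),
                                 keep_mask = keep, ...))
}
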