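nifti_affine <- function(voxel_mm, origin_mm) {
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- origin_mm
  structure(aff, code = 2L)
}

write_session_nifti <- function(session, path) {
  img <- RNifti::asNifti(
    session$data,
    pixdim = c(session$voxel_mm, session$tr_seconds)
  )
  img <- RNifti::`sform<-`(img, nifti_affine(session$voxel_mm, session$origin_mm))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a synthetic cohort to NIfTI, TSV and a JSON manifest
#'
#' Writes one `.nii.gz` per session, one 6-column motion TSV per
#' session (translations in mm, rotations in rad), the brain mask, the
#' ground-truth pattern maps as a 4D NIfTI stack, and a JSON manifest
#' that records geometry, seed voxels, condition gains, event times and
#' motion-spike frames, so the cohort round-trips losslessly up to
#' float storage precision.
#'
#' @param cohort the result of [generate_cohort()].
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly, as a list.
#' @export
export_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  truth <- cohort$truth
  sessions <- cohort$sessions

  entries <- purrr::pmap(sessions, function(subject_id, condition_label,
                                            session, motion_params) {
    stem <- paste0(subject_id, "_", condition_label)
    bold <- file.path(out_dir, paste0(stem, "_bold.nii.gz"))
    mot <- file.path(out_dir, paste0(stem, "_motion.tsv"))
    write_session_nifti(session, bold)
    utils::write.table(as.data.frame(motion_params), mot, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(subject_id = subject_id, condition_label = condition_label,
         bold = basename(bold), motion = basename(mot))
  })

  # mask + pattern stack share the session grid
  mask_img <- RNifti::asNifti(array(as.numeric(truth$mask),
                                    dim = truth$grid_dims),
                              pixdim = truth$voxel_mm)
  mask_img <- RNifti::`sform<-`(mask_img,
                                nifti_affine(truth$voxel_mm, truth$origin_mm))
  RNifti::writeNifti(mask_img, file.path(out_dir, "mask.nii.gz"))

  k <- nrow(truth$patterns)
  pat4 <- array(0, dim = c(truth$grid_dims, k))
  flat <- matrix(0, nrow = prod(truth$grid_dims), ncol = k)
  flat[as.vector(truth$mask), ] <- t(truth$patterns)
  pat4 <- array(flat, dim = c(truth$grid_dims, k))
  pat_img <- RNifti::asNifti(pat4, pixdim = c(truth$voxel_mm, 1))
  pat_img <- RNifti::`sform<-`(pat_img,
                               nifti_affine(truth$voxel_mm, truth$origin_mm))
  RNifti::writeNifti(pat_img, file.path(out_dir, "truth_patterns.nii.gz"))

  manifest <- list(
    format = "boldcaps-cohort", version = 1L,
    grid_dims = truth$grid_dims, voxel_mm = truth$voxel_mm,
    origin_mm = truth$origin_mm,
    tr_seconds = truth$params$tr_seconds,
    n_subjects = truth$params$n_subjects,
    n_conditions = truth$params$n_conditions,
    condition_labels = truth$condition_labels,
    mask_file = "mask.nii.gz", patterns_file = "truth_patterns.nii.gz",
    seed_voxels = truth$seed_voxels,
    seed_edge_mm = truth$params$seed_edge_mm,
    condition_gains = truth$condition_gains,
    noise_sd = truth$noise_sd,
    hrf_peak_lag_frames = truth$peak_lag_frames,
    sessions = entries,
    event_times = purrr::map(truth$event_times, ~ as.list(.x)),
    motion_spike_frames = truth$motion_spike_frames
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Re-import a cohort exported with [export_cohort()]
#'
#' @param dir directory containing `manifest.json` and the files it
#'   names.
#' @return A list with `sessions` (tibble as from [generate_cohort()])
#'   and `manifest` (the parsed JSON manifest; pattern maps are
#'   re-read into `manifest$patterns` as a k x voxels in-mask matrix).
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  gd <- as.integer(mf$grid_dims)
  mask <- array(as.vector(RNifti::readNifti(file.path(dir, mf$mask_file))) > 0.5,
                dim = gd)
  rows <- purrr::pmap(mf$sessions, function(subject_id, condition_label,
                                            bold, motion) {
    img <- RNifti::readNifti(file.path(dir, bold))
    ses <- bold_session(
      array(as.vector(img), dim = dim(img)), mask, mf$tr_seconds,
      subject_id = subject_id, condition_label = condition_label,
      voxel_mm = mf$voxel_mm, origin_mm = mf$origin_mm
    )
    mp <- as.matrix(utils::read.delim(file.path(dir, motion)))
    tibble::tibble(subject_id = subject_id,
                   condition_label = condition_label,
                   session = list(ses), motion_params = list(mp))
  })
  pat4 <- RNifti::readNifti(file.path(dir, mf$patterns_file))
  k <- dim(pat4)[4]
  flat <- matrix(as.vector(pat4), nrow = prod(gd), ncol = k)
  mf$patterns <- t(flat[as.vector(mask), , drop = FALSE])
  mf$mask <- mask
  list(sessions = dplyr::bind_rows(rows), manifest = mf)
}
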