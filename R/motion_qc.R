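#' Framewise displacement
#'
#' FD at frame `i` is the sum of the absolute frame-to-frame changes of
#' the three translations (mm) plus the three rotations converted to
#' arc length on a sphere of radius `head_radius_mm` (the conventional
#' 50 mm). `fd[1] = 0` since the first frame has no predecessor.
#'
#' @param params frames x 6 matrix: translations mm, rotations rad.
#' @param head_radius_mm sphere radius for the rotation arc length.
#' @return Numeric vector of FD in mm (non-negative).
#' @export
compute_fd <- function(params, head_radius_mm = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) {
    stop("`params` must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  }
  if (nrow(params) < 2L) stop("need at least 2 frames", call. = FALSE)
  d <- abs(diff(params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rowSums(d[, 4:6, drop = FALSE]) * head_radius_mm
  c(0, fd)
}

#' DVARS
#'
#' Root mean square over in-mask voxels of the frame-to-frame intensity
#' difference, expressed as a percentage of the session's in-mask
#' grand-mean intensity. Must be computed on data before voxelwise
#' standardization — "% BOLD" has no meaning after per-voxel z-scoring.
#' `dvars[1] = 0` by convention.
#'
#' @param session a [bold_session()] with unnormalized intensities.
#' @return Numeric vector of DVARS in % BOLD (non-negative).
#' @export
compute_dvars <- function(session) {
  vm <- voxel_matrix(session)
  if (nrow(vm) < 2L) stop("need at least 2 frames", call. = FALSE)
  gm <- mean(vm)
  if (gm <= 0) {
    stop("in-mask grand mean must be positive to express DVARS in % BOLD",
         call. = FALSE)
  }
  rms <- sqrt(rowMeans(diff(vm)^2))
  c(0, 100 * rms / gm)
}

#' Censor motion-corrupted frames
#'
#' With `rule = "and"` (the default), a frame is censored only when FD
#' and DVARS are *both* above their thresholds. `rule = "or"` censors
#' when either exceeds its threshold, the stricter convention of the
#' scrubbing literature; both are offered because the two conventions
#' coexist.
#'
#' @param fd,dvars equal-length series from [compute_fd()] /
#'   [compute_dvars()].
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @param dvars_thresh DVARS threshold in % BOLD (default 0.5).
#' @param rule `"and"` or `"or"`.
#' @return Logical keep mask (`TRUE` = keep the frame).
#' @export
censor_frames <- function(fd, dvars, fd_thresh = 0.5, dvars_thresh = 0.5,
                          rule = c("and", "or")) {
  rule <- match.arg(rule)
  if (length(fd) != length(dvars)) {
    stop("fd and dvars must have the same length", call. = FALSE)
  }
  bad <- if (rule == "and") {
    fd > fd_thresh & dvars > dvars_thresh
  } else {
    fd > fd_thresh | dvars > dvars_thresh
  }
  !bad
}

#' Motion quality-control report for one session
#'
#' Computes FD from the motion parameters and DVARS from the (raw,
#' unstandardized) session, applies the censoring rule, and returns a
#' per-frame tidy report.
#'
#' @inheritParams compute_fd
#' @inheritParams censor_frames
#' @param session a [bold_session()] with unnormalized intensities.
#' @return A tibble of class `motion_qc` with columns `subject_id`,
#'   `condition_label`, `frame`, `fd`, `dvars`, `kept`.
#' @export
motion_qc <- function(session, params, head_radius_mm = 50,
                      fd_thresh = 0.5, dvars_thresh = 0.5,
                      rule = c("and", "or")) {
  fd <- compute_fd(params, head_radius_mm)
  dvars <- compute_dvars(session)
  keep <- censor_frames(fd, dvars, fd_thresh, dvars_thresh, match.arg(rule))
  out <- tibble::tibble(
    subject_id = session$subject_id,
    condition_label = session$condition_label,
    frame = seq_along(fd), fd = fd, dvars = dvars, kept = keep
  )
  class(out) <- c("motion_qc", class(out))
  out
}

#' Summarize a motion QC report
#'
#' @param x a `motion_qc` tibble (possibly several sessions bound
#'   together).
#' @param ... unused.
#' @return One row per subject x condition with the censored fraction.
#' @export
glance.motion_qc <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$subject_id,
                    .data$condition_label),
    n_frames = dplyr::n(),
    n_censored = sum(!.data$kept),
    censored_fraction = mean(!.data$kept),
    max_fd = max(.data$fd), max_dvars = max(.data$dvars),
    .groups = "drop"
  )
}
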