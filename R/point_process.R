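#' Seed region specification
#'
#' A cubic seed of edge `edge_mm` centered at a mm coordinate. The
#' canonical posterior-cingulate seed in MNI space is a 6 mm cube at
#' (0, -53, 26); note the negative y — PCC is posterior, and published
#' coordinates occasionally drop the sign. For synthetic grids, the
#' default center (0, 0, 0) with `space_tag = "synthetic"` addresses
#' the planted seed cube at the grid center.
#'
#' @param center_mm 3 mm coordinates of the cube center.
#' @param edge_mm cube edge in mm; 0 selects the single voxel
#'   containing the center.
#' @param space_tag `"synthetic"` or `"MNI"`, matched against the
#'   session's `space_tag`.
#' @return A list of class `seed_spec`.
#' @export
seed_spec <- function(center_mm = c(0, 0, 0), edge_mm = 6,
                      space_tag = "synthetic") {
  stopifnot(length(center_mm) == 3L, edge_mm >= 0)
  structure(list(center_mm = as.numeric(center_mm), edge_mm = edge_mm,
                 space_tag = space_tag),
            class = "seed_spec")
}

#' Resolve a seed specification to in-mask voxel indices
#'
#' Selects every in-mask voxel whose center lies within the closed cube
#' of edge `edge_mm` around `center_mm`. With 3 mm voxels and a 6 mm
#' edge this yields at most 8 voxels (2 x 2 x 2 when the cube is
#' corner-aligned). `edge_mm = 0` degenerates to the single nearest
#' voxel containing the center.
#'
#' @param seed a [seed_spec()].
#' @param session a [bold_session()] supplying grid geometry and mask.
#' @return Integer indices into the in-mask voxel columns (the columns
#'   of [voxel_matrix()]).
#' @export
resolve_seed <- function(seed, session) {
  stopifnot(inherits(seed, "seed_spec"))
  if (!identical(seed$space_tag, session$space_tag)) {
    stop(sprintf("seed space '%s' does not match session space '%s'",
                 seed$space_tag, session$space_tag), call. = FALSE)
  }
  mm <- inmask_coords_mm(session)
  if (seed$edge_mm == 0) {
    # the voxel whose cell contains the center
    d <- sweep(mm, 2, seed$center_mm, `-`)
    inside <- abs(d[, 1]) <= session$voxel_mm[1] / 2 &
      abs(d[, 2]) <= session$voxel_mm[2] / 2 &
      abs(d[, 3]) <= session$voxel_mm[3] / 2
    idx <- which(inside)
    if (length(idx) > 1L) idx <- idx[which.min(rowSums(d[idx, , drop = FALSE]^2))]
  } else {
    half <- seed$edge_mm / 2
    idx <- which(
      abs(mm[, 1] - seed$center_mm[1]) <= half &
        abs(mm[, 2] - seed$center_mm[2]) <= half &
        abs(mm[, 3] - seed$center_mm[3]) <= half
    )
  }
  if (!length(idx)) {
    stop("seed cube contains no in-mask voxel centers (seed-placement error)",
         call. = FALSE)
  }
  idx
}

#' Mean seed time course, re-standardized
#'
#' Averages the (already standardized) series of the seed voxels and
#' re-standardizes the average to mean 0 / SD 1, so the selection
#' threshold is always in SD units of the seed trace itself.
#'
#' @param session a standardized [bold_session()].
#' @param seed_voxels in-mask column indices from [resolve_seed()].
#' @return Numeric vector of length `n_frames`.
#' @export
seed_timecourse <- function(session, seed_voxels) {
  if (!isTRUE(session$standardized)) {
    warning("session is not flagged as standardized; ",
            "the threshold may not be in SD units", call. = FALSE)
  }
  vm <- voxel_matrix(session)
  s <- rowMeans(vm[, seed_voxels, drop = FALSE])
  sdv <- stats::sd(s)
  if (sdv == 0) return(s * 0)
  (s - mean(s)) / sdv
}

#' Reduce a session to a spatio-temporal point process
#'
#' Keeps the frames at which the seed trace exceeds the threshold
#' (strictly above `threshold_sd` for `sign = "positive"`, strictly
#' below `-threshold_sd` for `sign = "negative"`). Frames flagged by
#' motion censoring are excluded. For a standardized Gaussian seed
#' trace and threshold 1 SD this keeps roughly 15.9% of frames
#' (`1 - pnorm(1)`). All consecutive supra-threshold frames are kept;
#' set `peaks_only = TRUE` to retain only local maxima of the seed
#' trace within supra-threshold runs.
#'
#' @param session a standardized [bold_session()].
#' @param seed_series seed trace from [seed_timecourse()].
#' @param threshold_sd threshold in SD units (> 0; default 1).
#' @param sign `"positive"` or `"negative"` threshold crossing.
#' @param keep_mask optional logical vector from [censor_frames()];
#'   `NULL` keeps all frames.
#' @param peaks_only keep only local seed-trace maxima among selected
#'   frames.
#' @return An object of class `point_process`: `event_indices`
#'   (1-based, strictly increasing), `seed_values`, `frames` (events x
#'   in-mask voxels matrix of standardized maps), `threshold_sd`,
#'   `sign`, `n_frames_total`, `n_frames_kept`, and the session
#'   identifiers.
#' @export
select_frames <- function(session, seed_series, threshold_sd = 1,
                          sign = c("positive", "negative"),
                          keep_mask = NULL, peaks_only = FALSE) {
  sign <- match.arg(sign)
  if (threshold_sd <= 0) stop("threshold_sd must be > 0", call. = FALSE)
  nt <- length(seed_series)
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, nt)
  if (length(keep_mask) != nt) {
    stop("keep_mask length must match the series", call. = FALSE)
  }
  sel <- if (sign == "positive") {
    seed_series > threshold_sd
  } else {
    seed_series < -threshold_sd
  }
  sel <- sel & keep_mask
  if (peaks_only && any(sel)) {
    is_peak <- vapply(seq_len(nt), function(i) {
      lo <- if (i > 1) seed_series[i - 1] else -Inf
      hi <- if (i < nt) seed_series[i + 1] else -Inf
      if (sign == "positive") {
        seed_series[i] >= lo && seed_series[i] >= hi
      } else {
        seed_series[i] <= lo && seed_series[i] <= hi
      }
    }, logical(1))
    sel <- sel & is_peak
  }
  idx <- which(sel)
  if (!length(idx)) {
    warning("no supra-threshold frames selected (empty point process)",
            call. = FALSE)
  }
  vm <- voxel_matrix(session)
  structure(
    list(
      event_indices = idx, seed_values = seed_series[idx],
      frames = vm[idx, , drop = FALSE],
      threshold_sd = threshold_sd, sign = sign,
      n_frames_total = nt, n_frames_kept = sum(keep_mask),
      subject_id = session$subject_id,
      condition_label = session$condition_label
    ),
    class = "point_process"
  )
}

#' @export
print.point_process <- function(x, ...) {
  cat(sprintf(
    "<point_process> %s / %s: %d events of %d frames (%.1f%%), %s threshold %.3g SD\n",
    x$subject_id, x$condition_label, length(x$event_indices),
    x$n_frames_total, 100 * length(x$event_indices) / x$n_frames_total,
    x$sign, x$threshold_sd
  ))
  invisible(x)
}

#' Tidy a point process into its event table
#'
#' @param x a `point_process`.
#' @param ... unused.
#' @return Tibble with `subject_id`, `condition_label`, `frame`,
#'   `seed_value`.
#' @export
tidy.point_process <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, condition_label = x$condition_label,
    frame = x$event_indices, seed_value = x$seed_values
  )
}

#' One-row summary of a point process
#'
#' @param x a `point_process`.
#' @param ... unused.
#' @return Tibble with event counts and the selected fraction, both
#'   relative to all frames and to censoring-surviving frames.
#' @export
glance.point_process <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, condition_label = x$condition_label,
    n_events = length(x$event_indices),
    n_frames_total = x$n_frames_total, n_frames_kept = x$n_frames_kept,
    selected_fraction = length(x$event_indices) / x$n_frames_total,
    selected_fraction_kept = length(x$event_indices) /
      max(1L, x$n_frames_kept)
  )
}
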