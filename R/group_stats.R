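# vectorized voxelwise one-sample t against 0, one-sided (greater).
# Zero-variance voxels use a documented sentinel: t = +Inf / p = 0 for a
# positive mean, t = -Inf / p = 1 for a negative mean, t = 0 / p = 0.5
# for an all-zero voxel. Never NaN.
one_sample_t <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  m <- colMeans(X)
  s <- sqrt(colSums(sweep(X, 2, m, `-`)^2) / (n - 1))
  tval <- numeric(length(m))
  pval <- numeric(length(m))
  nz <- s > 0
  tval[nz] <- m[nz] / (s[nz] / sqrt(n))
  pval[nz] <- stats::pt(tval[nz], df = n - 1, lower.tail = FALSE)
  degen <- !nz
  tval[degen] <- sign(m[degen]) * Inf
  tval[degen & m == 0] <- 0
  pval[degen] <- ifelse(m[degen] > 0, 0, ifelse(m[degen] < 0, 1, 0.5))
  list(t = tval, p = pval, n = n)
}

new_contrast_result <- function(tt, weights, q, sig) {
  structure(
    list(weights = weights, t_map = tt$t, p_map = tt$p,
         q_threshold = q, sig_mask = sig, n_subjects = tt$n),
    class = "contrast_result"
  )
}

#' Per-condition CAP significance
#'
#' Voxelwise one-sample t test across subjects of one condition's
#' subject-level CAP maps against 0, one-sided for co-activation
#' (mean > 0), followed by Benjamini-Hochberg FDR control at level
#' `q`.
#'
#' @param maps subjects x voxels matrix (one condition, one CAP; each
#'   row a subject's mean map over its frames in that CAP).
#' @param q FDR level (default 0.05).
#' @return A `contrast_result` with `t_map`, one-sided `p_map`,
#'   `sig_mask` and `q_threshold` (`weights` is `NULL` for this
#'   single-condition test).
#' @export
condition_significance <- function(maps, q = 0.05) {
  tt <- one_sample_t(maps)
  new_contrast_result(tt, NULL, q, fdr_bh(tt$p, q))
}

#' Linear consciousness contrast across conditions
#'
#' For each subject, forms the within-subject linear combination
#' `sum_c w_c map_c` of its per-condition CAP maps, then tests the
#' subject contrasts against 0 with a voxelwise one-sided one-sample t
#' and BH-FDR. Because the contrast is formed within subject before a
#' single one-sample test, no sphericity assumption on the condition
#' covariance is needed. The default weights (1.5, -0.5, -1.5, 0.5)
#' for wakefulness / sedation / unconsciousness / recovery encode a
#' linear decrease with sedation depth, with recovery down-weighted
#' relative to wakefulness (residual anesthetic at recovery). Subjects
#' missing any condition map are excluded with a message.
#'
#' @param maps_by_condition named list (condition order = weight
#'   order) of subjects x voxels matrices with identical row order
#'   (subjects); use `NA` rows for missing cells.
#' @param weights per-condition contrast coefficients; must sum to 0.
#' @param q FDR level (default 0.05).
#' @return A `contrast_result` with the weights used.
#' @export
linear_consciousness_contrast <- function(maps_by_condition,
                                          weights = c(1.5, -0.5, -1.5, 0.5),
                                          q = 0.05) {
  if (length(maps_by_condition) != length(weights)) {
    stop("one weight per condition required", call. = FALSE)
  }
  if (abs(sum(weights)) > 1e-12) {
    stop("contrast weights must sum to 0", call. = FALSE)
  }
  mats <- lapply(maps_by_condition, as.matrix)
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("condition matrices must share the subject dimension", call. = FALSE)
  }
  complete <- Reduce(`&`, lapply(mats, function(m) !apply(is.na(m), 1, any)))
  if (!all(complete)) {
    message("excluding ", sum(!complete),
            " subject(s) with missing condition cells")
    mats <- lapply(mats, function(m) m[complete, , drop = FALSE])
  }
  # since the weights sum to 0, the contrast is invariant to a common
  # offset; computing it on differences from the first condition makes
  # a condition-constant dataset give an exact (not just float-level) 0
  contrast <- Reduce(`+`, Map(function(m, w) w * (m - mats[[1]]),
                              mats[-1], weights[-1]))
  tt <- one_sample_t(contrast)
  new_contrast_result(tt, weights, q, fdr_bh(tt$p, q))
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `q`: rejects all hypotheses with
#' `p <= p_(k*)` where `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q FDR level.
#' @return Logical rejection mask, same length as `p_values`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH") <= q
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> %s over %d voxels, %d subjects: %d significant at FDR q = %g\n",
    if (is.null(x$weights)) "one-sample co-activation test"
    else paste0("contrast [", paste(x$weights, collapse = ", "), "]"),
    length(x$t_map), x$n_subjects, sum(x$sig_mask), x$q_threshold
  ))
  invisible(x)
}

#' Tidy a contrast result into a per-voxel table
#'
#' @param x a `contrast_result`.
#' @param ... unused.
#' @return Tibble with `voxel`, `t`, `p`, `significant`.
#' @export
tidy.contrast_result <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$t_map), t = x$t_map, p = x$p_map,
                 significant = x$sig_mask)
}

#' One-row summary of a contrast result
#'
#' @param x a `contrast_result`.
#' @param ... unused.
#' @return Tibble with voxel counts, rejections and the peak t.
#' @export
glance.contrast_result <- function(x, ...) {
  tibble::tibble(
    n_voxels = length(x$t_map), n_subjects = x$n_subjects,
    n_significant = sum(x$sig_mask),
    rejection_rate = mean(x$sig_mask),
    peak_t = max(x$t_map), q_threshold = x$q_threshold
  )
}

#' Seed-voxel correlation map
#'
#' Pearson correlation of every in-mask voxel's time series with the
#' mean seed series — the classic static seed-based connectivity map
#' that CAP analysis decomposes into transient patterns.
#'
#' @param session a standardized [bold_session()].
#' @param seed_voxels in-mask column indices from [resolve_seed()].
#' @return Numeric vector, one correlation per in-mask voxel
#'   (zero-variance voxels give `NA`).
#' @export
seed_correlation_map <- function(session, seed_voxels) {
  vm <- voxel_matrix(session)
  s <- rowMeans(vm[, seed_voxels, drop = FALSE])
  suppressWarnings(as.vector(stats::cor(s, vm)))
}

#' Sliding-window seed-correlation maps
#'
#' The standard dynamic-connectivity baseline: seed correlation maps
#' in consecutive windows of `window_frames` frames advanced by
#' `step`, suitable for clustering with the same k-means machinery as
#' the point-process frames. A window spanning the full series
#' degenerates to [seed_correlation_map()].
#'
#' @param session a standardized [bold_session()].
#' @param seed_voxels in-mask column indices.
#' @param window_frames window length in frames (>= 3).
#' @param step window advance in frames (>= 1).
#' @return A list with `maps` (windows x voxels matrix) and `windows`
#'   (tibble of `window`, `start`, `end`).
#' @export
sliding_window_maps <- function(session, seed_voxels, window_frames,
                                step = 1L) {
  nt <- n_frames(session)
  if (window_frames < 3L) stop("window_frames must be >= 3", call. = FALSE)
  if (window_frames > nt) {
    stop("window longer than the series", call. = FALSE)
  }
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  starts <- seq(1L, nt - window_frames + 1L, by = step)
  vm <- voxel_matrix(session)
  s <- rowMeans(vm[, seed_voxels, drop = FALSE])
  maps <- t(vapply(starts, function(st) {
    rng <- st:(st + window_frames - 1L)
    suppressWarnings(as.vector(stats::cor(s[rng], vm[rng, , drop = FALSE])))
  }, numeric(ncol(vm))))
  list(
    maps = maps,
    windows = tibble::tibble(window = seq_along(starts), start = starts,
                             end = starts + window_frames - 1L)
  )
}
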