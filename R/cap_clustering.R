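# Center and unit-normalize each row, so Euclidean distance between
# rows orders identically to 1 - Pearson correlation. Zero-variance
# rows are left as zero vectors.
normalize_frames <- function(frames) {
  frames <- as.matrix(frames)
  ctr <- frames - rowMeans(frames)
  nrm <- sqrt(rowSums(ctr^2))
  nz <- nrm > 0
  ctr[nz, ] <- ctr[nz, , drop = FALSE] / nrm[nz]
  ctr
}

# squared Euclidean distances between rows of a and rows of b
row_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
}

# kmeans++ seeding on normalized rows
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- row_dist2(x, x[centers[1], , drop = FALSE])[, 1]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- pmax(d2, 0)
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, row_dist2(x, x[centers[j], , drop = FALSE])[, 1])
    }
  }
  x[centers, , drop = FALSE]
}

# one Lloyd run; returns labels, centroids, per-iteration objective
lloyd <- function(x, centers, max_iter = 100L) {
  obj_trace <- numeric(0)
  labels <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- row_dist2(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(nrow(x)), new_labels)])
    obj_trace <- c(obj_trace, obj)
    if (it > 1 && identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(nrow(centers))) {
      memb <- labels == j
      if (any(memb)) {
        centers[j, ] <- colMeans(x[memb, , drop = FALSE])
      }
    }
  }
  d2 <- row_dist2(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  obj <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(labels = labels, centers = centers,
       objective = obj, objective_trace = c(obj_trace, obj))
}

#' Fit CAP cluster centroids by k-means
#'
#' Clusters supra-threshold frames by spatial similarity: each frame is
#' centered and unit-normalized (so Euclidean k-means orders like
#' 1 - Pearson correlation), seeded with kmeans++, run with Lloyd
#' iterations, and the best of `n_restarts` runs by within-cluster sum
#' of squares is kept. The fit is deterministic given `rng_seed`, so a
#' centroid set fitted once on a reference cohort can serve as a fixed
#' benchmark against which other conditions are assigned.
#'
#' @param frames events x voxels matrix (e.g. `rbind` of
#'   `point_process$frames` across sessions).
#' @param k number of clusters (default 8).
#' @param n_restarts independent kmeans++ restarts (default 10).
#' @param rng_seed integer seed recorded in the provenance.
#' @param max_iter Lloyd iteration cap per restart.
#' @param provenance free-text id of the dataset the fit used.
#' @return An object of class `centroid_set`: `centroids` (k x voxels,
#'   in normalized frame space), `k`, `metric` ("correlation"),
#'   `objective`, `objective_trace` (best restart), `labels` (training
#'   frame assignment), `provenance` (list with `dataset`, `rng_seed`,
#'   `n_frames`, `n_restarts`).
#' @export
fit_centroids <- function(frames, k = 8L, n_restarts = 10L, rng_seed = 1L,
                          max_iter = 100L, provenance = "unnamed") {
  frames <- as.matrix(frames)
  if (nrow(frames) < k) {
    stop(sprintf("cannot fit %d clusters from %d frames", k, nrow(frames)),
         call. = FALSE)
  }
  x <- normalize_frames(frames)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(rng_seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd(x, kmeanspp_init(x, k), max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(
    list(
      centroids = best$centers, k = as.integer(k), metric = "correlation",
      objective = best$objective, objective_trace = best$objective_trace,
      labels = best$labels,
      provenance = list(dataset = provenance, rng_seed = as.integer(rng_seed),
                        n_frames = nrow(frames),
                        n_restarts = as.integer(n_restarts))
    ),
    class = "centroid_set"
  )
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf(
    "<centroid_set> k = %d on %d voxels (%s metric), objective %.4g, fit on '%s' (seed %d)\n",
    x$k, ncol(x$centroids), x$metric, x$objective,
    x$provenance$dataset, x$provenance$rng_seed
  ))
  invisible(x)
}

#' Assign frames to fixed centroids
#'
#' Labels each frame with its nearest centroid under the centroid
#' set's metric, without updating the centroids — the step that makes
#' cluster indices comparable across conditions. Exact distance ties
#' are broken toward the lowest centroid index.
#'
#' @param frames events x voxels matrix.
#' @param centroids a [fit_centroids()] result.
#' @return Integer label vector in `1..k`.
#' @export
assign_to_centroids <- function(frames, centroids) {
  stopifnot(inherits(centroids, "centroid_set"))
  frames <- as.matrix(frames)
  if (ncol(frames) != ncol(centroids$centroids)) {
    stop(sprintf("frames have %d voxels but centroids have %d",
                 ncol(frames), ncol(centroids$centroids)), call. = FALSE)
  }
  x <- normalize_frames(frames)
  d2 <- row_dist2(x, centroids$centroids)
  max.col(-d2, ties.method = "first")
}

#' Average frames within clusters into co-activation patterns
#'
#' CAP `j` is the arithmetic mean of the original (standardized,
#' per-frame-unnormalized) frames labelled `j`, so CAP amplitude keeps
#' its BOLD-SD meaning. An empty cluster yields an all-zero CAP with
#' occupancy 0 and a warning. By construction the occupancy-weighted
#' mean of the CAPs equals the grand mean of all clustered frames.
#'
#' @param frames events x voxels matrix.
#' @param labels integer labels in `1..k`.
#' @param k number of clusters.
#' @param condition_label identifier stored with the result.
#' @return An object of class `cap_set`: `caps` (k x voxels),
#'   `occupancy` (k counts), `member_index` (per-frame label),
#'   `condition_label`, `n_frames`.
#' @export
compute_caps <- function(frames, labels, k, condition_label = "none") {
  frames <- as.matrix(frames)
  if (length(labels) != nrow(frames)) {
    stop("one label per frame required", call. = FALSE)
  }
  if (any(labels < 1L | labels > k)) {
    stop("labels must lie in 1..k", call. = FALSE)
  }
  caps <- matrix(0, nrow = k, ncol = ncol(frames))
  occupancy <- integer(k)
  for (j in seq_len(k)) {
    memb <- labels == j
    occupancy[j] <- sum(memb)
    if (occupancy[j] > 0) {
      caps[j, ] <- colMeans(frames[memb, , drop = FALSE])
    }
  }
  if (any(occupancy == 0)) {
    warning("empty cluster(s): ",
            paste(which(occupancy == 0), collapse = ", "), call. = FALSE)
  }
  structure(
    list(caps = caps, occupancy = occupancy, member_index = labels,
         condition_label = condition_label, n_frames = nrow(frames)),
    class = "cap_set"
  )
}

#' @export
print.cap_set <- function(x, ...) {
  cat(sprintf("<cap_set> %s: %d CAPs over %d frames; occupancy %s\n",
              x$condition_label, length(x$occupancy), x$n_frames,
              paste(x$occupancy, collapse = "/")))
  invisible(x)
}

#' Tidy a CAP set into its occupancy table
#'
#' @param x a `cap_set`.
#' @param ... unused.
#' @return Tibble with `condition_label`, `cap`, `occupancy`,
#'   `occupancy_fraction`.
#' @export
tidy.cap_set <- function(x, ...) {
  tibble::tibble(
    condition_label = x$condition_label,
    cap = seq_along(x$occupancy),
    occupancy = x$occupancy,
    occupancy_fraction = x$occupancy / max(1L, x$n_frames)
  )
}

#' One-row summary of a CAP set
#'
#' @param x a `cap_set`.
#' @param ... unused.
#' @return Tibble with frame counts and the number of empty CAPs.
#' @export
glance.cap_set <- function(x, ...) {
  tibble::tibble(
    condition_label = x$condition_label,
    k = length(x$occupancy), n_frames = x$n_frames,
    n_empty = sum(x$occupancy == 0)
  )
}

#' Compare two CAP sets index by index
#'
#' With fixed centroids, CAP `j` in one condition corresponds to CAP
#' `j` in another; this reports the per-index spatial Pearson
#' correlation between corresponding CAPs plus the occupancy change.
#' Empty CAPs yield `NA` correlation.
#'
#' @param caps_a,caps_b `cap_set`s over the same voxel space with the
#'   same k.
#' @return Tibble with `cap`, `condition_a`, `condition_b`,
#'   `correlation`, `occupancy_a`, `occupancy_b`, `occupancy_delta`.
#' @export
match_and_compare <- function(caps_a, caps_b) {
  stopifnot(inherits(caps_a, "cap_set"), inherits(caps_b, "cap_set"))
  if (length(caps_a$occupancy) != length(caps_b$occupancy) ||
      ncol(caps_a$caps) != ncol(caps_b$caps)) {
    stop("CAP sets differ in k or voxel space", call. = FALSE)
  }
  k <- length(caps_a$occupancy)
  cors <- vapply(seq_len(k), function(j) {
    a <- caps_a$caps[j, ]; b <- caps_b$caps[j, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, numeric(1))
  tibble::tibble(
    cap = seq_len(k),
    condition_a = caps_a$condition_label,
    condition_b = caps_b$condition_label,
    correlation = cors,
    occupancy_a = caps_a$occupancy, occupancy_b = caps_b$occupancy,
    occupancy_delta = caps_b$occupancy - caps_a$occupancy
  )
}
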