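# a centroid_set around given (already centered+normalized) rows
manual_centroids <- function(centroids) {
  structure(
    list(centroids = centroids, k = nrow(centroids), metric = "correlation",
         objective = NA_real_, objective_trace = numeric(0),
         labels = integer(0),
         provenance = list(dataset = "manual", rng_seed = 0L,
                           n_frames = 0L, n_restarts = 0L)),
    class = "centroid_set"
  )
}

test_that("exactly repeated orthogonal patterns cluster perfectly", {
  base <- diag(3)[rep(1:3, each = 10), ] + 0  # 30 frames, 3 orthogonal rows
  base <- cbind(base, -rowSums(base))         # make rows non-constant
  cs <- fit_centroids(base, k = 3, n_restarts = 5, rng_seed = 4)
  expect_equal(cs$objective, 0, tolerance = 1e-20)
  labels <- assign_to_centroids(base, cs)
  expect_identical(length(unique(labels[1:10])), 1L)
  expect_identical(length(unique(labels[11:20])), 1L)
  expect_identical(length(unique(labels[21:30])), 1L)
  expect_identical(length(unique(labels)), 3L)
})

test_that("k = 1 returns the normalized grand-mean direction", {
  withr::with_seed(6, x <- matrix(rnorm(40), 8, 5))
  cs <- fit_centroids(x, k = 1, n_restarts = 2, rng_seed = 1)
  xn <- boldcaps:::normalize_frames(x)
  expect_equal(cs$centroids[1, ], colMeans(xn), tolerance = 1e-10)
})

test_that("the fitted objective equals the exhaustive 2-partition optimum", {
  withr::with_seed(14, {
    a <- matrix(rnorm(6 * 10, mean = 0), 6, 10) + matrix(rep(c(5, 0), each = 5), 6, 10, byrow = TRUE)
    b <- matrix(rnorm(6 * 10, mean = 0), 6, 10) + matrix(rep(c(0, 5), each = 5), 6, 10, byrow = TRUE)
  })
  x <- rbind(a, b)  # 12 frames in 2 well-separated blobs
  cs <- fit_centroids(x, k = 2, n_restarts = 10, rng_seed = 3)
  expect_equal(cs$objective, exhaustive_two_cluster(x), tolerance = 1e-8)
})

test_that("the objective trace is non-increasing and restarts only improve", {
  withr::with_seed(20, x <- matrix(rnorm(60 * 15), 60, 15))
  cs <- fit_centroids(x, k = 4, n_restarts = 1, rng_seed = 7)
  expect_true(all(diff(cs$objective_trace) <= 1e-9))
  more <- fit_centroids(x, k = 4, n_restarts = 10, rng_seed = 7)
  expect_lte(more$objective, cs$objective + 1e-9)
})

test_that("correlation k-means agrees with stats::kmeans on normalized rows", {
  mu_a <- rep(c(3, 0), each = 6)
  mu_b <- rep(c(0, 3), each = 6)
  withr::with_seed(30, {
    x <- rbind(
      matrix(rnorm(20 * 12), 20, 12, byrow = TRUE) + rep(mu_a, each = 20),
      matrix(rnorm(20 * 12), 20, 12, byrow = TRUE) + rep(mu_b, each = 20)
    )
  })
  xn <- boldcaps:::normalize_frames(x)
  cs <- fit_centroids(x, k = 2, n_restarts = 10, rng_seed = 5)
  km <- withr::with_seed(99, kmeans(xn, centers = 2, nstart = 20))
  expect_equal(cs$objective, km$tot.withinss, tolerance = 1e-6)
})

test_that("fixed-centroid assignment is nearest-by-distance with low-index ties", {
  c1 <- c(1, 0, -1) / sqrt(2)
  c2 <- c(0, 1, -1) / sqrt(2)
  cs <- manual_centroids(rbind(c1, c2))
  # a frame equal to a centroid gets its label
  expect_identical(assign_to_centroids(rbind(c2), cs), 2L)
  # exact equidistance breaks toward the lower index
  tie <- c(1, 1, -2) / sqrt(6)
  expect_identical(assign_to_centroids(rbind(tie), cs), 1L)
  # 0.9 A + 0.1 B with A orthogonal to B labels A
  A <- c(1, -1, 0, 0) / sqrt(2)
  B <- c(0, 0, 1, -1) / sqrt(2)
  cs2 <- manual_centroids(rbind(B, A))
  expect_identical(assign_to_centroids(rbind(0.9 * A + 0.1 * B), cs2), 2L)
  expect_error(assign_to_centroids(matrix(0, 1, 5), cs), "voxels")
})

test_that("assignment to fixed centroids never mutates them", {
  withr::with_seed(40, x <- matrix(rnorm(50 * 8), 50, 8))
  cs <- fit_centroids(x[1:30, ], k = 3, n_restarts = 3, rng_seed = 2)
  before <- cs$centroids
  invisible(assign_to_centroids(x[31:50, ], cs))
  expect_identical(cs$centroids, before)
})

test_that("CAP averaging conserves the grand mean and handles empty clusters", {
  withr::with_seed(50, x <- matrix(rnorm(21 * 9), 21, 9))
  labels <- rep(1:3, each = 7)
  caps <- compute_caps(x, labels, 3)
  # occupancy sums to the number of frames
  expect_identical(sum(caps$occupancy), 21L)
  # occupancy-weighted mean of caps equals the grand mean of frames
  recon <- colSums(caps$caps * caps$occupancy) / sum(caps$occupancy)
  expect_equal(recon, colMeans(x), tolerance = 1e-8)
  # cancellation: a cluster of f and -f averages to zero
  f <- rnorm(9)
  cc <- compute_caps(rbind(f, -f), c(1, 1), 1)
  expect_equal(cc$caps[1, ], rep(0, 9), tolerance = 1e-12)
  # single-frame cluster returns the frame
  expect_equal(compute_caps(rbind(f), 1L, 1)$caps[1, ], f)
  # an empty cluster is zero with occupancy 0 and a warning
  expect_warning(e <- compute_caps(rbind(f, f), c(1, 1), 2), "empty")
  expect_identical(e$occupancy, c(2L, 0L))
  expect_identical(e$caps[2, ], rep(0, 9))
})

test_that("CAP set comparison reports per-index correlations and occupancy deltas", {
  withr::with_seed(60, m <- matrix(rnorm(4 * 12), 4, 12))
  a <- compute_caps(m, 1:4, 4, condition_label = "wakefulness")
  expect_equal(match_and_compare(a, a)$correlation, rep(1, 4))
  b <- a
  b$caps[2, ] <- -a$caps[2, ]
  b$condition_label <- "sedation"
  cmp <- match_and_compare(a, b)
  expect_equal(cmp$correlation[2], -1)
  expect_equal(cmp$correlation[-2], rep(1, 3))
  expect_identical(cmp$occupancy_delta, rep(0L, 4))
  short <- compute_caps(m[1:2, ], 1:2, 2)
  expect_error(match_and_compare(a, short), "differ")
})
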