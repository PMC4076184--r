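test_that("voxelwise one-sample t matches the textbook formula and t.test", {
  x <- c(2.1, 1.9, 2.0, 2.2, 1.8)
  res <- condition_significance(cbind(x, -x, rep(0, 5)))
  t_hand <- mean(x) / (sd(x) / sqrt(5))
  expect_equal(res$t_map[1], t_hand, tolerance = 1e-10)
  tt <- t.test(x, alternative = "greater")
  expect_equal(res$t_map[1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_map[1], tt$p.value, tolerance = 1e-10)
  expect_equal(res$t_map[2], -t_hand, tolerance = 1e-10)
  # all-zero maps: t = 0, p = 0.5
  expect_identical(res$t_map[3], 0)
  expect_identical(res$p_map[3], 0.5)
})

test_that("zero-variance voxels return the documented sentinel, not NaN", {
  maps <- cbind(rep(1, 4), rep(-2, 4), rnorm(4))
  res <- condition_significance(maps)
  expect_identical(res$t_map[1], Inf)
  expect_identical(res$p_map[1], 0)
  expect_identical(res$t_map[2], -Inf)
  expect_identical(res$p_map[2], 1)
  expect_false(any(is.nan(res$t_map)) || any(is.nan(res$p_map)))
  expect_error(condition_significance(maps[1:2, ]), "3 subjects")
})

test_that("the linear consciousness contrast is exactly zero on condition-constant data", {
  withr::with_seed(3, base <- matrix(rnorm(6 * 50), 6, 50))
  maps <- list(w = base, s = base, u = base, r = base)
  res <- linear_consciousness_contrast(maps)
  expect_identical(sum(abs(res$weights)), 4)
  expect_equal(sum(res$weights), 0)
  expect_true(all(res$t_map == 0))
  expect_true(all(res$p_map == 0.5))
  expect_false(any(res$sig_mask))
  expect_error(linear_consciousness_contrast(maps, weights = c(1, 1, -1, 0)),
               "sum to 0")
  expect_error(linear_consciousness_contrast(maps[1:3]), "one weight")
})

test_that("subjects with missing condition cells are excluded pairwise", {
  withr::with_seed(4, m <- matrix(rnorm(5 * 20), 5, 20))
  maps <- list(m, m, m, m)
  maps[[2]][4, ] <- NA
  expect_message(res <- linear_consciousness_contrast(maps), "excluding 1")
  expect_identical(res$n_subjects, 4L)
})

test_that("planted monotone gains are preferentially detected at pattern voxels", {
  # subject maps = gain_c * pattern + noise; weights track the gain profile
  gains <- c(1, 0.6, 0.2, 0.9)
  n_sub <- 12L
  nv <- 400L
  pattern <- c(rep(1, 40), rep(0, nv - 40))
  withr::with_seed(7, {
    maps <- lapply(gains, function(g) {
      g * matrix(pattern, n_sub, nv, byrow = TRUE) +
        matrix(rnorm(n_sub * nv, sd = 0.4), n_sub, nv)
    })
  })
  res <- linear_consciousness_contrast(maps, q = 0.05)
  hit_rate <- mean(res$sig_mask[pattern > 0])
  fa_rate <- mean(res$sig_mask[pattern == 0])
  expect_gt(hit_rate, 0.5)
  expect_gt(hit_rate, 5 * max(fa_rate, 1 / nv))
})

test_that("BH-FDR equals the brute-force step-up on an exhaustive small grid", {
  grid <- c(0, 0.004, 0.01, 0.02, 0.04, 0.2, 0.6, 1)
  withr::with_seed(9, {
    for (m in 1:6) {
      for (rep in 1:40) {
        p <- sample(grid, m, replace = TRUE)
        expect_identical(fdr_bh(p, 0.05), bh_oracle(p, 0.05))
        expect_identical(fdr_bh(p, 0.2), bh_oracle(p, 0.2))
      }
    }
  })
  expect_identical(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_identical(fdr_bh(c(0.5, 0.6), 0.05), rep(FALSE, 2))
  expect_identical(fdr_bh(rep(0, 5), 0.05), rep(TRUE, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("seed correlation maps behave on self, negation, and degenerate windows", {
  nt <- 60L
  withr::with_seed(10, mat <- matrix(rnorm(nt * 5), nt, 5))
  mat[, 2] <- -mat[, 1]
  ses <- session_from_matrix(mat, standardized = TRUE)
  cmap <- seed_correlation_map(ses, 1L)
  expect_equal(cmap[1], 1)
  expect_equal(cmap[2], -1)
  # full-length window degenerates to the static map
  sw <- sliding_window_maps(ses, 1L, window_frames = nt, step = 1)
  expect_identical(nrow(sw$maps), 1L)
  expect_equal(sw$maps[1, ], cmap, tolerance = 1e-12)
})

test_that("sliding windows are counted by the floor formula", {
  ses <- session_from_matrix(matrix(rnorm(50 * 3), 50, 3),
                             standardized = TRUE)
  for (w in c(5, 10, 20)) {
    for (st in c(1, 3, 7)) {
      sw <- sliding_window_maps(ses, 1L, w, st)
      expect_identical(nrow(sw$windows), as.integer(floor((50 - w) / st) + 1))
    }
  }
  expect_error(sliding_window_maps(ses, 1L, 60), "longer")
  expect_error(sliding_window_maps(ses, 1L, 2), "window_frames")
})

test_that("null contrasts control the voxelwise rejection rate", {
  # global null: no condition effect anywhere; BH at q = 0.05
  n_rep <- 60L
  n_sub <- 10L
  nv <- 150L
  withr::with_seed(123, {
    rej <- vapply(seq_len(n_rep), function(r) {
      maps <- lapply(1:4, function(cc) matrix(rnorm(n_sub * nv), n_sub, nv))
      mean(linear_consciousness_contrast(maps, q = 0.05)$sig_mask)
    }, numeric(1))
  })
  n_tot <- n_rep * nv
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / n_tot))
})
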