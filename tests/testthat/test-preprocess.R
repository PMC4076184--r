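test_that("bandpass passes in-band sinusoids and kills DC and out-of-band", {
  tr <- 2.46
  nt <- 2000L
  t_sec <- (seq_len(nt) - 1) * tr
  mid <- 800:1200  # away from filtfilt edge transients
  mat <- cbind(
    rep(5, nt),                     # DC
    sin(2 * pi * 0.05 * t_sec),     # in band
    sin(2 * pi * 0.19 * t_sec)      # ~1 octave above the band
  )
  out <- voxel_matrix(bandpass_filter(session_from_matrix(mat, tr),
                                      0.005, 0.1))
  expect_lt(max(abs(out[, 1])), 1e-6)
  expect_gte(max(abs(out[mid, 2])), 0.9)
  expect_lte(max(abs(out[mid, 3])), 0.1)
})

test_that("bandpass rejects bands at or beyond Nyquist", {
  ses <- session_from_matrix(matrix(rnorm(20), ncol = 1), tr_seconds = 2.46)
  expect_error(bandpass_filter(ses, 0.005, 0.21), "Nyquist")
  expect_error(bandpass_filter(ses, 0.1, 0.05), "low_hz")
})

test_that("polynomial detrending is an exact projection", {
  nt <- 50L
  tt <- seq_len(nt)
  quad <- 2 + 0.3 * tt - 0.01 * tt^2
  cubic <- (tt / 10)^3
  withr::with_seed(8, noise <- rnorm(nt))
  ses <- session_from_matrix(cbind(quad, cubic, noise))
  out <- voxel_matrix(detrend_poly(ses, order = 2))
  # exact quadratic -> zero
  expect_lt(max(abs(out[, 1])), 1e-8)
  # cubic -> residual of the least-squares quadratic fit (lm oracle)
  oracle <- residuals(lm(cubic ~ tt + I(tt^2)))
  expect_equal(out[, 2], unname(oracle), tolerance = 1e-8)
  # projection contracts the norm
  expect_lte(var(out[, 3]), var(noise))
  # residual orthogonal to the basis
  basis <- cbind(1, tt, tt^2)
  expect_lt(max(abs(crossprod(basis, out))) /
              (max(abs(basis)) * max(abs(out))), 1e-8)
  expect_error(detrend_poly(ses, order = 3), "order")
})

test_that("nuisance regression matches the OLS oracle and flags collinearity", {
  nt <- 60L
  withr::with_seed(11, {
    reg <- matrix(rnorm(nt * 3), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
    y <- matrix(rnorm(nt * 4), ncol = 4)
  })
  y[, 1] <- reg[, 1]                       # equals a regressor
  ses <- session_from_matrix(y)
  out <- voxel_matrix(regress_nuisance(ses, reg))
  expect_lt(max(abs(out[, 1])), 1e-8)
  oracle <- residuals(lm(y[, 2] ~ reg))
  expect_equal(out[, 2], unname(oracle), tolerance = 1e-8)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(crossprod(reg, out))), 1e-6)
  dup <- cbind(reg, d = reg[, 1])
  expect_error(regress_nuisance(ses, dup), "collinear")
  zero <- cbind(reg, z = 0)
  expect_error(regress_nuisance(ses, zero), "all-zero")
})

test_that("spatial smoothing has the closed-form Gaussian peak and conserves mass", {
  n <- 15L
  nt <- 10L
  dat <- array(0, dim = c(n, n, n, nt))
  dat[8, 8, 8, ] <- 1  # centered impulse in every frame
  ses <- bold_session(dat, array(TRUE, dim = c(n, n, n)), 2.46)
  sm <- smooth_spatial(ses, fwhm_mm = 8)
  sigma_vox <- 8 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sm$data[8, 8, 8, 1], (2 * pi * sigma_vox^2)^(-3 / 2),
               tolerance = 0.02)
  # kernel sums to 1: total intensity conserved
  expect_equal(sum(sm$data[, , , 1]), 1, tolerance = 0.01)
  # fwhm 0 is the identity
  expect_identical(smooth_spatial(ses, 0)$data, ses$data)
  # constant volume stays constant in the interior
  const <- bold_session(array(3, dim = c(n, n, n, nt)),
                        array(TRUE, dim = c(n, n, n)), 2.46)
  smc <- smooth_spatial(const, 6)
  expect_equal(smc$data[5:11, 5:11, 5:11, 1],
               array(3, dim = c(7, 7, 7)), tolerance = 1e-9)
})

test_that("standardization is exact, idempotent, and flags flat voxels", {
  mat <- cbind(c(1, 2, 3, rep(2, 9)), rep(7, 12))
  ses <- session_from_matrix(mat)
  expect_warning(out <- standardize(ses), "1 zero-variance")
  vm <- voxel_matrix(out)
  expect_equal(mean(vm[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(vm[, 1]), 1, tolerance = 1e-12)
  expect_identical(vm[, 2], rep(0, 12))
  expect_identical(attr(out, "n_zero_variance"), 1L)
  # sample SD convention on the documented 3-point example
  short <- standardize(session_from_matrix(
    cbind(rep(c(1, 2, 3), 4))))
  first3 <- voxel_matrix(short)[1:3, 1]
  expect_equal(first3, (c(1, 2, 3) - 2) / sd(rep(1:3, 4)) * 1,
               tolerance = 1e-12)
  # idempotence (the flat voxel is re-flagged, which is fine)
  again <- suppressWarnings(standardize(out))
  expect_equal(voxel_matrix(again), vm, tolerance = 1e-12)
})

test_that("every stage leaves out-of-mask voxels untouched", {
  n <- 10L
  mask <- array(FALSE, dim = c(n, n, n))
  mask[3:8, 3:8, 3:8] <- TRUE
  withr::with_seed(4, dat <- array(rnorm(n^3 * 20, 5), dim = c(n, n, n, 20)))
  ses <- bold_session(dat, mask, 2.46)
  outside <- !rep(mask, 20)
  for (f in list(function(s) detrend_poly(s, 2),
                 function(s) bandpass_filter(s),
                 function(s) smooth_spatial(s, 6),
                 function(s) standardize(s))) {
    res <- suppressWarnings(f(ses))
    expect_true(all(res$data[outside] == 0))
  }
})

test_that("the full chain preserves planted patterns at isolated events", {
  p <- sim_params(n_subjects = 1, n_conditions = 1, n_frames = 120,
                  grid_dims = c(20, 24, 20), k_true = 3, noise_sd = 0,
                  drift_sd = 1, physio_sd = 2, rng_seed = 11)
  co <- generate_cohort(p)
  ses <- co$sessions$session[[1]]
  nuis <- build_nuisance(ses, co$sessions$motion_params[[1]],
                         include = "motion")
  pre <- suppressWarnings(preprocess_session(ses, nuisance = nuis,
                                             fwhm_mm = 6))
  vm <- voxel_matrix(pre)
  ev <- co$truth$event_times[[1]]
  lag <- co$truth$peak_lag_frames
  iso <- which(vapply(seq_len(nrow(ev)), function(i) {
    all(abs(ev$frame[-i] - ev$frame[i]) > 4) && ev$frame[i] + lag <= 120
  }, logical(1)))
  expect_gt(length(iso), 1)
  cors <- vapply(iso, function(i) {
    cor(vm[ev$frame[i] + lag, ], co$truth$patterns[ev$pattern[i], ])
  }, numeric(1))
  expect_true(all(cors >= 0.8))
})
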