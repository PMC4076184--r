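#' Temporal bandpass filter
#'
#' Zero-phase (forward-backward) Butterworth bandpass, order 2 per
#' pass, applied to every in-mask voxel time series. The forward and
#' backward passes square the magnitude response, so the effective
#' attenuation outside the band is the single-pass response squared.
#' The mean (0 Hz) lies below any positive low cutoff and is removed.
#'
#' @param session a [bold_session()].
#' @param low_hz,high_hz band edges in Hz; `0 <= low_hz < high_hz` and
#'   `high_hz` must be below the Nyquist frequency `1 / (2 TR)`.
#' @return The filtered session.
#' @export
bandpass_filter <- function(session, low_hz = 0.005, high_hz = 0.1) {
  nyq <- 1 / (2 * session$tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz) {
    stop("need 0 <= low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyq) {
    stop(sprintf("high_hz (%.4g) must be below Nyquist (%.4g Hz)",
                 high_hz, nyq), call. = FALSE)
  }
  flt <- if (low_hz > 0) {
    signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  } else {
    signal::butter(2, high_hz / nyq, type = "low")
  }
  vm <- voxel_matrix(session)
  # remove the mean first: 0 Hz is below any positive low cutoff, and a
  # demeaned input avoids the slow step transient of the low band edge
  vm <- sweep(vm, 2, colMeans(vm), `-`)
  out <- apply(vm, 2, function(x) signal::filtfilt(flt, x))
  if (low_hz == 0) out <- sweep(out, 2, colMeans(out), `-`)
  set_voxel_matrix(session, out)
}

#' Remove polynomial temporal trends
#'
#' Projects every in-mask voxel time series onto the orthogonal
#' complement of the polynomial basis `1, t, ..., t^order`, removing
#' linear (and, with `order = 2`, quadratic) drift together with the
#' mean. The residual is orthogonal to the basis by construction.
#'
#' @param session a [bold_session()].
#' @param order polynomial order, 1 or 2.
#' @return The detrended session.
#' @export
detrend_poly <- function(session, order = 2L) {
  if (!order %in% 1:2) stop("`order` must be 1 or 2", call. = FALSE)
  nt <- n_frames(session)
  if (nt <= order + 1) {
    stop("too few frames for a degree-", order, " fit", call. = FALSE)
  }
  tt <- seq_len(nt)
  basis <- cbind(1, stats::poly(tt, degree = order))
  vm <- voxel_matrix(session)
  fit <- basis %*% qr.solve(qr(basis), vm)
  set_voxel_matrix(session, vm - fit)
}

#' Assemble a nuisance regressor matrix
#'
#' Builds the standard nuisance set: the brain-averaged (global)
#' signal, mean series of white-matter and CSF stand-in masks, and the
#' six rigid-body motion parameters. On synthetic grids there is no
#' tissue segmentation, so the WM/CSF masks are caller-supplied stand-in
#' masks (or omitted).
#'
#' @param session a [bold_session()].
#' @param motion_params optional frames x 6 matrix.
#' @param wm_mask,csf_mask optional 3D logical arrays on the session
#'   grid.
#' @param include character subset of
#'   `c("global", "wm", "csf", "motion")`.
#' @return A frames x r numeric matrix with named columns (possibly 0
#'   columns).
#' @export
build_nuisance <- function(session, motion_params = NULL,
                           wm_mask = NULL, csf_mask = NULL,
                           include = c("global", "motion")) {
  include <- match.arg(include, c("global", "wm", "csf", "motion"),
                       several.ok = TRUE)
  vm <- voxel_matrix(session)
  cols <- list()
  if ("global" %in% include) cols$global <- rowMeans(vm)
  roi_mean <- function(roi) {
    sel <- as.vector(roi)[as.vector(session$mask)]
    rowMeans(vm[, sel, drop = FALSE])
  }
  if ("wm" %in% include && !is.null(wm_mask)) cols$wm <- roi_mean(wm_mask)
  if ("csf" %in% include && !is.null(csf_mask)) cols$csf <- roi_mean(csf_mask)
  if ("motion" %in% include && !is.null(motion_params)) {
    mp <- as.matrix(motion_params)
    if (ncol(mp) != 6L) stop("motion_params must have 6 columns", call. = FALSE)
    colnames(mp) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
    cols <- c(cols, as.list(as.data.frame(mp)))
  }
  reg <- do.call(cbind, cols)
  if (is.null(reg)) reg <- matrix(numeric(0), nrow = nrow(vm), ncol = 0)
  reg
}

#' Regress nuisance signals out of a session
#'
#' Ordinary least squares per voxel: an intercept is always included,
#' and the residual is orthogonal to every supplied regressor. Flagged
#' all-zero regressors and rank-deficient designs are rejected with the
#' offending column names.
#'
#' @param session a [bold_session()].
#' @param nuisance frames x r regressor matrix, e.g. from
#'   [build_nuisance()].
#' @return The residual session.
#' @export
regress_nuisance <- function(session, nuisance) {
  nuisance <- as.matrix(nuisance)
  nt <- n_frames(session)
  if (nrow(nuisance) != nt) stop("regressor length mismatch", call. = FALSE)
  if (ncol(nuisance) > nt - 2) {
    stop("too many regressors for the series length", call. = FALSE)
  }
  zero_cols <- which(apply(nuisance, 2, function(x) all(x == 0)))
  if (length(zero_cols)) {
    stop("all-zero nuisance regressor(s): ",
         paste(colnames(nuisance)[zero_cols], collapse = ", "), call. = FALSE)
  }
  X <- cbind(`(intercept)` = 1, nuisance)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1, ncol(X))]]
    stop("collinear nuisance regressor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vm <- voxel_matrix(session)
  res <- vm - X %*% qr.coef(qrx, vm)
  set_voxel_matrix(session, res)
}

# reflective-boundary 1-D Gaussian convolution matrix of size n
gauss_conv_matrix <- function(n, sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  w <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq(-half, half)) {
      j <- i + k
      # reflect about the edges (half-sample symmetric)
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      K[i, j] <- K[i, j] + w[k + half + 1L]
    }
  }
  K
}

#' Spatial Gaussian smoothing
#'
#' Separable 3D Gaussian smoothing of every frame with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis, converted to voxel
#' units from the session's voxel size. Boundaries are handled by
#' reflection, which avoids edge dimming on small grids; the kernel
#' sums to 1 so total intensity is conserved away from mask edges.
#' Smoothing acts on the masked volume (out-of-mask voxels are zero
#' before and after).
#'
#' @param session a [bold_session()].
#' @param fwhm_mm full width at half maximum in mm; 0 is the identity.
#' @return The smoothed session.
#' @export
smooth_spatial <- function(session, fwhm_mm = 8) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(session)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  gd <- dim(session$data)[1:3]
  nt <- dim(session$data)[4]
  Ks <- lapply(1:3, function(a) gauss_conv_matrix(gd[a], sigma_mm / session$voxel_mm[a]))
  dat <- session$data
  dat[!rep(session$mask, nt)] <- 0
  for (f in seq_len(nt)) {
    vol <- dat[, , , f]
    # axis 1
    vol <- array(Ks[[1]] %*% matrix(vol, gd[1]), dim = gd)
    # axis 2
    v2 <- aperm(vol, c(2, 1, 3))
    v2 <- array(Ks[[2]] %*% matrix(v2, gd[2]), dim = gd[c(2, 1, 3)])
    vol <- aperm(v2, c(2, 1, 3))
    # axis 3
    v3 <- aperm(vol, c(3, 1, 2))
    v3 <- array(Ks[[3]] %*% matrix(v3, gd[3]), dim = gd[c(3, 1, 2)])
    vol <- aperm(v3, c(2, 3, 1))
    vol[!session$mask] <- 0
    dat[, , , f] <- vol
  }
  session$data <- dat
  session
}

#' Voxelwise standardization
#'
#' Demeans every in-mask voxel time series and divides by its temporal
#' sample standard deviation (denominator n - 1). Voxels with (numerically)
#' zero variance — SD below `1e-8` times the largest voxel SD, which
#' catches exact zeros as well as pure float residue left by earlier
#' stages — are set to 0 and reported via a warning and the
#' `n_zero_variance` attribute.
#'
#' @param session a [bold_session()].
#' @return The standardized session (`$standardized` set to `TRUE`).
#' @export
standardize <- function(session) {
  vm <- voxel_matrix(session)
  mu <- colMeans(vm)
  sdv <- apply(vm, 2, stats::sd)
  tol <- 1e-8 * max(sdv[is.finite(sdv)], 0)
  zero <- sdv <= tol | !is.finite(sdv)
  sdv[zero] <- 1
  out <- sweep(sweep(vm, 2, mu, `-`), 2, sdv, `/`)
  out[, zero] <- 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance voxel(s) set to 0", call. = FALSE)
  }
  session <- set_voxel_matrix(session, out)
  session$standardized <- TRUE
  attr(session, "n_zero_variance") <- sum(zero)
  session
}

# apply the same temporal operations (polynomial detrend, bandpass) to
# the nuisance regressors that were applied to the data, so regression
# removes the regressors' in-band content completely instead of fitting
# filtered data with unfiltered series (filter-regressor mismatch).
filter_regressors <- function(nuisance, tr_seconds, detrend_order,
                              bandpass) {
  nuisance <- as.matrix(nuisance)
  if (!is.null(detrend_order)) {
    tt <- seq_len(nrow(nuisance))
    basis <- cbind(1, stats::poly(tt, degree = detrend_order))
    nuisance <- nuisance - basis %*% qr.coef(qr(basis), nuisance)
  }
  if (!is.null(bandpass)) {
    nyq <- 1 / (2 * tr_seconds)
    flt <- if (bandpass[1] > 0) {
      signal::butter(2, bandpass / nyq, type = "pass")
    } else {
      signal::butter(2, bandpass[2] / nyq, type = "low")
    }
    nuisance <- apply(nuisance, 2, function(x) signal::filtfilt(flt, x))
  }
  nuisance
}

#' Full preprocessing chain
#'
#' Applies, in order: polynomial detrending, zero-phase bandpass,
#' nuisance regression, spatial smoothing, voxelwise standardization.
#' Detrending before filtering keeps drift out of the filter's pass
#' band edge; nuisance regressors are passed through the same detrend
#' and bandpass operations as the data before regression, so their
#' in-band content is removed completely (no filter-regressor
#' frequency mismatch); regression before smoothing keeps nuisance
#' estimates at native resolution. Any stage can be disabled.
#'
#' @param session a [bold_session()].
#' @param detrend_order 1, 2, or `NULL` to skip.
#' @param bandpass `c(low_hz, high_hz)` or `NULL` to skip.
#' @param nuisance regressor matrix or `NULL` to skip.
#' @param fwhm_mm smoothing kernel FWHM; 0 or `NULL` to skip.
#' @param do_standardize standardize at the end (default `TRUE`).
#' @return The preprocessed session.
#' @export
preprocess_session <- function(session, detrend_order = 2L,
                               bandpass = c(0.005, 0.1), nuisance = NULL,
                               fwhm_mm = 8, do_standardize = TRUE) {
  if (!is.null(detrend_order)) session <- detrend_poly(session, detrend_order)
  if (!is.null(bandpass)) {
    session <- bandpass_filter(session, bandpass[1], bandpass[2])
  }
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0) {
    nuisance <- filter_regressors(nuisance, session$tr_seconds,
                                  detrend_order, bandpass)
    session <- regress_nuisance(session, nuisance)
  }
  if (!is.null(fwhm_mm) && fwhm_mm > 0) {
    session <- smooth_spatial(session, fwhm_mm)
  }
  if (do_standardize) session <- standardize(session)
  session
}
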