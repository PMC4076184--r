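#' Simulation parameters for a synthetic CAP cohort
#'
#' Bundles the study-design knobs of the synthetic generator. The
#' defaults emulate a propofol-style resting-state protocol: 18 subjects
#' scanned in 4 conditions, 197 volumes per session at TR = 2.46 s, on a
#' 20 x 24 x 20 grid of 3 mm voxels, with supra-threshold seed events at
#' roughly 15% of frames and per-condition motion-spike rates of
#' 5%, 3%, 8% and 1%.
#'
#' @param n_subjects,n_conditions cohort size.
#' @param n_frames frames per session (>= 10).
#' @param tr_seconds repetition time in seconds.
#' @param grid_dims 3 integers, the voxel grid.
#' @param voxel_mm voxel edge lengths in mm.
#' @param k_true number of planted spatial patterns (>= 1). This is a
#'   free simulation knob, not an estimate of how many patterns real
#'   data contains.
#' @param event_rate per-frame Bernoulli probability of a seed event,
#'   in (0, 1).
#' @param amplitude BOLD amplitude (a.u.) of an event at HRF peak,
#'   before the condition gain multiplier.
#' @param seed_amplitude amplitude added to the seed cube at every
#'   event regardless of which pattern fired, so the seed signal peaks
#'   whenever any pattern is expressed.
#' @param baseline constant intensity offset (a.u.); gives DVARS'
#'   percent-of-mean normalization a realistic denominator.
#' @param physio_sd SD of a brain-wide slow physiological-like
#'   fluctuation (a.u.) shared by all in-mask voxels; gives every voxel
#'   temporal variance even in the noiseless limit, which keeps
#'   voxelwise standardization well defined.
#' @param noise_sd SD of i.i.d. Gaussian voxel noise (a.u.).
#' @param drift_sd SD of the random per-voxel linear and quadratic
#'   drift coefficients (a.u. over the session).
#' @param spike_rate per-frame probability of a motion spike; recycled
#'   over conditions, so a vector gives condition-specific rates.
#' @param seed_edge_mm edge of the cubic seed region planted at the
#'   grid center.
#' @param rng_seed integer seed; the same seed reproduces the cohort
#'   bit-identically.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 18L, n_conditions = 4L,
                       n_frames = 197L, tr_seconds = 2.46,
                       grid_dims = c(20L, 24L, 20L), voxel_mm = c(3, 3, 3),
                       k_true = 8L, event_rate = 0.15,
                       amplitude = 4, seed_amplitude = 4, baseline = 1000,
                       physio_sd = 2, noise_sd = 1, drift_sd = 1,
                       spike_rate = c(0.05, 0.03, 0.08, 0.01),
                       seed_edge_mm = 6, rng_seed = 1L) {
  stopifnot(n_subjects >= 1L, n_conditions >= 1L)
  if (n_frames < 10L) stop("n_frames must be >= 10", call. = FALSE)
  if (k_true < 1L) stop("k_true must be >= 1", call. = FALSE)
  if (event_rate <= 0 || event_rate >= 1) {
    stop("event_rate must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_conditions = as.integer(n_conditions),
      n_frames = as.integer(n_frames), tr_seconds = tr_seconds,
      grid_dims = as.integer(grid_dims), voxel_mm = as.numeric(voxel_mm),
      k_true = as.integer(k_true), event_rate = event_rate,
      amplitude = amplitude, seed_amplitude = seed_amplitude,
      baseline = baseline, physio_sd = physio_sd,
      noise_sd = noise_sd, drift_sd = drift_sd,
      spike_rate = rep_len(spike_rate, n_conditions),
      seed_edge_mm = seed_edge_mm, rng_seed = as.integer(rng_seed)
    ),
    class = "sim_params"
  )
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' The standard difference-of-gammas impulse response (response peak
#' near 5 s, undershoot near 15 s), sampled at the repetition time and
#' scaled so its continuous-time peak equals 1. Events planted by the
#' generator are convolved with this kernel, so a neural event at frame
#' `i` produces its BOLD peak `which.max(kernel) - 1` frames later.
#'
#' @param tr_seconds sampling interval in seconds.
#' @param duration_seconds kernel support; 32 s covers the undershoot.
#' @return Numeric vector of kernel samples starting at lag 0.
#' @export
hrf_kernel <- function(tr_seconds, duration_seconds = 32) {
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- function(tt) {
    stats::dgamma(tt, shape = 6, rate = 1) -
      stats::dgamma(tt, shape = 16, rate = 1) / 6
  }
  h(t) / h(5)
}

# K blob patterns with disjoint supports on the grid: each pattern is a
# pair of Gaussian blobs (truncated at 3 sigma, so supports are compact)
# centered in lattice cells assigned to it alone, which keeps pairwise
# spatial correlation far below 0.5 by construction.
make_patterns <- function(grid_dims, mask, k_true, sigma_vox = 1.6) {
  nv <- sum(mask)
  coords <- which(mask, arr.ind = TRUE)
  # partition the grid into >= 2*k_true cells and take the cell centers
  n_cells_axis <- ceiling((2 * k_true)^(1 / 3))
  centers <- as.matrix(expand.grid(
    x = seq(1, grid_dims[1], length.out = n_cells_axis + 2)[-c(1, n_cells_axis + 2)],
    y = seq(1, grid_dims[2], length.out = n_cells_axis + 2)[-c(1, n_cells_axis + 2)],
    z = seq(1, grid_dims[3], length.out = n_cells_axis + 2)[-c(1, n_cells_axis + 2)]
  ))
  if (nrow(centers) < 2 * k_true) {
    stop("grid too small to place ", k_true, " distinct patterns", call. = FALSE)
  }
  centers <- centers[sample(nrow(centers))[seq_len(2 * k_true)], , drop = FALSE]
  pat <- matrix(0, nrow = k_true, ncol = nv)
  for (j in seq_len(k_true)) {
    for (b in c(2 * j - 1, 2 * j)) {
      d2 <- rowSums(sweep(coords, 2, centers[b, ], `-`)^2)
      blob <- exp(-d2 / (2 * sigma_vox^2))
      blob[d2 > (3 * sigma_vox)^2] <- 0
      pat[j, ] <- pat[j, ] + blob
    }
    pat[j, ] <- pat[j, ] / max(pat[j, ])
  }
  pat
}

# linear indices (within the mask-column ordering) of the seed cube
seed_cube_indices <- function(grid_dims, voxel_mm, origin_mm, mask, edge_mm) {
  ijk <- which(mask, arr.ind = TRUE)
  mm <- sweep(sweep(ijk - 1, 2, voxel_mm, `*`), 2, origin_mm, `+`)
  center <- c(0, 0, 0)
  inside <- abs(mm[, 1] - center[1]) <= edge_mm / 2 &
    abs(mm[, 2] - center[2]) <= edge_mm / 2 &
    abs(mm[, 3] - center[3]) <= edge_mm / 2
  which(inside)
}

#' Generate a synthetic multi-subject, multi-condition BOLD cohort
#'
#' Builds `n_subjects x n_conditions` sessions with known ground truth:
#' each session's signal is a sum over planted spatial patterns of
#' (condition gain) x (pattern map) x (HRF-convolved event train), plus
#' a constant baseline, per-voxel linear and quadratic drift, and white
#' Gaussian noise. The seed cube additionally receives a positive
#' amplitude at every event regardless of which pattern fired. Motion
#' traces carry baseline jitter plus translation steps at spike frames;
#' the image intensity is blipped globally at the same frames so both
#' FD and DVARS flag them.
#'
#' @param params a [sim_params()] object.
#' @param gains `n_conditions x k_true` matrix of non-negative pattern
#'   amplitude multipliers. Row `c` both scales pattern amplitudes in
#'   condition `c` and weights which pattern an event expresses.
#'   Defaults to all ones (no condition effect).
#'
#' @return A list with elements
#'   * `sessions`: tibble with columns `subject_id`, `condition_label`,
#'     `session` (list of [bold_session()]), `motion_params` (list of
#'     frames x 6 matrices: translations mm, rotations rad);
#'   * `truth`: a `ground_truth` list — `patterns` (k_true x voxels,
#'     in-mask), `condition_gains`, `event_times` (per-session tibbles
#'     of frame/pattern), `motion_spike_frames`, `seed_voxels` (in-mask
#'     column indices), `hrf` and `peak_lag_frames`, `noise_sd`,
#'     `drift_coeffs`, plus the mask and grid geometry.
#' @export
generate_cohort <- function(params, gains = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(gains)) {
    gains <- matrix(1, params$n_conditions, params$k_true)
  }
  gains <- as.matrix(gains)
  if (!identical(dim(gains), c(params$n_conditions, params$k_true))) {
    stop(sprintf("`gains` must be %d x %d (conditions x patterns)",
                 params$n_conditions, params$k_true), call. = FALSE)
  }
  if (any(gains < 0)) stop("condition gains must be non-negative", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(params$rng_seed)

  gd <- params$grid_dims
  nt <- params$n_frames
  # ellipsoidal brain mask inscribed in the grid
  ax <- lapply(1:3, function(a) (seq_len(gd[a]) - (gd[a] + 1) / 2) / (gd[a] / 2))
  mask <- array(
    outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`) <= 1,
    dim = gd
  )
  origin_mm <- -(gd - 1) / 2 * params$voxel_mm
  nv <- sum(mask)

  patterns <- make_patterns(gd, mask, params$k_true)
  seed_vox <- seed_cube_indices(gd, params$voxel_mm, origin_mm, mask,
                                params$seed_edge_mm)
  hrf <- hrf_kernel(params$tr_seconds)
  peak_lag <- which.max(hrf) - 1L
  cond_labels <- c("wakefulness", "sedation", "unconsciousness", "recovery",
                   paste0("condition", 5:20))[seq_len(params$n_conditions)]

  tvec <- seq(-1, 1, length.out = nt)
  drift_basis <- cbind(tvec, tvec^2)

  rows <- vector("list", params$n_subjects * params$n_conditions)
  event_times <- vector("list", length(rows))
  spike_frames <- vector("list", length(rows))
  drift_coeffs <- vector("list", length(rows))
  idx <- 0L
  for (s in seq_len(params$n_subjects)) {
    for (cc in seq_len(params$n_conditions)) {
      idx <- idx + 1L
      sid <- sprintf("sub-%02d", s)
      g <- gains[cc, ]

      is_event <- stats::runif(nt) < params$event_rate
      ev_frames <- which(is_event)
      ev_pattern <- if (length(ev_frames) && sum(g) > 0) {
        sample.int(params$k_true, length(ev_frames), replace = TRUE,
                   prob = g / sum(g))
      } else integer(0)
      if (sum(g) == 0) ev_frames <- integer(0)

      # per-pattern event trains convolved with the HRF
      sig <- matrix(0, nrow = nt, ncol = nv)
      any_train <- numeric(nt)
      for (j in seq_len(params$k_true)) {
        tr_j <- numeric(nt)
        fj <- ev_frames[ev_pattern == j]
        tr_j[fj] <- params$amplitude * g[j]
        if (any(tr_j != 0)) {
          conv <- stats::convolve(tr_j, rev(hrf), type = "open")[seq_len(nt)]
          sig <- sig + conv %o% patterns[j, ]
        }
      }
      any_train[ev_frames] <- params$seed_amplitude
      if (any(any_train != 0)) {
        conv_any <- stats::convolve(any_train, rev(hrf), type = "open")[seq_len(nt)]
        sig[, seed_vox] <- sig[, seed_vox] + conv_any
      }

      if (params$physio_sd > 0) {
        # brain-wide slow fluctuation: smoothed white noise, unit SD
        raw <- stats::filter(stats::rnorm(nt + 16), rep(1 / 10, 10),
                             sides = 1)[17:(nt + 16)]
        g <- params$physio_sd * as.numeric(scale(raw))
        sig <- sig + g
      }
      dc <- matrix(stats::rnorm(nv * 2, sd = params$drift_sd), ncol = 2)
      sig <- sig + drift_basis %*% t(dc)
      if (params$noise_sd > 0) {
        sig <- sig + matrix(stats::rnorm(nt * nv, sd = params$noise_sd),
                            nrow = nt)
      }
      sig <- sig + params$baseline

      # motion: baseline jitter + persistent translation steps at spikes
      # binomial spike count at the condition's rate, placed with a
      # minimum gap of 2 frames: adjacent corrupted frames would mask
      # each other's DVARS excursion under the joint (FD AND DVARS) rule
      n_sp <- stats::rbinom(1, nt, params$spike_rate[cc])
      sp <- integer(0)
      for (f in sample(2:nt)) {
        if (length(sp) >= n_sp) break
        if (!any(abs(sp - f) <= 1L)) sp <- c(sp, f)
      }
      sp <- sort(sp)
      mp <- cbind(
        matrix(stats::rnorm(nt * 3, sd = 0.01), ncol = 3),
        matrix(stats::rnorm(nt * 3, sd = 2e-4), ncol = 3)
      )
      for (f in sp) {
        step <- 0.8 * sample(c(-1, 1), 1)
        mp[f:nt, 1] <- mp[f:nt, 1] + step
        # single-frame global intensity blip of 1% BOLD: far enough above
        # the 0.5% DVARS censoring threshold that slow-fluctuation swings
        # cannot mask it, yet mild enough not to distort the session's
        # variance structure
        sig[f, ] <- sig[f, ] * 1.01
      }
      colnames(mp) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")

      flat <- matrix(0, nrow = prod(gd), ncol = nt)
      flat[as.vector(mask), ] <- t(sig)
      d4 <- array(flat, dim = c(gd, nt))

      ses <- bold_session(
        d4, mask, params$tr_seconds, subject_id = sid,
        condition_label = cond_labels[cc], voxel_mm = params$voxel_mm,
        origin_mm = origin_mm, space_tag = "synthetic"
      )
      rows[[idx]] <- tibble::tibble(
        subject_id = sid, condition_label = cond_labels[cc],
        session = list(ses), motion_params = list(mp)
      )
      event_times[[idx]] <- tibble::tibble(frame = ev_frames,
                                           pattern = ev_pattern)
      spike_frames[[idx]] <- sp
      drift_coeffs[[idx]] <- dc
    }
  }

  sessions <- dplyr::bind_rows(rows)
  key <- paste(sessions$subject_id, sessions$condition_label, sep = "/")
  names(event_times) <- names(spike_frames) <- names(drift_coeffs) <- key

  truth <- structure(
    list(
      patterns = patterns, condition_gains = gains,
      condition_labels = cond_labels,
      event_times = event_times, motion_spike_frames = spike_frames,
      drift_coeffs = drift_coeffs, noise_sd = params$noise_sd,
      seed_voxels = seed_vox, hrf = hrf, peak_lag_frames = peak_lag,
      mask = mask, grid_dims = gd, voxel_mm = params$voxel_mm,
      origin_mm = origin_mm, params = params
    ),
    class = "ground_truth"
  )
  list(sessions = sessions, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d patterns on %d in-mask voxels, %d sessions, seed cube of %d voxels\n",
    nrow(x$patterns), ncol(x$patterns), length(x$event_times),
    length(x$seed_voxels)
  ))
  invisible(x)
}
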