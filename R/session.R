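#' BOLD session container
#'
#' A `bold_session` holds one subject x condition 4D BOLD time series
#' together with its grid geometry: a 3D logical brain mask, the voxel
#' size in mm, the mm coordinate of the first voxel's center, and the
#' repetition time. All voxelwise operations in the package act on the
#' in-mask voxels only; out-of-mask voxels are left untouched.
#'
#' @param data 4D numeric array (x, y, z, t) of BOLD intensities (a.u.).
#' @param mask 3D logical array matching the spatial dimensions of
#'   `data`; at least one voxel must be `TRUE`.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id,condition_label identifiers carried through the
#'   pipeline and into all tidy outputs.
#' @param voxel_mm voxel edge lengths in mm along x, y, z.
#' @param origin_mm mm coordinate of the center of voxel (1, 1, 1).
#'   Defaults to placing the grid center at the mm origin, which is the
#'   convention for synthetic grids that live in no standard space.
#' @param space_tag `"synthetic"` or `"MNI"`; only used to label seed
#'   specifications so mismatched seed/session spaces can be caught.
#'
#' @return An object of class `bold_session`.
#' @export
bold_session <- function(data, mask, tr_seconds,
                         subject_id = "sub-01", condition_label = "none",
                         voxel_mm = c(3, 3, 3), origin_mm = NULL,
                         space_tag = "synthetic") {
  if (length(dim(data)) != 4L) {
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  }
  if (!identical(dim(mask), dim(data)[1:3])) {
    stop("`mask` dimensions must match the spatial dimensions of `data`",
         call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("`mask` must contain at least one voxel", call. = FALSE)
  if (dim(data)[4] < 10L) {
    stop("a session needs at least 10 frames", call. = FALSE)
  }
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0)) {
    stop("`voxel_mm` must be 3 positive lengths", call. = FALSE)
  }
  if (is.null(origin_mm)) {
    origin_mm <- -(dim(data)[1:3] - 1) / 2 * voxel_mm
  }
  structure(
    list(
      data = data, mask = mask, tr_seconds = tr_seconds,
      subject_id = subject_id, condition_label = condition_label,
      voxel_mm = as.numeric(voxel_mm), origin_mm = as.numeric(origin_mm),
      space_tag = space_tag, standardized = FALSE
    ),
    class = "bold_session"
  )
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bold_session> %s / %s: %dx%dx%d grid, %d frames, TR %.3g s, %d in-mask voxels%s\n",
    x$subject_id, x$condition_label, d[1], d[2], d[3], d[4], x$tr_seconds,
    sum(x$mask), if (isTRUE(x$standardized)) " (standardized)" else ""
  ))
  invisible(x)
}

#' @export
dim.bold_session <- function(x) dim(x$data)

n_frames <- function(session) dim(session$data)[4]

#' Extract the in-mask voxel matrix of a session
#'
#' @param session a [bold_session()].
#' @return A frames x voxels numeric matrix; column `j` is the time
#'   series of the `j`-th in-mask voxel (column-major mask order).
#' @export
voxel_matrix <- function(session) {
  d <- dim(session$data)
  m <- matrix(session$data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[as.vector(session$mask), , drop = FALSE])
}

#' Replace the in-mask voxel data of a session
#'
#' Out-of-mask voxels are zeroed, so every preprocessing stage is
#' mask-respecting by construction.
#'
#' @param session a [bold_session()].
#' @param mat frames x voxels matrix as produced by [voxel_matrix()].
#' @return The session with `data` rebuilt from `mat`.
#' @export
set_voxel_matrix <- function(session, mat) {
  d <- dim(session$data)
  stopifnot(nrow(mat) == d[4], ncol(mat) == sum(session$mask))
  flat <- matrix(0, nrow = prod(d[1:3]), ncol = d[4])
  flat[as.vector(session$mask), ] <- t(mat)
  session$data <- array(flat, dim = d)
  session
}

# mm coordinates of the centers of all in-mask voxels (V x 3)
inmask_coords_mm <- function(session) {
  ijk <- which(session$mask, arr.ind = TRUE)
  sweep(sweep(ijk - 1, 2, session$voxel_mm, `*`), 2, session$origin_mm, `+`)
}

#' Convert a session's frames to a long tibble
#'
#' @param x a [bold_session()].
#' @param ... unused.
#' @return A tibble with columns `subject_id`, `condition_label`,
#'   `frame`, `voxel`, `value` (in-mask voxels only).
#' @export
as_tibble.bold_session <- function(x, ...) {
  vm <- voxel_matrix(x)
  tibble::tibble(
    subject_id = x$subject_id,
    condition_label = x$condition_label,
    frame = rep(seq_len(nrow(vm)), times = ncol(vm)),
    voxel = rep(seq_len(ncol(vm)), each = nrow(vm)),
    value = as.vector(vm)
  )
}
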