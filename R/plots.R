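#' Plot a motion QC report
#'
#' FD and DVARS traces per session with their censoring thresholds;
#' censored frames are marked.
#'
#' @param object a `motion_qc` tibble.
#' @param fd_thresh,dvars_thresh thresholds drawn as reference lines.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.motion_qc <- function(object, fd_thresh = 0.5, dvars_thresh = 0.5,
                               ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("fd", "dvars"),
                              names_to = "metric", values_to = "value")
  thr <- tibble::tibble(metric = c("fd", "dvars"),
                        threshold = c(fd_thresh, dvars_thresh))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::filter(long, !.data$kept),
                        color = "red", size = 0.8) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", color = "grey40") +
    ggplot2::facet_grid(
      metric ~ subject_id + condition_label, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL,
                  title = "Motion QC: FD (mm) and DVARS (% BOLD)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot CAP occupancy
#'
#' @param object a `cap_set`.
#' @param ... unused.
#' @return A ggplot bar chart of frames per CAP.
#' @export
autoplot.cap_set <- function(object, ...) {
  ggplot2::ggplot(tidy.cap_set(object),
                  ggplot2::aes(x = factor(.data$cap), y = .data$occupancy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "CAP", y = "occupancy (frames)",
                  title = paste("CAP occupancy:", object$condition_label)) +
    ggplot2::theme_minimal()
}

#' Plot a contrast result
#'
#' Histogram of the voxelwise t statistics with the significant voxels
#' overlaid, a compact view of where the contrast finds signal.
#'
#' @param object a `contrast_result`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.contrast_result <- function(object, bins = 60, ...) {
  df <- tidy.contrast_result(object)
  df <- df[is.finite(df$t), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, fill = .data$significant)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "t statistic", y = "voxels",
                  fill = paste0("FDR q ≤ ", object$q_threshold),
                  title = "Voxelwise contrast t statistics") +
    ggplot2::theme_minimal()
}

#' Axial slice montage of voxel maps
#'
#' Renders one or more in-mask voxel vectors (CAP maps, t maps, seed
#' correlation maps) as axial slices of the 3D grid.
#'
#' @param maps matrix (maps x voxels) or a single voxel vector, in the
#'   in-mask column order of [voxel_matrix()].
#' @param mask the session's 3D logical mask.
#' @param slices z indices to show; defaults to 4 evenly spaced ones.
#' @param map_names optional facet labels, one per map.
#' @return A ggplot raster montage (maps as rows, slices as columns).
#' @export
plot_voxel_maps <- function(maps, mask, slices = NULL, map_names = NULL) {
  if (is.null(dim(maps))) maps <- matrix(maps, nrow = 1)
  gd <- dim(mask)
  if (is.null(slices)) {
    slices <- unique(round(seq(gd[3] * 0.25, gd[3] * 0.75, length.out = 4)))
  }
  if (is.null(map_names)) map_names <- paste("map", seq_len(nrow(maps)))
  flat_idx <- which(as.vector(mask))
  dfs <- purrr::map_dfr(seq_len(nrow(maps)), function(m) {
    vol <- numeric(prod(gd))
    vol[flat_idx] <- maps[m, ]
    vol <- array(vol, dim = gd)
    purrr::map_dfr(slices, function(zz) {
      vals <- as.vector(vol[, , zz])
      inm <- as.vector(mask[, , zz])
      tibble::tibble(
        map = map_names[m], z = zz,
        x = rep(seq_len(gd[1]), times = gd[2]),
        y = rep(seq_len(gd[2]), each = gd[1]),
        value = vals, in_mask = inm
      )
    })
  })
  dfs$value[!dfs$in_mask] <- NA
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black",
                                  high = "yellow", na.value = "white") +
    ggplot2::facet_grid(map ~ z, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_void()
}
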