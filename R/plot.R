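#' Plot one slice with the detected region overlaid
#'
#' Raster view of a grayscale slice with the segmentation highlighted,
#' the standard per-slice inspection view for judging whether the
#' threshold and seed produced an anatomically sensible boundary.
#'
#' @param object A `sinus_segmentation` (see [segment_sinus()]).
#' @param stack The [grayscale_stack()] that was segmented (needed for
#'   the underlay; omit to show the mask alone).
#' @param slice Slice index; defaults to the seed's slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sinus_segmentation <- function(object, stack = NULL, slice = NULL,
                                        ...) {
  slice <- slice %||% object$params$seed[1]
  m <- get_slice(object$mask, slice)
  df <- tibble(
    row = as.vector(row(m)),
    col = as.vector(col(m)),
    detected = as.vector(m) == 1L,
    intensity = if (is.null(stack)) NA_real_ else as.vector(get_slice(stack, slice))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row))
  if (!is.null(stack)) {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
      ggplot2::scale_fill_gradient(
        low = "black", high = "white", limits = c(0, 255), guide = "none"
      )
  }
  p +
    ggplot2::geom_raster(
      data = dplyr::filter(df, .data$detected),
      fill = "red", alpha = 0.45
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Detected sinus, slice %d", slice),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of pre/post cohort volumes
#'
#' Paired preoperative and postoperative volumes per sample, the
#' standard visual summary of a pre/post surgical series.
#'
#' @param object A [cohort_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_summary <- function(object, ...) {
  s <- object$samples
  if (is.null(s$sample_id)) s$sample_id <- paste("Sample", seq_len(nrow(s)))
  long <- tibble(
    sample_id = rep(s$sample_id, 2),
    phase = rep(c("pre", "post"), each = nrow(s)),
    volume = c(s$v_pre, s$v_post)
  )
  long$phase <- factor(long$phase, levels = c("pre", "post"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$sample_id, y = .data$volume, fill = .data$phase)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(
      x = NULL, y = "Volume", fill = NULL,
      title = "Sinus volume before and after surgery"
    ) +
    ggplot2::theme_minimal()
}
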