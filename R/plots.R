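#' Heatmap of a network matrix
#'
#' @param netmat a `netmat` object.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_netmat <- function(netmat, title = NULL) {
  stopifnot(inherits(netmat, "netmat"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires ggplot2", call. = FALSE)
  V <- netmat$values
  d <- ncol(V)
  df <- data.frame(row = rep(seq_len(d), d), col = rep(seq_len(d), each = d),
                   value = as.numeric(V))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = if (is.null(title))
      sprintf("%s netmat%s", netmat$method,
              if (netmat$fisher) " (Fisher z)" else "") else title,
      x = "component", y = "component", fill = "value") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a spatial inference result
#'
#' Shows the correlation map for one axial slice with significant voxels
#' outlined.
#'
#' @param object a `spatial_inference` object.
#' @param slice z-slice index; defaults to the middle slice.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spatial_inference <- function(object, slice = NULL, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires ggplot2", call. = FALSE)
  grid <- object$grid
  if (is.null(slice)) slice <- ceiling(grid$dims[3] / 2)
  rvol <- unmask_volumes(object$r_map, grid)
  svol <- unmask_volumes(object$sig_mask * 1, grid)
  df <- expand.grid(x = seq_len(grid$dims[1]), y = seq_len(grid$dims[2]))
  df$r <- as.numeric(rvol[, , slice])
  df$sig <- as.numeric(svol[, , slice]) > 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$r)) +
    ggplot2::geom_point(data = df[df$sig, , drop = FALSE], size = 0.8,
                        shape = 4) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("behaviour correlation, slice z = %d (x = FWE p < %.2g)",
                                  slice, object$alpha),
                  fill = "r") +
    ggplot2::theme_minimal()
}
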