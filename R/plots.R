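#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects for the main result types:
#' P(s) curves and derivatives on log axes, insulation tracks, saddle and
#' pileup heatmaps, loop-lines, and intensity distributions.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name hicsig_plots
NULL

#' @rdname hicsig_plots
#' @export
autoplot.ps_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_bp, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic separation s (bp)", y = "contact probability P(s)")
}

#' @rdname hicsig_plots
#' @export
autoplot.derivative_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_bp, y = .data$slope)) +
    ggplot2::geom_line() + ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genomic separation s (bp)",
                  y = "d log10 P / d log10 s")
}

#' @rdname hicsig_plots
#' @export
autoplot.delta_ratio_curve <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !.data$masked),
                  ggplot2::aes(x = .data$s_bp, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genomic separation s (bp)",
                  y = "depleted / intact P(s) difference ratio")
}

#' @rdname hicsig_plots
#' @export
autoplot.insulation_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "position (bp)", y = "insulation score (log2)")
}

#' @rdname hicsig_plots
#' @export
autoplot.loop_line <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_bp, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from loop pixel (bp)", y = "mean O/E")
}

#' @rdname hicsig_plots
#' @export
autoplot.loop_pileup <- function(object, ...) {
  df <- tidy.loop_pileup(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset2_bin, y = .data$offset1_bin,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "anchor 2 offset (bins)", y = "anchor 1 offset (bins)",
                  fill = "O/E")
}

#' @rdname hicsig_plots
#' @export
autoplot.boundary_pileup <- function(object, ...) {
  df <- tidy.boundary_pileup(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset2_bin, y = .data$offset1_bin,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "offset (bins)", y = "offset (bins)", fill = "O/E")
}

#' @rdname hicsig_plots
#' @export
autoplot.saddle_result <- function(object, ...) {
  S <- object$saddle
  df <- tibble::tibble(rank1 = rep(seq_len(nrow(S)), times = ncol(S)),
                       rank2 = rep(seq_len(ncol(S)), each = nrow(S)),
                       value = as.vector(S))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank2, y = .data$rank1,
                                   fill = log2(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "E1 rank bin (B to A)", y = "E1 rank bin (B to A)",
                  fill = "log2 O/E")
}

#' @rdname hicsig_plots
#' @export
autoplot.intensity_table <- function(object, ...) {
  df <- if ("outlier" %in% names(object))
    dplyr::filter(object, !.data$outlier) else object
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$intensity)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "intra-TAD intensity (O/E)")
}

#' @rdname hicsig_plots
#' @export
autoplot.eigen_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$e1)) +
    ggplot2::geom_area(na.rm = TRUE,
                       ggplot2::aes(fill = .data$e1 > 0), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "navy")) +
    ggplot2::labs(x = "position (bp)", y = "E1")
}
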