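# Zahnreihen graphs: tooth position against maturity stage, with runs drawn
# as connecting lines. Functional teeth are triangles, replacement teeth
# circles, matching the conventional presentation of Z-spacing diagrams.

#' Plot a Zahnreihen graph
#'
#' `autoplot()` draws the (position, maturity stage) scatter of a Z-spacing
#' report with one connecting polyline per Zahnreihe; exception points are
#' shown unconnected. `plot_zahnreihen()` additionally writes the figure to
#' a file whose format follows its extension (e.g. `.svg`, `.png`, `.pdf`).
#'
#' @param object,report A `zspacing_report` from [analyze_quadrant()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(analyze_quadrant(load_fixture("v18638_right_maxilla_stages")))
#' @method autoplot zspacing_report
#' @export
autoplot.zspacing_report <- function(object, ...) {
  pts <- object$points
  title <- paste(object$specimen_id, object$element, object$side)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::scale_y_continuous(breaks = 1:7, labels = maturity_ladder,
                                limits = c(1, 7)) +
    ggplot2::scale_x_continuous(
      breaks = if (object$row_length >= 1) seq_len(max(object$row_length, 1)) else NULL,
      limits = c(1, max(object$row_length, 1))
    ) +
    ggplot2::labs(x = "Tooth position (rostral to caudal)",
                  y = "Tooth replacement stage", title = title,
                  shape = NULL) +
    ggplot2::theme_minimal()
  if (nrow(pts) > 0) {
    p <- p +
      ggplot2::geom_line(
        data = dplyr::filter(pts, !is.na(.data$zahnreihe)),
        ggplot2::aes(group = .data$zahnreihe),
        colour = "grey30", linewidth = 0.4
      ) +
      ggplot2::geom_point(
        ggplot2::aes(shape = .data$kind),
        size = 2.5, colour = "black", fill = "grey60"
      ) +
      ggplot2::scale_shape_manual(
        values = c(functional = 17, replacement = 21),
        labels = c(functional = "functional tooth",
                   replacement = "replacement tooth")
      )
  }
  p
}

#' @rdname autoplot.zspacing_report
#' @param path Output file path.
#' @param width,height Figure size in inches.
#' @export
plot_zahnreihen <- function(report, path, width = 7, height = 4) {
  p <- ggplot2::autoplot(report)
  ok <- try(ggplot2::ggsave(path, plot = p, width = width, height = height),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("could not write plot to '", path, "'", call. = FALSE)
  }
  invisible(p)
}
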