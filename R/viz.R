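# Okabe-Ito palette: colour-blind safe, recycled as needed
okabe_ito <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
               "#0072B2", "#D55E00", "#CC79A7", "#999999")

#' Plot appearance options
#'
#' Bundles the tunable appearance settings of [dot_plot()] into one object,
#' mirroring the knobs a bench scientist adjusts when polishing a figure.
#'
#' @param point_size Point diameter (mm). Default 2.
#' @param alpha Point opacity in (0, 1]. Default 0.8.
#' @param gridlines Draw panel gridlines. Default TRUE.
#' @param summary_stat Per-group centre line: `"median"` (default),
#'   `"mean"` or `"none"`.
#' @param error_overlay Per-group spread overlay: `"none"` (default),
#'   `"sd"`, `"sem"`, `"ci95"` or `"iqr"`.
#' @param font_size Base font size (pt). Default 11.
#' @param width,height Figure size in inches for export. Defaults 7 x 5.
#' @param rotate Rotate the panel 90 degrees (horizontal dot plot), which
#'   often improves readability and leaves room for construct cartoons.
#' @param show_reference Include the reference group in the plot. Default TRUE.
#' @param y_scale `"linear"` (default) or `"log10"`.
#' @param jitter_width Horizontal jitter as a fraction of group spacing.
#' @param jitter_seed Seed for the deterministic jitter, so repeated exports
#'   are pixel-identical.
#' @return A `plot_options` list.
#' @export
plot_options <- function(point_size = 2, alpha = 0.8, gridlines = TRUE,
                         summary_stat = c("median", "mean", "none"),
                         error_overlay = c("none", "sd", "sem", "ci95", "iqr"),
                         font_size = 11, width = 7, height = 5,
                         rotate = FALSE, show_reference = TRUE,
                         y_scale = c("linear", "log10"),
                         jitter_width = 0.2, jitter_seed = 42) {
  stopifnot(point_size > 0, alpha > 0, alpha <= 1, font_size > 0,
            width > 0, height > 0, jitter_width >= 0)
  structure(list(point_size = point_size, alpha = alpha, gridlines = gridlines,
                 summary_stat = match.arg(summary_stat),
                 error_overlay = match.arg(error_overlay),
                 font_size = font_size, width = width, height = height,
                 rotate = rotate, show_reference = show_reference,
                 y_scale = match.arg(y_scale),
                 jitter_width = jitter_width, jitter_seed = jitter_seed),
            class = "plot_options")
}

#' Plate heatmap of raw luminescence
#'
#' False-colour overview of one channel across the 96-well plate: rows A--H
#' top to bottom, columns 1--12 left to right, viridis colour map
#' (perceptually uniform). Wells absent from the readings are drawn as empty
#' grey cells, visually distinct from a measured zero.
#'
#' @param readings A [plate_readings()] table.
#' @param channel `"firefly"` or `"renilla"`.
#' @return A ggplot object; its `$data` carries the per-well values.
#' @export
plate_heatmap <- function(readings, channel = c("firefly", "renilla")) {
  channel <- match.arg(channel)
  stopifnot(inherits(readings, "plate_readings"))
  grid <- tibble::tibble(well = plate_wells())
  grid$row <- well_row(grid$well)
  grid$col <- well_col(grid$well)
  grid$value <- readings[[channel]][match(grid$well, readings$well)]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.5) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = channel) +
    ggplot2::scale_x_continuous(breaks = 1:12, position = "top",
                                expand = c(0, 0)) +
    ggplot2::scale_y_discrete(limits = rev(LETTERS[1:8]), expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(channel, " luminescence (",
                                 attr(readings, "plate_id") %||% "plate", ")")) +
    ggplot2::theme_minimal()
}

#' Dot plot of fold change or ratio per condition
#'
#' The package's main figure: every observation drawn as a point (no silent
#' aggregation), grouped by one design factor on the x axis, optionally
#' faceted by further factors, with a per-group summary line. When a
#' reference has been applied the y axis is the fold change with a guide
#' line at 1; otherwise it is the firefly/renilla ratio.
#'
#' @param exp A [tidy_experiment()] with `ratio` (and usually `fold_change`)
#'   computed.
#' @param x Factor name for the x axis.
#' @param facets Character vector of factor names to facet by (one panel per
#'   observed combination).
#' @param options A [plot_options()] object.
#' @return A ggplot object.
#' @export
dot_plot <- function(exp, x, facets = character(), options = plot_options()) {
  stopifnot(inherits(exp, "tidy_experiment"), inherits(options, "plot_options"))
  unknown <- setdiff(c(x, facets), factor_names(exp))
  if (length(unknown)) {
    stop("not a design factor: ", paste(unknown, collapse = ", "),
         " (available: ", paste(factor_names(exp), collapse = ", "), ")",
         call. = FALSE)
  }
  value <- if ("fold_change" %in% names(exp)) "fold_change" else "ratio"
  if (!value %in% names(exp)) exp <- compute_ratios(exp)
  normalized <- value == "fold_change"
  if (!options$show_reference && normalized) {
    keep <- !is_reference_row(exp)
    exp <- restore_experiment(exp[keep, , drop = FALSE], exp)
  }
  if (any(!is.finite(exp[[value]]))) {
    stop("non-finite ", value, " values; clean the data before plotting",
         call. = FALSE)
  }
  df <- tibble::as_tibble(exp)

  ylab <- if (normalized) "Fold Change" else
    if (has_renilla(exp)) "firefly/renilla ratio" else "firefly signal"

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[value]],
                                        colour = .data[[x]]))
  if (normalized) {
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                                 colour = "grey50")
  }
  p <- p + ggplot2::geom_point(
    size = options$point_size, alpha = options$alpha,
    position = ggplot2::position_jitter(width = options$jitter_width,
                                        height = 0,
                                        seed = options$jitter_seed))
  if (options$summary_stat != "none") {
    fun <- if (options$summary_stat == "median") stats::median else mean
    p <- p + ggplot2::stat_summary(fun = fun, geom = "crossbar",
                                   width = 0.5, linewidth = 0.4,
                                   colour = "black")
  }
  if (options$error_overlay != "none") {
    range_fun <- switch(options$error_overlay,
      sd = function(v) { m <- mean(v); s <- stats::sd(v)
        data.frame(y = m, ymin = m - s, ymax = m + s) },
      sem = function(v) { m <- mean(v); s <- stats::sd(v) / sqrt(length(v))
        data.frame(y = m, ymin = m - s, ymax = m + s) },
      ci95 = function(v) { m <- mean(v)
        s <- stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
        data.frame(y = m, ymin = m - s, ymax = m + s) },
      iqr = function(v) { q <- stats::quantile(v, c(0.25, 0.5, 0.75))
        data.frame(y = q[2], ymin = q[1], ymax = q[3]) })
    p <- p + ggplot2::stat_summary(fun.data = range_fun, geom = "errorbar",
                                   width = 0.25, colour = "black")
  }
  if (length(facets)) {
    p <- p + ggplot2::facet_wrap(facets, labeller = ggplot2::label_both)
  }
  p <- p +
    ggplot2::scale_colour_manual(values = rep_len(okabe_ito,
                                                  length(unique(df[[x]]))),
                                 guide = "none") +
    ggplot2::labs(x = x, y = ylab) +
    ggplot2::theme_bw(base_size = options$font_size)
  if (options$y_scale == "log10") p <- p + ggplot2::scale_y_log10()
  if (!options$gridlines) {
    p <- p + ggplot2::theme(panel.grid = ggplot2::element_blank())
  }
  if (options$rotate) p <- p + ggplot2::coord_flip()
  p
}

#' Export a figure to PNG or PDF
#'
#' PNG output honours the requested size and resolution exactly; PDF output
#' is vector graphics, suited to downstream editing.
#'
#' @param figure A ggplot object.
#' @param path Output path.
#' @param format `"png"` or `"pdf"`; `"auto"` follows the file extension.
#' @param dpi Raster resolution for PNG.
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
export_figure <- function(figure, path, format = c("auto", "png", "pdf"),
                          dpi = 300, width = 7, height = 5) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("png", "pdf")) {
      stop("unsupported figure format: '", ext, "' (use png or pdf)",
           call. = FALSE)
    }
    format <- ext
  }
  if (format == "png") {
    dev <- if (requireNamespace("ragg", quietly = TRUE)) {
      function(filename, ...) ragg::agg_png(filename, width = width,
                                            height = height, units = "in",
                                            res = dpi)
    } else "png"
    ggplot2::ggsave(path, figure, device = dev, width = width,
                    height = height, dpi = dpi)
  } else {
    ggplot2::ggsave(path, figure, device = grDevices::pdf, width = width,
                    height = height)
  }
  invisible(path)
}
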