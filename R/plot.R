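#' Plot the series of one measure
#'
#' Spaghetti-style panel per participant (columns by side for bilateral
#' measures): assessment points connected within phase, vertical lines at
#' phase boundaries, a grey band of +/-15% of each phase's median (the
#' stability criterion range), a dashed horizontal line at the baseline
#' median extended across the intervention phase (the PEM reference), a
#' solid horizontal segment at each within-phase mean, and an asterisk at
#' the week of any missed assessment.
#'
#' @param data long tibble.
#' @param measure measure name to plot.
#' @param config gate configuration (band fraction and zero-median
#'   fallback are taken from it).
#' @param file optional output path (written with [ggplot2::ggsave()];
#'   the extension selects the device, e.g. `.svg` or `.png`).
#' @param width,height device size in inches when `file` is given.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_series <- function(data, measure, config = gate_config(), file = NULL,
                        width = 8, height = 10) {
  d <- data[data$measure == measure, , drop = FALSE]
  if (nrow(d) == 0) stop("no data for measure: ", measure, call. = FALSE)
  d$phase <- as_phase(d$phase)

  per_phase <- d |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$participant, .data$side, .data$phase) |>
    dplyr::summarise(med = median(.data$value),
                     level = mean(.data$value),
                     wmin = min(.data$week), wmax = max(.data$week),
                     .groups = "drop") |>
    dplyr::mutate(half = ifelse(.data$med == 0, config$median_epsilon,
                                config$band_fraction * abs(.data$med)))

  pem_line <- per_phase[per_phase$phase == "baseline", ] |>
    dplyr::select("participant", "side", pem_med = "med")
  iv_span <- per_phase[per_phase$phase == "intervention",
                       c("participant", "side", "wmin", "wmax")]
  pem_line <- dplyr::inner_join(pem_line, iv_span, by = c("participant", "side"))

  boundaries <- d |>
    dplyr::group_by(.data$participant, .data$side, .data$phase) |>
    dplyr::summarise(first_week = min(.data$week), .groups = "drop") |>
    dplyr::filter(.data$phase != "baseline")

  missing_pts <- d[is.na(d$value), , drop = FALSE]
  miss_y <- per_phase |>
    dplyr::group_by(.data$participant, .data$side) |>
    dplyr::summarise(y = min(.data$med - .data$half), .groups = "drop")
  missing_pts <- dplyr::left_join(missing_pts, miss_y,
                                  by = c("participant", "side"))

  p <- ggplot2::ggplot(d[!is.na(d$value), ],
                       ggplot2::aes(x = .data$week, y = .data$value)) +
    ggplot2::geom_rect(data = per_phase, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$wmin - 0.4, xmax = .data$wmax + 0.4,
                                    ymin = .data$med - .data$half,
                                    ymax = .data$med + .data$half),
                       fill = "grey80", alpha = 0.6) +
    ggplot2::geom_vline(data = boundaries,
                        ggplot2::aes(xintercept = .data$first_week - 0.5),
                        linetype = "solid", colour = "grey40") +
    ggplot2::geom_segment(data = pem_line, inherit.aes = FALSE,
                          ggplot2::aes(x = .data$wmin - 0.4, xend = .data$wmax + 0.4,
                                       y = .data$pem_med, yend = .data$pem_med),
                          linetype = "dashed") +
    ggplot2::geom_segment(data = per_phase, inherit.aes = FALSE,
                          ggplot2::aes(x = .data$wmin - 0.4, xend = .data$wmax + 0.4,
                                       y = .data$level, yend = .data$level),
                          linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(group = .data$phase)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_grid(participant ~ side) +
    ggplot2::labs(x = "week", y = measure) +
    ggplot2::theme_bw()
  if (nrow(missing_pts) > 0) {
    p <- p + ggplot2::geom_text(data = missing_pts, inherit.aes = FALSE,
                                ggplot2::aes(x = .data$week, y = .data$y),
                                label = "*", size = 5)
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}
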