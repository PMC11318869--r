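#' Plot a voltage trace as a compartment-by-time heat map
#'
#' @param trace an `nd_trace` (or any `[timesteps x N]` voltage matrix).
#' @param t_range optional time range in ms to display.
#' @return a ggplot object.
#' @export
plot_trace <- function(trace, t_range = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trace requires ggplot2")
  v <- if (inherits(trace, "nd_trace")) trace$voltage else as.matrix(trace)
  dt <- if (inherits(trace, "nd_trace")) trace$record_dt else 1
  df <- data.frame(
    time = rep(seq_len(nrow(v)) * dt, ncol(v)),
    compartment = rep(seq_len(ncol(v)), each = nrow(v)),
    voltage = as.numeric(v))
  if (!is.null(t_range))
    df <- df[df$time >= t_range[1] & df$time <= t_range[2], ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$compartment,
                                   fill = .data$voltage)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "V (mV)") +
    ggplot2::labs(x = "time (ms)", y = "compartment") +
    ggplot2::theme_minimal()
}

#' Plot an expert-diversity matrix
#'
#' @param D an `nd_diversity_matrix` (or square numeric matrix).
#' @return a ggplot object.
#' @export
plot_diversity_matrix <- function(D) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_diversity_matrix requires ggplot2")
  D <- unclass(D)
  df <- expand.grid(expert_a = seq_len(nrow(D)), expert_b = seq_len(ncol(D)))
  df$distance <- as.numeric(D)
  ggplot2::ggplot(df, ggplot2::aes(.data$expert_a, .data$expert_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "expert", y = "expert") +
    ggplot2::theme_minimal()
}
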