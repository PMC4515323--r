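#' Plot a simulated trajectory
#'
#' One line per node over time; useful for the single-cell temperature-shift
#' protocol.
#'
#' @param object A `wdm_trajectory` from [simulate_trajectory()].
#' @param nodes Optional subset of node names to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wdm_trajectory
#' @export
autoplot.wdm_trajectory <- function(object, nodes = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "node", values_to = "activity")
  if (!is.null(nodes)) long <- long[long$node %in% nodes, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$activity,
                                     colour = .data$node)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (steps)", y = "activity level", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.wdm_trajectory
#' @method autoplot wdm_trajectory_panel
#' @export
autoplot.wdm_trajectory_panel <- function(object, nodes = NULL, ...) {
  dat <- as_tibble(object)
  if (!is.null(nodes)) dat <- dat[dat$node %in% nodes, , drop = FALSE]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$activity,
                                         colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (steps)", y = "mean activity level", colour = NULL,
                  title = unique(dat$strain)) +
    ggplot2::theme_minimal()
  t0 <- attr(object, "t0")
  if (!is.null(t0)) {
    p <- p + ggplot2::geom_vline(xintercept = t0, linetype = "dashed")
  }
  p
}

#' Plot a predicted expression panel
#'
#' Bar chart of normalized reporter ratios per strain and condition, the
#' model-side counterpart of a reporter-activity figure.
#'
#' @param object A `wdm_panel` from [predict_panel()].
#' @param node Node whose ratio is shown (default `"HSE"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wdm_panel
#' @export
autoplot.wdm_panel <- function(object, node = "HSE", ...) {
  dat <- object[object$node == node, , drop = FALSE]
  dat$strain <- factor(dat$strain, levels = unique(dat$strain))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$strain, y = .data$ratio,
                                    fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = sprintf("%s expression ratio", node),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
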