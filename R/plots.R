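#' Plot a PCoA ordination
#'
#' Scatter of the first two principal coordinates, optionally colored by
#' group.
#'
#' @param object A [pcoa()] result.
#' @param groups Optional group label per sample (in sample order).
#' @param axes Which two axes to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_ord <- function(object, groups = NULL, axes = c(1, 2), ...) {
  pts <- object$points
  ax <- paste0("Axis.", axes)
  if (!all(ax %in% names(pts))) abort("requested axes not available.")
  lab <- sprintf(
    "%s (%.1f%%)", ax,
    100 * object$var_explained[axes]
  )
  df <- pts
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}

#' Forest plot of a serial mediation decomposition
#'
#' Point estimates and percentile bootstrap intervals for the total,
#' direct, and three indirect effects.
#'
#' @param object A [serial_mediation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.serial_mediation <- function(object, ...) {
  df <- object$effects
  df$label <- factor(
    paste0(df$effect, " (", df$pathway, ")"),
    levels = rev(paste0(df$effect, " (", df$pathway, ")"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::labs(
      x = "effect (unstandardized)", y = NULL,
      title = sprintf(
        "Serial mediation decomposition (n = %d, %d bootstrap draws)",
        object$n, object$n_boot
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a BOLD-CSF cross-correlation function
#'
#' Correlation against lag, with the most negative point marked.
#'
#' @param object A [bold_csf_ccf()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coupling_ccf <- function(object, ...) {
  chosen <- attr(object, "chosen_lag")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag (s), positive = CSF follows gBOLD", y = "correlation") +
    ggplot2::theme_minimal()
  if (!is.na(chosen)) {
    p <- p + ggplot2::annotate("point",
      x = chosen,
      y = object$r[object$lag == chosen], colour = "red", size = 3
    )
  }
  p
}
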