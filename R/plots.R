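#' Plot methods
#'
#' ggplot2 views of the main result objects: the StARS instability path
#' with the selected penalty, the NMDS ordination coloured by group, the
#' log-log degree distribution behind the scale-free diagnostic, and
#' per-zone alpha-diversity boxplots.
#'
#' @param object,x Result object.
#' @param groups Optional group label per point (NMDS).
#' @param index Which alpha index to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name climbiome-plots
NULL

#' @rdname climbiome-plots
#' @export
autoplot.stars_path <- function(object, ...) {
  sel <- attr(object, "lambda_selected")
  beta <- attr(object, "beta")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$instability_monotone)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$instability), alpha = 0.6) +
    ggplot2::geom_hline(yintercept = beta, linetype = 2) +
    ggplot2::geom_vline(xintercept = sel, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "penalty (log scale)", y = "edge instability",
                  title = "StARS stability path") +
    ggplot2::theme_minimal()
}

#' @rdname climbiome-plots
#' @export
autoplot.nmds_ordination <- function(object, groups = NULL, ...) {
  df <- object$points
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
  p + ggplot2::labs(title = sprintf("NMDS (stress = %.3f)", object$stress)) +
    ggplot2::theme_minimal()
}

#' @rdname climbiome-plots
#' @export
plot_degree_distribution <- function(x, ...) {
  fit <- scale_free_fit(x)
  ggplot2::ggplot(fit$degree_table,
                  ggplot2::aes(x = .data$degree, y = .data$rel_freq)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "relative frequency",
                  title = sprintf("Degree distribution (R² = %.3f)",
                                  fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname climbiome-plots
#' @export
plot_alpha_diversity <- function(x, index = "shannon", ...) {
  stopifnot(index %in% c("shannon", "simpson", "chao1"),
            "climate_zone" %in% names(x))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$climate_zone,
                                  y = .data[[index]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "climate zone", y = index) +
    ggplot2::theme_minimal()
}
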