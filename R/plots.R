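#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a CAP ordination
#'
#' Scatter of the first two canonical axes, coloured by group.
#'
#' @param object A `mag_cap` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mag_cap <- function(object, ...) {
  sc <- object$scores
  axes <- grep("^LD", names(sc), value = TRUE)
  if (length(axes) == 1) {
    sc$LD2 <- 0
    axes <- c(axes, "LD2")
  }
  ggplot2::ggplot(sc, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      title = sprintf("CAP (m = %d, LOO success %.2f)", object$m,
                      object$loo_success),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot alpha diversities by species and component
#'
#' @param alpha Tidy alpha table with `species`, `component`, `diversity`
#'   (e.g. from [run_study()]).
#' @return A ggplot (boxplots, one facet per component, free scales).
#' @export
plot_alpha_diversity <- function(alpha) {
  ggplot2::ggplot(alpha, ggplot2::aes(.data$species, .data$diversity,
                                      fill = .data$species)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(y = "effective number (q = 1)", x = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot within-individual turnover by species and component
#'
#' @param turnover Tidy turnover table from [turnover_series()] /
#'   [run_study()].
#' @param kind Which turnover kind to plot (default consecutive pairs).
#' @return A ggplot.
#' @export
plot_turnover <- function(turnover, kind = "consecutive") {
  tb <- dplyr::filter(turnover, .data$kind == !!kind)
  ggplot2::ggplot(tb, ggplot2::aes(.data$species, .data$turnover,
                                   fill = .data$species)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(y = "Sorensen-type turnover", x = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot community-weighted mean trajectories with intervals
#'
#' @param trajectories Tibble from [treatment_intervals()] (optionally with
#'   a `species` column for faceting).
#' @param functions Optional subset of function ids to show.
#' @return A ggplot of CWM means with interval error bars over treatments.
#' @export
plot_cwm_trajectories <- function(trajectories, functions = NULL) {
  tb <- trajectories
  if (!is.null(functions)) {
    tb <- dplyr::filter(tb, .data$function_id %in% functions)
  }
  tb <- dplyr::mutate(tb, treatment = stats::reorder(.data$treatment,
                                                     .data$time_index))
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data$treatment, .data$cwm_mean,
                                        group = .data$function_id)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(y = "community-weighted mean capacity", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("species" %in% names(tb)) {
    p + ggplot2::facet_grid(function_id ~ species)
  } else {
    p + ggplot2::facet_wrap(~function_id)
  }
}

#' Plot the diversity-redundancy relationship
#'
#' @param relation Result of [redundancy_diversity_relation()].
#' @return A ggplot of redundancy against log neutral diversity.
#' @export
plot_redundancy_diversity <- function(relation) {
  ggplot2::ggplot(relation$data, ggplot2::aes(.data$log_diversity, .data$rstar)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "log neutral diversity (q = 1)",
                  y = "functional redundancy (Rstar)") +
    ggplot2::theme_minimal()
}
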