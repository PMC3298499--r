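#' Score scatter plot for a fitted decomposition
#'
#' Plots samples on two components, optionally coloured by a label vector
#' (known biological conditions). Works for all fit classes in the package.
#'
#' @param object a fitted decomposition.
#' @param components which two components to show.
#' @param labels optional per-sample grouping.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ipca_fit <- function(object, components = c(1, 2), labels = NULL,
                              ...) {
  plot_scores(object, components, labels)
}

#' @rdname autoplot.ipca_fit
#' @export
autoplot.pca_fit <- function(object, components = c(1, 2), labels = NULL,
                             ...) {
  plot_scores(object, components, labels)
}

#' @rdname autoplot.ipca_fit
#' @export
autoplot.ica_fit <- function(object, components = c(1, 2), labels = NULL,
                             ...) {
  plot_scores(object, components, labels)
}

#' @rdname autoplot.ipca_fit
#' @export
autoplot.spca_fit <- function(object, components = c(1, 2), labels = NULL,
                              ...) {
  plot_scores(object, components, labels)
}

plot_scores <- function(object, components, labels) {
  s <- object$scores[, components, drop = FALSE]
  df <- tibble::tibble(x = s[, 1], y = s[, 2],
                       sample = rownames(s) %||% seq_len(nrow(s)))
  nm <- colnames(s)
  gg <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  } else {
    df$label <- labels
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label))
  }
  gg +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = nm[1], y = nm[2]) +
    ggplot2::theme_minimal()
}

#' Kurtosis drop plot
#'
#' Visualizes the per-component loading kurtosis of an IPCA fit; the
#' "sudden drop" marks how many components carry non-Gaussian structure.
#'
#' @param fit an [ipca_fit()] object.
#' @return a ggplot object.
#' @export
plot_kurtosis <- function(fit) {
  df <- kurtosis_drop(fit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$kurtosis)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = df$component) +
    ggplot2::labs(x = "component", y = "loading kurtosis") +
    ggplot2::theme_minimal()
}

#' Replicate benchmark plot
#'
#' Distribution of a metric across replicates, one panel per component,
#' coloured by method.
#'
#' @param object a [run_replicates()] report (with `keep_replicates = TRUE`).
#' @param metric which metric to plot (`"angle"`, `"kurtosis"`,
#'   `"id_rate"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.replicate_report <- function(object, metric = NULL, ...) {
  if (is.null(object$replicates)) {
    abort("report was run with keep_replicates = FALSE; nothing to plot.")
  }
  metric <- metric %||% object$replicates$metric[1]
  df <- dplyr::filter(object$replicates, .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~ component, labeller = ggplot2::label_both) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_minimal()
}
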