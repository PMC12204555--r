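#' Plot a parameter scan
#'
#' Objective value (or a chosen response) against the scanned value;
#' infeasible grid points are marked along the axis.
#'
#' @param object An `xfba_scan` tibble.
#' @param y Response column to plot (default: the first numeric response
#'   column present among `objective_value`, `community_growth`, `mu1`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xfba_scan <- function(object, y = NULL, ...) {
  xcol <- intersect(c("value", "o2", "exchange", "fraction"),
                    names(object))[1]
  y <- y %||% intersect(c("objective_value", "community_growth", "mu1"),
                        names(object))[1]
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]], y = .data[[y]])) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status), na.rm = TRUE) +
    ggplot2::labs(x = xcol, y = y,
                  title = attr(object, "reaction") %||% "parameter scan") +
    ggplot2::theme_minimal()
}

#' Plot a PCA of flux distributions
#'
#' Score plot of the first two components with explained variance in the
#' axis labels.
#'
#' @param object A `pca_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_result <- function(object, ...) {
  if (isTRUE(object$degenerate)) {
    stop("degenerate PCA (zero variance); nothing to plot", call. = FALSE)
  }
  ev <- object$explained_variance
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * ev[[i]])
  df <- object$scores
  ycol <- if ("PC2" %in% names(df)) "PC2" else "PC1"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data[[ycol]],
                                   label = .data$observation)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(x = lab(1),
                  y = if (ycol == "PC2") lab(2) else lab(1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
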