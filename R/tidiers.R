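#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux solution
#'
#' One row per reaction with its flux; `NA` fluxes for non-optimal
#' statuses.
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return A tibble with `reaction` and `flux`.
#' @export
tidy.flux_solution <- function(x, ...) {
  x$fluxes
}

#' @rdname tidy.flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  out <- tibble::tibble(model = x$model_id, status = x$status,
                        objective = x$objective,
                        objective_value = x$objective_value)
  if (!is.null(x$members)) {
    agg <- stats::setNames(as.list(x$members$value), x$members$quantity)
    out <- dplyr::bind_cols(out, tibble::as_tibble(agg))
  }
  out
}

#' Tidy a PCA of flux distributions
#'
#' @param x A `pca_result` from [pca_flux_comparison()].
#' @param matrix `"scores"`, `"loadings"` or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in the requested view.
#' @export
tidy.pca_result <- function(x, matrix = c("scores", "loadings",
                                          "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (isTRUE(x$degenerate)) {
    stop("degenerate PCA (zero variance); nothing to tidy", call. = FALSE)
  }
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, -"observation",
                                 names_to = "component",
                                 values_to = "score"),
    loadings = tidyr::pivot_longer(x$loadings, -"reaction",
                                   names_to = "component",
                                   values_to = "loading"),
    eigenvalues = tibble::tibble(component = names(x$explained_variance),
                                 explained_variance = x$explained_variance))
}

#' @rdname tidy.pca_result
#' @export
glance.pca_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    return(tibble::tibble(degenerate = TRUE, n_components = 0L,
                          pc1 = NA_real_, pc2 = NA_real_))
  }
  ev <- x$explained_variance
  tibble::tibble(degenerate = FALSE, n_components = sum(ev > 1e-12),
                 pc1 = ev[[1]],
                 pc2 = if (length(ev) > 1) ev[[2]] else NA_real_)
}
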