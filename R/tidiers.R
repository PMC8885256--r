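# broom-style verbs for fitted clusterings.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted clustering: one row per cluster
#'
#' @param x A `wbfc_fit` or `owbfc_fit`.
#' @param ... Unused.
#' @return A tibble with `cluster`, the center coordinates, `size` (hard
#'   assignment count) and `mass` (total membership claimed).
#' @method tidy wbfc_fit
#' @export
tidy.wbfc_fit <- function(x, ...) {
  q <- ncol(x$membership)
  cent <- x$centers
  if (is.null(colnames(cent))) colnames(cent) <- paste0("x", seq_len(ncol(cent)))
  tibble::tibble(
    cluster = seq_len(q),
    size = tabulate(x$labels, nbins = q),
    mass = colSums(x$membership * x$weights)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(cent))
}

#' One-row model summary
#'
#' @param x A `wbfc_fit` or `owbfc_fit`.
#' @param ... Unused.
#' @return A tibble with `objective` (J at the MAP), `sweeps`, `converged`,
#'   `accept_rate` (mean membership acceptance), `clusters` and `blocks`.
#' @method glance wbfc_fit
#' @export
glance.wbfc_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    sweeps = x$sweeps,
    converged = x$converged,
    accept_rate = mean(x$trace$accept_rate),
    clusters = ncol(x$membership),
    blocks = if (!is.null(x$plan)) x$plan$d else 1L
  )
}

#' Augment data with cluster assignments and memberships
#'
#' @param x A `wbfc_fit` or `owbfc_fit`.
#' @param data Optional data frame to augment (defaults to the features the
#'   model was fitted on; must have one row per fitted sample).
#' @param ... Unused.
#' @return `data` as a tibble with `.cluster` (factor hard label) and one
#'   `.u<q>` membership column per cluster.
#' @method augment wbfc_fit
#' @export
augment.wbfc_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) data <- tibble::as_tibble(x$x)
  data <- tibble::as_tibble(data)
  if (nrow(data) != nrow(x$membership)) {
    stop_contract("`data` must have one row per fitted sample.")
  }
  u <- x$membership
  colnames(u) <- paste0(".u", seq_len(ncol(u)))
  dplyr::bind_cols(data,
                   tibble::tibble(.cluster = factor(x$labels)),
                   tibble::as_tibble(u))
}
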