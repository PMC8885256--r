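# User-facing fitters. Data-frame-first: numeric columns are the features,
# everything happens on a matrix internally, results come back as tibbles
# through tidy()/glance()/augment().

#' Weighted Bayesian fuzzy clustering (WBFC)
#'
#' Fits the Bayesian fuzzy clustering model by Metropolis-within-Gibbs MAP
#' inference. With unit weights (the default) this *is* the unweighted BFC
#' model; positive per-sample weights scale each sample's contribution to the
#' likelihood, which is how the online framework treats representative points.
#'
#' Each sweep proposes a new membership row for every sample from a Dirichlet
#' random walk (accepted by a Hastings-corrected Metropolis rule) and redraws
#' every center from its exact Gaussian full conditional. The returned
#' clustering is the best-so-far state under the joint objective `J`
#' ([joint_objective()]); the sampler stops after `n_iter` sweeps or when the
#' relative improvement of `J` over `window` sweeps falls below `tol`.
#'
#' @param data Data frame or numeric matrix; rows are samples, numeric
#'   columns are features (non-numeric columns are ignored).
#' @param clusters Number of clusters N.
#' @param weights Optional positive per-sample weights (`NULL` = unit).
#' @param m Fuzzy index: exponent on memberships in the likelihood
#'   controlling assignment softness. Default 1.7.
#' @param alpha Dirichlet membership prior parameter, scalar or N-vector.
#'   Default 1 (flat prior on the simplex).
#' @param gamma Center-prior strength multiplier. Default 3.
#' @param kappa Membership-proposal concentration. Default 50.
#' @param n_iter Maximum sampler sweeps. Default 200.
#' @param tol Relative-improvement convergence threshold on J. Default 1e-6.
#' @param window Sweeps without sufficient improvement before stopping.
#'   Default 10.
#' @param seed Integer RNG seed; identical seeds and inputs give bit-identical
#'   fits. Default 0.
#' @return An object of class `wbfc_fit` with elements `centers` (N x D),
#'   `membership` (K x N, MAP), `labels` (hard assignments), `objective`
#'   (J at the MAP), `trace` (tibble of per-sweep best J and acceptance
#'   rate), `sweeps`, `converged`, `prior`, `weights`, `params`, `seed` and
#'   the feature matrix `x`.
#' @examples
#' pts <- make_mixture(sizes = c(30, 30, 30), seed = 1)
#' fit <- wbfc(pts, clusters = 3, seed = 1)
#' glance(fit)
#' @seealso [owbfc()] for block-wise online fitting, [tidy.wbfc_fit()],
#'   [augment.wbfc_fit()], [autoplot.wbfc_fit()].
#' @export
wbfc <- function(data, clusters, weights = NULL, m = 1.7, alpha = 1,
                 gamma = 3, kappa = 50, n_iter = 200, tol = 1e-6,
                 window = 10, seed = 0) {
  x <- as_feature_matrix(data)
  with_fit_seed(seed, {
    res <- wbfc_engine(x, clusters, weights, m, alpha, gamma, kappa,
                       n_iter, tol, window)
    new_wbfc_fit(res, x, seed)
  })
}

new_wbfc_fit <- function(res, x, seed, class = character()) {
  colnames(res$centers) <- colnames(x)
  structure(
    list(
      centers = res$centers,
      membership = res$u,
      labels = res$labels,
      objective = res$objective,
      trace = tibble::tibble(
        sweep = seq_along(res$j_trace),
        objective = res$j_trace,
        accept_rate = res$accept_rate
      ),
      per_sample_best = res$per_sample_best,
      per_center_best = res$per_center_best,
      sweeps = res$sweeps,
      converged = res$converged,
      prior = res$prior,
      weights = res$weights,
      params = res$params,
      seed = seed,
      x = x
    ),
    class = c(class, "wbfc_fit")
  )
}

# Seed the one RNG stream for a fit, restoring the caller's RNG state after.
with_fit_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_contract("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @export
print.wbfc_fit <- function(x, ...) {
  cat("<wbfc_fit> K =", nrow(x$membership), " N =", ncol(x$membership),
      " D =", ncol(x$centers), "\n")
  cat("  J =", format(x$objective, digits = 6),
      " sweeps =", x$sweeps,
      " converged =", x$converged, "\n")
  cat("  cluster sizes:", tabulate(x$labels, nbins = ncol(x$membership)), "\n")
  invisible(x)
}

#' Number of clusters / samples of a fit
#' @param fit A `wbfc_fit`.
#' @return Integer.
#' @keywords internal
#' @noRd
n_clusters <- function(fit) ncol(fit$membership)
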