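# Log-domain evaluation of every term of the Bayesian fuzzy clustering (BFC)
# probability model and its per-sample-weighted extension (WBFC).
#
# Model: data likelihood is Gaussian with per-sample-per-cluster isotropic
# precision u_kn^m * I (u_kn = fuzzy membership, m = fuzzy index); membership
# rows carry a Dirichlet(alpha) prior whose awkward normalisation constant
# cancels against the likelihood's; centers carry a Gaussian prior built
# empirically from the data. All constants independent of (U, C) are dropped:
# they cancel in Metropolis ratios and do not move the MAP.

#' Empirical Gaussian prior for cluster centers
#'
#' Builds the center prior from the data itself: the prior mean is the
#' (weighted) sample mean and the prior covariance is `gamma / K` times the
#' (weighted) sum of squared deviations, so `gamma` scales how strongly
#' centers are shrunk toward the data centroid. A small ridge
#' (`1e-8 * max(trace/D, 1) * I`) is always added so the covariance is
#' invertible even for degenerate data (e.g. all rows identical).
#'
#' @param x Numeric matrix or data frame, one row per sample (numeric columns
#'   are used).
#' @param gamma Positive prior-strength multiplier. Default 3.
#' @param weights Optional positive per-sample weights; `NULL` means unit
#'   weights. Weighted sums replace plain sums so representative points can
#'   stand in for the samples they summarise.
#' @return An object of class `owbfc_center_prior`: a list with elements
#'   `mu` (D-vector), `sigma` (D x D covariance, ridge-regularised),
#'   `precision` (its inverse) and `gamma`.
#' @examples
#' center_prior(matrix(c(0, 2), ncol = 1), gamma = 3)
#' @export
center_prior <- function(x, gamma = 3, weights = NULL) {
  x <- as_feature_matrix(x)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop_contract("`gamma` must be a single positive number.")
  }
  k <- nrow(x)
  d <- ncol(x)
  w <- check_weights(weights, k)
  wt <- sum(w)
  mu <- colSums(x * w) / wt
  xc <- sweep(x, 2L, mu)
  sigma <- crossprod(xc * sqrt(w), xc * sqrt(w)) * (gamma / wt)
  sigma <- (sigma + t(sigma)) / 2
  ridge <- 1e-8 * max(sum(diag(sigma)) / d, 1)
  sigma_reg <- sigma + diag(ridge, d)
  structure(
    list(
      mu = mu,
      sigma = sigma_reg,
      sigma_raw = sigma,
      precision = solve(sigma_reg),
      gamma = gamma
    ),
    class = "owbfc_center_prior"
  )
}

#' @export
print.owbfc_center_prior <- function(x, ...) {
  cat("<owbfc_center_prior> D =", length(x$mu), " gamma =", x$gamma, "\n")
  cat("mu:", format(x$mu, digits = 4), "\n")
  invisible(x)
}

#' Log fuzzy data likelihood (unnormalised kernel)
#'
#' Evaluates `-(1/2) * sum_k sum_n w_k * u_kn^m * ||x_k - c_n||^2`, the log of
#' the exponential kernel of the (weighted) fuzzy Gaussian data likelihood.
#' The normalisation constant of the fuzzy likelihood is never evaluated: it
#' cancels exactly against the membership prior.
#'
#' @param x K x D feature matrix.
#' @param u K x N membership matrix; rows on the probability simplex, entries
#'   strictly positive.
#' @param centers N x D center matrix.
#' @param weights Optional positive K-vector of per-sample weights (`NULL` =
#'   unit weights, the unweighted BFC model).
#' @param m Fuzzy index (default 1.7).
#' @return A single number (log kernel; `<= 0` for `m > 0`).
#' @export
log_data_likelihood <- function(x, u, centers, weights = NULL, m = 1.7) {
  x <- as_feature_matrix(x)
  centers <- as_center_matrix(centers, ncol(x))
  u <- check_membership(u, nrow(x), nrow(centers))
  w <- check_weights(weights, nrow(x))
  check_fuzzy_index(m, u)
  d2 <- sq_distances(x, centers)
  -0.5 * sum(w * (u^m) * d2)
}

#' Log Dirichlet membership prior (kernel)
#'
#' Evaluates `sum_k sum_n (alpha_n - 1) * log(u_kn)`, the log of the Dirichlet
#' kernel that survives once the fuzzy likelihood's normaliser and the
#' compensating factors of the membership prior cancel. Constants independent
#' of `u` are dropped.
#'
#' @param u K x N membership matrix (strictly positive rows on the simplex).
#' @param alpha Dirichlet parameter: positive scalar (broadcast across
#'   clusters) or N-vector.
#' @return A single number.
#' @export
log_membership_prior <- function(u, alpha = 1) {
  u <- check_membership(u, nrow(u), ncol(u))
  a <- check_alpha(alpha, ncol(u))
  sum(sweep(log(u), 2L, a - 1, `*`))
}

#' Log Gaussian center prior (kernel)
#'
#' Evaluates `-(1/2) * sum_n (c_n - mu)' Sigma^{-1} (c_n - mu)`, dropping the
#' Gaussian normalising constant. Always non-positive.
#'
#' @param centers N x D center matrix.
#' @param prior An [center_prior()] object (its covariance must be invertible;
#'   regularisation is `center_prior()`'s job, not this function's).
#' @return A single non-positive number.
#' @export
log_center_prior <- function(centers, prior) {
  check_prior(prior)
  centers <- as_center_matrix(centers, length(prior$mu))
  cc <- sweep(centers, 2L, prior$mu)
  -0.5 * sum((cc %*% prior$precision) * cc)
}

#' Joint negative-log-posterior objective J
#'
#' The quantity MAP inference minimises:
#' \deqn{J = \sum_{k,n} w_k u_{kn}^m \|x_k - c_n\|^2
#'       - 2 \sum_{k,n} (\alpha_n - 1)\log u_{kn}
#'       + \sum_n (c_n-\mu_c)^\top \Sigma_c^{-1}(c_n-\mu_c).}
#' Equals `-2 *` the sum of the three log kernels ([log_data_likelihood()],
#' [log_membership_prior()], [log_center_prior()]); lower is better. It is
#' evaluated directly from its definition here, which the test suite exploits
#' as an independent cross-check of the kernel identity.
#'
#' @inheritParams log_data_likelihood
#' @param alpha Dirichlet parameter (scalar or N-vector).
#' @param prior A [center_prior()] object.
#' @return A single number; lower values are better clusterings.
#' @examples
#' x <- matrix(c(0, 2), ncol = 1)
#' pr <- center_prior(x, gamma = 3)
#' joint_objective(x, matrix(1, 2, 1), matrix(1, 1, 1), prior = pr) # 2
#' @export
joint_objective <- function(x, u, centers, weights = NULL, m = 1.7, alpha = 1,
                            prior) {
  x <- as_feature_matrix(x)
  centers <- as_center_matrix(centers, ncol(x))
  u <- check_membership(u, nrow(x), nrow(centers))
  w <- check_weights(weights, nrow(x))
  a <- check_alpha(alpha, nrow(centers))
  check_fuzzy_index(m, u)
  check_prior(prior)
  d2 <- sq_distances(x, centers)
  data_term <- sum(w * (u^m) * d2)
  memb_term <- -2 * sum(sweep(log(u), 2L, a - 1, `*`))
  cc <- sweep(centers, 2L, prior$mu)
  center_term <- sum((cc %*% prior$precision) * cc)
  data_term + memb_term + center_term
}

#' Per-sample log conditional p(x_k, u_k | C)
#'
#' The Metropolis target for one membership row, up to an additive constant:
#' `sum_n [ -(1/2) w_k u_kn^m ||x_k - c_n||^2 + (alpha_n - 1) log u_kn ]`.
#'
#' @param x_k D-vector (one sample).
#' @param u_k N-vector on the simplex, strictly positive.
#' @param centers N x D center matrix.
#' @param w_k Positive sample weight.
#' @param m Fuzzy index.
#' @param alpha Dirichlet parameter (scalar or N-vector).
#' @return A single number.
#' @export
log_sample_conditional <- function(x_k, u_k, centers, w_k = 1, m = 1.7,
                                   alpha = 1) {
  centers <- as_center_matrix(centers, length(x_k))
  u <- check_membership(matrix(u_k, nrow = 1L), 1L, nrow(centers))
  a <- check_alpha(alpha, nrow(centers))
  if (!is.numeric(w_k) || length(w_k) != 1L || !is.finite(w_k) || w_k <= 0) {
    stop_contract("`w_k` must be a single positive number.")
  }
  check_fuzzy_index(m, u)
  d2 <- colSums((t(centers) - as.numeric(x_k))^2)
  sum(-0.5 * w_k * (u[1L, ]^m) * d2 + (a - 1) * log(u[1L, ]))
}

#' Per-center log conditional p(X, c_n | U)
#'
#' The (exactly quadratic) log target for one cluster center, up to an
#' additive constant: the membership-weighted squared distances to `c_n` plus
#' the Gaussian prior penalty. Because it is an exact negative quadratic the
#' full conditional of `c_n` is Gaussian, which [sample_center()] exploits.
#'
#' @param x K x D feature matrix.
#' @param u K x N membership matrix.
#' @param weights Optional positive K-vector (`NULL` = unit).
#' @param c_n D-vector, the candidate center.
#' @param n Cluster index in `1..N`.
#' @param prior A [center_prior()] object.
#' @param m Fuzzy index.
#' @return A single number.
#' @export
log_center_conditional <- function(x, u, weights = NULL, c_n, n, prior,
                                   m = 1.7) {
  x <- as_feature_matrix(x)
  check_prior(prior)
  u <- check_membership(u, nrow(x), ncol(u))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > ncol(u)) {
    stop_contract("`n` must be a cluster index in 1..N.")
  }
  w <- check_weights(weights, nrow(x))
  check_fuzzy_index(m, u)
  c_n <- as.numeric(c_n)
  if (length(c_n) != ncol(x) || !all(is.finite(c_n))) {
    stop_contract("`c_n` must be a finite D-vector.")
  }
  d2 <- colSums((t(x) - c_n)^2)
  dd <- c_n - prior$mu
  -0.5 * sum(w * (u[, n]^m) * d2) - 0.5 * sum(dd * (prior$precision %*% dd))
}

# ---- internal validation / shape helpers ------------------------------------

sq_distances <- function(x, centers) {
  # ||x_k - c_n||^2 for all (k, n), K x N
  xn <- rowSums(x^2)
  cn <- rowSums(centers^2)
  d2 <- outer(xn, cn, `+`) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    # numeric columns are features; dot-prefixed columns (".class", ".cluster",
    # ...) are metadata and never reach the model
    keep <- vapply(x, is.numeric, logical(1L)) & !startsWith(names(x), ".")
    x <- as.matrix(x[keep])
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L) stop_invalid_data("Feature matrix must be at least 1 x 1.")
  if (!all(is.finite(x))) stop_invalid_data("Feature matrix contains non-finite values.")
  x
}

as_center_matrix <- function(centers, d) {
  if (is.data.frame(centers)) centers <- as.matrix(centers)
  if (!is.matrix(centers)) centers <- matrix(centers, ncol = d)
  storage.mode(centers) <- "double"
  if (ncol(centers) != d) {
    stop_contract("Center matrix has ", ncol(centers), " columns; expected ", d, ".")
  }
  if (!all(is.finite(centers))) stop_invalid_data("Center matrix contains non-finite values.")
  centers
}

check_membership <- function(u, k, n) {
  if (is.data.frame(u)) u <- as.matrix(u)
  if (!is.matrix(u)) u <- matrix(u, nrow = k)
  storage.mode(u) <- "double"
  if (nrow(u) != k || ncol(u) != n) {
    stop_contract("Membership matrix is ", nrow(u), " x ", ncol(u),
                  "; expected ", k, " x ", n, ".")
  }
  if (any(!is.finite(u)) || any(u <= 0)) {
    stop_domain("Memberships must be strictly positive (log u must be finite).")
  }
  if (any(abs(rowSums(u) - 1) > 1e-9)) {
    stop_contract("Membership rows must sum to 1 (simplex constraint).")
  }
  u
}

check_weights <- function(weights, k) {
  if (is.null(weights)) return(rep(1, k))
  w <- as.numeric(weights)
  if (length(w) == 1L) w <- rep(w, k)
  if (length(w) != k) stop_contract("`weights` must have length K = ", k, ".")
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop_contract("All weights must be positive and finite.")
  }
  w
}

check_alpha <- function(alpha, n) {
  a <- as.numeric(alpha)
  if (length(a) == 1L) a <- rep(a, n)
  if (length(a) != n) stop_contract("`alpha` must be a scalar or an N-vector.")
  if (any(!is.finite(a)) || any(a <= 0)) stop_contract("All `alpha` must be positive.")
  a
}

check_fuzzy_index <- function(m, u) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m)) {
    stop_contract("`m` must be a single finite number.")
  }
  if (m < 0 && any(u == 0)) {
    stop_domain("u = 0 with negative fuzzy index is undefined.")
  }
  invisible(m)
}

check_prior <- function(prior) {
  if (!inherits(prior, "owbfc_center_prior")) {
    stop_contract("`prior` must be built by center_prior().")
  }
  invisible(prior)
}

stop_contract <- function(...) {
  rlang::abort(paste0(...), class = "owbfc_error_contract")
}

stop_domain <- function(...) {
  rlang::abort(paste0(...), class = "owbfc_error_domain")
}

stop_invalid_data <- function(...) {
  rlang::abort(paste0(...), class = "owbfc_error_data")
}
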