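# Metropolis-within-Gibbs MAP inference for weighted Bayesian fuzzy
# clustering. Membership rows get an asymmetric Dirichlet random-walk
# proposal with a Hastings correction; centers are drawn from their exact
# Gaussian full conditional (a valid Gibbs step, accepted with probability
# one). The reported clustering is the maximum a posteriori state: the
# best-so-far (U, C) by the joint objective J among all states visited.

MEMB_FLOOR <- 1e-12      # keeps log(u) finite after sampling
PROPOSAL_FLOOR <- 0.1    # Dirichlet proposal concentration floor per coord

#' Draw an initial sampler state
#'
#' Membership rows are drawn from `Dirichlet(alpha)`; centers from the
#' Gaussian center prior `N(mu_c, Sigma_c)`. Uses the current RNG stream
#' (seed it with `set.seed()` for reproducibility).
#'
#' @param x K x D feature matrix.
#' @param clusters Number of clusters N.
#' @param alpha Dirichlet parameter (scalar or N-vector).
#' @param prior A [center_prior()] object.
#' @return List with `u` (K x N membership matrix) and `centers` (N x D).
#' @export
init_state <- function(x, clusters, alpha = 1, prior) {
  x <- as_feature_matrix(x)
  check_prior(prior)
  n <- as.integer(clusters)
  if (n < 1L) stop_contract("`clusters` must be >= 1.")
  a <- check_alpha(alpha, n)
  u <- rdirichlet_rows(matrix(a, nrow = nrow(x), ncol = n, byrow = TRUE))
  ch <- chol(prior$sigma)
  z <- matrix(stats::rnorm(n * length(prior$mu)), nrow = n)
  centers <- sweep(z %*% ch, 2L, prior$mu, `+`)
  list(u = u, centers = centers)
}

#' Propose a new membership row
#'
#' Dirichlet random walk on the simplex: the proposal is
#' `Dirichlet(kappa * u_k + 0.1)`, concentrated around the current row with
#' concentration `kappa`. The proposal is asymmetric, so the log Hastings
#' ratio `log q(u | u') - log q(u' | u)` is returned alongside the draw and
#' must enter the acceptance probability.
#'
#' @param u_k Current membership row (strictly positive simplex vector).
#' @param kappa Positive proposal concentration; larger values make smaller
#'   moves. Default 50.
#' @return List with `proposal` (simplex vector) and `log_hastings`.
#' @export
propose_membership <- function(u_k, kappa = 50) {
  u <- check_membership(matrix(u_k, nrow = 1L), 1L, length(u_k))
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop_contract("`kappa` must be a single positive number.")
  }
  res <- propose_membership_rows(u, kappa)
  list(proposal = res$proposal[1L, ], log_hastings = res$log_hastings[[1L]])
}

# Vectorised proposal for all K rows at once. Rows of U are conditionally
# independent given C, so proposing/accepting them jointly elementwise is a
# valid Metropolis-within-Gibbs sweep.
propose_membership_rows <- function(u, kappa) {
  conc_fwd <- kappa * u + PROPOSAL_FLOOR
  prop <- rdirichlet_rows(conc_fwd)
  conc_rev <- kappa * prop + PROPOSAL_FLOOR
  log_hastings <- ddirichlet_rows(u, conc_rev) - ddirichlet_rows(prop, conc_fwd)
  list(proposal = prop, log_hastings = log_hastings)
}

# Independence proposal centred on the conditional's mode. For m > 1 the
# maximiser of -(1/2) w sum_n u_n^m d_n^2 over the simplex is the classic
# fuzzy-c-means membership u_n proportional to d_n^{-2/(m-1)}; proposing
# Dirichlet(kappa * u_mode + 0.1) rows makes large, data-informed jumps that
# a local random walk cannot, which is what lets the chain break the
# symmetric all-centers-at-the-mean state. The proposal density does not
# depend on the current row, so the Hastings ratio is q(current)-q(proposal).
propose_membership_rows_informed <- function(u, d2, m, kappa) {
  expo <- -1 / (m - 1)
  t_raw <- pmax(d2, 1e-12)^expo
  mode_u <- t_raw / rowSums(t_raw)
  conc <- kappa * pmax(mode_u, MEMB_FLOOR) + PROPOSAL_FLOOR
  prop <- rdirichlet_rows(conc)
  log_hastings <- ddirichlet_rows(u, conc) - ddirichlet_rows(prop, conc)
  list(proposal = prop, log_hastings = log_hastings)
}

rdirichlet_rows <- function(conc) {
  g <- matrix(stats::rgamma(length(conc), shape = conc), nrow = nrow(conc))
  u <- g / rowSums(g)
  u <- pmax(u, MEMB_FLOOR)
  u / rowSums(u)
}

# Row-wise Dirichlet log density at `x` with parameter matrix `conc`.
ddirichlet_rows <- function(x, conc) {
  rowSums((conc - 1) * log(x)) + lgamma(rowSums(conc)) - rowSums(lgamma(conc))
}

#' Metropolis accept/reject for a membership row
#'
#' Computes `delta = log p(x_k, u' | C) - log p(x_k, u | C) + log_hastings`
#' and accepts the proposal with probability `min(1, exp(delta))`, consuming
#' one uniform draw from the current RNG stream.
#'
#' @param x_k D-vector (one sample).
#' @param u_current,u_proposed Current and proposed membership rows.
#' @param log_hastings Log Hastings correction from [propose_membership()].
#' @param centers N x D center matrix.
#' @param w_k Positive sample weight.
#' @param m Fuzzy index.
#' @param alpha Dirichlet parameter.
#' @return List with `u` (the row retained), `accepted` (logical) and
#'   `log_conditional` (log target at the retained row).
#' @export
accept_membership <- function(x_k, u_current, u_proposed, log_hastings,
                              centers, w_k = 1, m = 1.7, alpha = 1) {
  lp_cur <- log_sample_conditional(x_k, u_current, centers, w_k, m, alpha)
  lp_new <- log_sample_conditional(x_k, u_proposed, centers, w_k, m, alpha)
  delta <- lp_new - lp_cur + log_hastings
  accepted <- log(stats::runif(1L)) < delta
  if (accepted) {
    list(u = u_proposed, accepted = TRUE, log_conditional = lp_new)
  } else {
    list(u = u_current, accepted = FALSE, log_conditional = lp_cur)
  }
}

#' Closed-form Gaussian full conditional of a center
#'
#' The per-center log target ([log_center_conditional()]) is an exact
#' negative quadratic in `c_n`, so the full conditional is Gaussian with
#' precision `Sigma_c^{-1} + (sum_k w_k u_kn^m) I` and mean
#' `Lambda^{-1} (Sigma_c^{-1} mu_c + sum_k w_k u_kn^m x_k)`.
#'
#' @inheritParams log_center_conditional
#' @return List with `mean` (D-vector), `precision` (D x D) and `covariance`.
#' @export
center_conditional <- function(x, u, weights = NULL, n, prior, m = 1.7) {
  x <- as_feature_matrix(x)
  check_prior(prior)
  u <- check_membership(u, nrow(x), ncol(u))
  w <- check_weights(weights, nrow(x))
  check_fuzzy_index(m, u)
  s <- w * (u[, n]^m)
  lambda <- prior$precision + diag(sum(s), ncol(x))
  b <- as.numeric(prior$precision %*% prior$mu) + colSums(x * s)
  cov <- chol2inv(chol(lambda))
  list(mean = as.numeric(cov %*% b), precision = lambda, covariance = cov)
}

#' Draw a center from its exact Gaussian full conditional
#'
#' Because the proposal is the exact conditional, the Hastings-corrected
#' Metropolis acceptance probability is identically 1 and the draw is always
#' accepted (a plain Gibbs step).
#'
#' @inheritParams center_conditional
#' @return A D-vector.
#' @export
sample_center <- function(x, u, weights = NULL, n, prior, m = 1.7) {
  cond <- center_conditional(x, u, weights, n, prior, m)
  ch <- chol(cond$covariance)
  as.numeric(cond$mean + t(ch) %*% stats::rnorm(length(cond$mean)))
}

#' Hard cluster labels from a membership matrix
#'
#' Argmax over clusters per row; ties break toward the lowest cluster index.
#'
#' @param u K x N membership matrix.
#' @return Integer K-vector of cluster indices in `1..N`.
#' @export
hard_labels <- function(u) {
  if (is.data.frame(u)) u <- as.matrix(u)
  if (!is.matrix(u)) u <- matrix(u, nrow = 1L)
  max.col(u, ties.method = "first")
}

# ---- the sampler engine -----------------------------------------------------

# Runs in the CURRENT RNG stream (callers seed once); all user-facing fitters
# are thin wrappers. Returns the MAP state plus diagnostics.
#
# update_centers = FALSE freezes C (used for the final full-data membership
# pass of the online framework); init supplies warm-start centers.
wbfc_engine <- function(x, clusters, weights = NULL, m = 1.7, alpha = 1,
                        gamma = 3, kappa = 50, n_iter = 200, tol = 1e-6,
                        window = 10, prior = NULL, init_centers = NULL,
                        update_centers = TRUE) {
  x <- as_feature_matrix(x)
  k <- nrow(x)
  n <- as.integer(clusters)
  if (n < 1L) stop_contract("`clusters` must be >= 1.")
  if (n_iter < 1L) stop_contract("`n_iter` must be >= 1.")
  w <- check_weights(weights, k)
  a <- check_alpha(alpha, n)
  if (is.null(prior)) prior <- center_prior(x, gamma = gamma)
  check_prior(prior)

  st <- init_state(x, n, a, prior)
  u <- st$u
  centers <- if (is.null(init_centers)) st$centers else as_center_matrix(init_centers, ncol(x))
  if (!is.null(init_centers) && nrow(centers) != n) {
    stop_contract("`init_centers` must have one row per cluster.")
  }

  a_row <- matrix(a, nrow = k, ncol = n, byrow = TRUE)
  row_conditional <- function(u, d2) {
    rowSums(-0.5 * w * (u^m) * d2 + (a_row - 1) * log(u))
  }
  center_logps <- function(u, centers, d2) {
    cc <- sweep(centers, 2L, prior$mu)
    -0.5 * colSums((u^m) * w * d2) - 0.5 * rowSums((cc %*% prior$precision) * cc)
  }
  objective <- function(u, centers) {
    joint_objective(x, u, centers, w, m, a, prior)
  }

  # MAP (star) state. Membership candidates are screened against C*, center
  # candidates against U*, so every star update lowers the joint objective J
  # at (U*, C*): a stochastic coordinate ascent fed by the chain's proposals,
  # monotone in J by construction. The chain itself keeps exploring the
  # posterior independently of the star state.
  u_star <- u
  c_star <- centers
  d2_star <- sq_distances(x, c_star)
  star_scores <- row_conditional(u_star, d2_star)   # log p(x_k, u*_k | C*)
  per_sample_best <- star_scores
  per_center_best <- center_logps(u_star, c_star, d2_star)
  j_trace <- numeric(0L)
  acc_trace <- numeric(0L)
  converged <- FALSE
  sweeps <- 0L

  screen_membership <- function(cand) {
    sc <- row_conditional(cand, d2_star)
    upd <- sc > star_scores
    if (any(upd)) {
      u_star[upd, ] <<- cand[upd, , drop = FALSE]
      star_scores[upd] <<- sc[upd]
    }
  }

  for (t in seq_len(n_iter)) {
    sweeps <- t
    # membership kernels target the conditional given the star centers, and
    # center draws condition on the star memberships: the chain explores
    # around the MAP ratchet rather than around the fuzzy posterior bulk
    d2 <- d2_star
    if (n > 1L) {
      # two Metropolis kernels per sweep, each in detailed balance with the
      # row conditional: a local Dirichlet random walk, then (for m > 1) an
      # independence proposal at the conditional's fuzzy-c-means mode
      pr <- propose_membership_rows(u, kappa)
      delta <- row_conditional(pr$proposal, d2) - row_conditional(u, d2) +
        pr$log_hastings
      acc <- log(stats::runif(k)) < delta
      u[acc, ] <- pr$proposal[acc, , drop = FALSE]
      acc_trace[t] <- mean(acc)
      screen_membership(pr$proposal)
      if (m > 1) {
        pri <- propose_membership_rows_informed(u, d2, m, kappa)
        delta <- row_conditional(pri$proposal, d2) - row_conditional(u, d2) +
          pri$log_hastings
        acc <- log(stats::runif(k)) < delta
        u[acc, ] <- pri$proposal[acc, , drop = FALSE]
        screen_membership(pri$proposal)
      }
      screen_membership(u)
    } else {
      u[] <- 1
      acc_trace[t] <- 1
      screen_membership(u)
    }

    if (update_centers) {
      s_mat <- w * (u_star^m)                  # K x N
      s_tot <- colSums(s_mat)
      pb <- as.numeric(prior$precision %*% prior$mu)
      for (j in seq_len(n)) {
        lambda <- prior$precision + diag(s_tot[[j]], ncol(x))
        cov <- chol2inv(chol(lambda))
        mean_j <- as.numeric(cov %*% (pb + colSums(x * s_mat[, j])))
        centers[j, ] <- mean_j + as.numeric(t(chol(cov)) %*% stats::rnorm(ncol(x)))
      }

      # screen the fresh center draws against the star memberships
      star_lc_new <- center_logps(u_star, centers, sq_distances(x, centers))
      star_lc_cur <- center_logps(u_star, c_star, d2_star)
      updc <- star_lc_new > star_lc_cur
      if (any(updc)) {
        c_star[updc, ] <- centers[updc, , drop = FALSE]
        d2_star <- sq_distances(x, c_star)
        star_scores <- row_conditional(u_star, d2_star)
      }
      per_center_best <- pmax(per_center_best,
                              center_logps(u_star, c_star, d2_star))
    }
    per_sample_best <- pmax(per_sample_best, star_scores)

    j_trace[t] <- objective(u_star, c_star)

    if (t > window) {
      drop <- (j_trace[t - window] - j_trace[t]) / max(abs(j_trace[t]), 1)
      if (drop < tol) {
        converged <- TRUE
        break
      }
    }
  }

  list(
    u = u_star,
    centers = c_star,
    labels = hard_labels(u_star),
    objective = j_trace[sweeps],
    j_trace = j_trace,
    accept_rate = acc_trace,
    per_sample_best = per_sample_best,
    per_center_best = per_center_best,
    sweeps = sweeps,
    converged = converged,
    prior = prior,
    weights = w,
    params = list(m = m, alpha = a, gamma = gamma, kappa = kappa,
                  n_iter = n_iter, tol = tol, window = window)
  )
}
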