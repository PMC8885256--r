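# Metropolis-within-Gibbs machinery: initialisation, proposals, acceptance,
# center draws and the full WBFC fit.

test_that("initial state is reproducible and Dirichlet-distributed", {
  x <- matrix(rnorm(40), 20, 2)
  pr <- center_prior(x, 3)
  set.seed(5); s1 <- init_state(x, 3, 1, pr)
  set.seed(5); s2 <- init_state(x, 3, 1, pr)
  expect_identical(s1, s2)
  expect_equal(rowSums(s1$u), rep(1, 20), tolerance = 1e-9)
  expect_equal(dim(s1$centers), c(3L, 2L))

  # flat Dirichlet: per-coordinate mean 1/N within 3 standard errors
  big <- matrix(rnorm(2e4), 1e4, 2)
  set.seed(6)
  s <- init_state(big, 4, 1, center_prior(big, 3))
  se <- sqrt(1 / 4 * 3 / 4 / (4 + 1)) / sqrt(1e4)  # Dirichlet(1,1,1,1) variance
  expect_true(all(abs(colMeans(s$u) - 1 / 4) < 3 * se))
})

test_that("single-cluster membership state is the all-ones column", {
  x <- matrix(rnorm(10), 5, 2)
  set.seed(1)
  s <- init_state(x, 1, 1, center_prior(x, 3))
  expect_equal(s$u, matrix(1, 5, 1))
})

test_that("membership proposals stay on the simplex with a correct Hastings term", {
  set.seed(8)
  u <- c(0.2, 0.5, 0.3)
  for (i in 1:200) {
    pm <- propose_membership(u, kappa = 50)
    expect_equal(sum(pm$proposal), 1, tolerance = 1e-12)
    expect_true(all(pm$proposal > 0))
  }
  # Hastings term agrees with an independent full Dirichlet density oracle
  set.seed(9)
  for (i in 1:50) {
    u <- as.numeric(random_membership(1, 3))
    pm <- propose_membership(u, kappa = 30)
    fwd <- oracle_ddirichlet(pm$proposal, 30 * u + 0.1)
    rev <- oracle_ddirichlet(u, 30 * pm$proposal + 0.1)
    expect_equal(pm$log_hastings, rev - fwd, tolerance = 1e-10)
  }
})

test_that("degenerate one-cluster proposal is the identity", {
  pm <- propose_membership(1, kappa = 50)
  expect_equal(pm$proposal, 1)
  expect_equal(pm$log_hastings, 0)
})

test_that("acceptance rule accepts sure improvements and matches Monte-Carlo rates", {
  cc <- matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE)
  x_k <- c(0.1, 0)
  u_good <- c(0.95, 0.05)
  u_bad <- c(0.05, 0.95)
  # proposal identical to current: delta = 0, always accepted
  set.seed(2)
  res <- accept_membership(x_k, u_good, u_good, 0, cc)
  expect_true(res$accepted)
  # overwhelming improvement is always accepted
  set.seed(3)
  res <- accept_membership(x_k, u_bad, u_good, 0, cc)
  expect_true(res$accepted)

  # empirical acceptance rate matches E[min(1, exp(delta))] for a fixed pair
  u_a <- c(0.7, 0.3); u_b <- c(0.55, 0.45)
  lp <- function(u) log_sample_conditional(x_k, u, cc)
  delta <- lp(u_b) - lp(u_a)   # fixed proposal, log_hastings = 0
  p_theory <- min(1, exp(delta))
  set.seed(4)
  acc <- replicate(4000, accept_membership(x_k, u_a, u_b, 0, cc)$accepted)
  se <- sqrt(p_theory * (1 - p_theory) / 4000)
  expect_lt(abs(mean(acc) - p_theory), 3 * se + 1e-12)
})

test_that("center conditional matches the conjugate closed form and its draws", {
  # 1-D toy: x = 2, w * u^m = 1, mu_c = 0, sigma_c = 1 -> mean 1, var 1/2
  x <- matrix(2)
  u <- matrix(1)
  pr <- center_prior(x, 3)
  pr$mu <- 0
  pr$sigma <- matrix(1)
  pr$precision <- matrix(1)
  cond <- center_conditional(x, u, weights = 1, n = 1, prior = pr, m = 1)
  expect_equal(cond$mean, 1, tolerance = 1e-12)
  expect_equal(cond$covariance[1, 1], 0.5, tolerance = 1e-12)

  # cross-check by numeric integration of exp(log_center_conditional)
  f <- Vectorize(function(c1) {
    exp(log_center_conditional(x, u, weights = 1, c_n = c1, n = 1,
                               prior = pr, m = 1))
  })
  z <- integrate(f, -10, 10, rel.tol = 1e-10)$value
  mean_num <- integrate(function(c1) c1 * f(c1), -10, 10, rel.tol = 1e-10)$value / z
  var_num <- integrate(function(c1) c1^2 * f(c1), -10, 10, rel.tol = 1e-10)$value / z -
    mean_num^2
  expect_equal(mean_num, 1, tolerance = 1e-6)
  expect_equal(var_num, 0.5, tolerance = 1e-6)

  # empirical mean of draws within 3 standard errors
  set.seed(10)
  draws <- replicate(20000, sample_center(x, u, weights = 1, n = 1,
                                          prior = pr, m = 1))
  expect_lt(abs(mean(draws) - 1), 3 * sqrt(0.5 / 20000))
})

test_that("with no data influence the center conditional approaches the prior", {
  x <- matrix(c(0, 1), 2, 1)
  pr <- center_prior(x, 3)
  u <- matrix(c(1 - 1e-9, 1e-9, 1 - 1e-9, 1e-9), 2, 2, byrow = TRUE)
  cond <- center_conditional(x, u, n = 2, prior = pr, m = 8)  # u^m ~ 0
  expect_equal(cond$mean, pr$mu, tolerance = 1e-4)
  expect_equal(cond$covariance, pr$sigma, tolerance = 1e-4)
})

test_that("hard labels take the row argmax with ties to the lowest index", {
  expect_equal(hard_labels(matrix(c(0.2, 0.8), 1)), 2L)
  expect_equal(hard_labels(matrix(c(0.5, 0.5), 1)), 1L)
  u <- diag(3)[c(2, 3, 1), ]
  expect_equal(hard_labels(u), c(2L, 3L, 1L))
})

test_that("seeded fits are bit-reproducible", {
  pts <- canonical_mixture(seed = 2)
  f1 <- wbfc(pts, 3, seed = 7, n_iter = 30)
  f2 <- wbfc(pts, 3, seed = 7, n_iter = 30)
  expect_identical(f1$centers, f2$centers)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$trace, f2$trace)
})

test_that("a single-cluster fit shrinks to the prior-weighted mean", {
  set.seed(21)
  x <- matrix(rnorm(60, mean = 5), 30, 2)
  fit <- wbfc(x, 1, seed = 3, n_iter = 50)
  expect_equal(fit$membership, matrix(1, 30, 1))
  # with K = 30 samples the prior pull is tiny: center ~ sample mean
  expect_equal(as.numeric(fit$centers), colMeans(x), tolerance = 0.05)
})

test_that("two well-separated 1-D clumps are recovered", {
  set.seed(31)
  x <- matrix(c(rnorm(40, -5, 0.3), rnorm(40, 5, 0.3)), ncol = 1)
  hits <- 0
  for (s in 1:10) {
    fit <- wbfc(x, 2, seed = s)
    mm <- match_centers(fit$centers, matrix(c(-5, 5), 2, 1))
    if (max(mm$distance) < 0.5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("membership rows remain on the simplex through a full fit", {
  pts <- canonical_mixture(seed = 3)
  fit <- wbfc(pts, 3, seed = 11, n_iter = 40)
  expect_equal(rowSums(fit$membership), rep(1, nrow(pts)), tolerance = 1e-9)
})

test_that("the MAP objective trace is non-increasing", {
  pts <- canonical_mixture(seed = 4)
  for (s in 1:3) {
    fit <- wbfc(pts, 3, seed = s, n_iter = 60)
    expect_true(all(diff(fit$trace$objective) <= 1e-9))
  }
})

test_that("per-sample and per-center best scores never decrease", {
  # engine internals: run twice with different sweep budgets from one seed;
  # the longer run's running maxima must dominate the shorter run's
  pts <- canonical_mixture(seed = 5)
  f_short <- wbfc(pts, 3, seed = 9, n_iter = 15, tol = 0)
  f_long <- wbfc(pts, 3, seed = 9, n_iter = 45, tol = 0)
  expect_true(all(f_long$per_sample_best >= f_short$per_sample_best - 1e-12))
  expect_true(all(f_long$per_center_best >= f_short$per_center_best - 1e-12))
})

test_that("frozen-center membership chain matches the conditional density", {
  # 1 sample, 2 clusters, centers frozen: long-run accepted-u distribution
  # vs the normalized target on a 1-D grid over u1
  d2 <- c(0.4, 2.2)   # squared distances to the two centers
  m <- 1.7
  target <- function(u1) exp(-0.5 * (u1^m * d2[1] + (1 - u1)^m * d2[2]))
  edges <- seq(0, 1, length.out = 21)
  probs <- diff(sapply(edges, function(e) {
    integrate(Vectorize(target), 0, max(e, 1e-12))$value
  }))
  probs <- probs / sum(probs)

  set.seed(12)
  u <- c(0.5, 0.5)
  cc <- matrix(c(0, sqrt(d2[1]) + sqrt(d2[2])), 2, 1)
  cc[1] <- -sqrt(d2[1])  # sample at 0: distances match d2
  cc[2] <- sqrt(d2[2])
  n_sweep <- 30000
  kept <- numeric(n_sweep)
  for (t in seq_len(n_sweep)) {
    pm <- propose_membership(u, kappa = 8)
    res <- accept_membership(0, u, pm$proposal, pm$log_hastings, cc, m = m)
    u <- res$u
    kept[t] <- u[1]
  }
  emp <- tabulate(findInterval(kept, edges, rightmost.closed = TRUE), 20) / n_sweep
  tv <- 0.5 * sum(abs(emp - probs))
  expect_lt(tv, 0.05)
})
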