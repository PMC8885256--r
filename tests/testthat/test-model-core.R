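# The probability model: every log-kernel term, the joint objective and
# their worked-by-hand values.

test_that("center prior reproduces hand-computed mean and covariance", {
  x <- matrix(c(0, 2), ncol = 1)
  pr <- center_prior(x, gamma = 3)
  expect_equal(pr$mu, 1)
  # (3/2) * ((0-1)^2 + (2-1)^2) = 3, before the ridge
  expect_equal(pr$sigma_raw[1, 1], 3)
  expect_equal(pr$sigma[1, 1], 3, tolerance = 1e-6)
  expect_equal(pr$gamma, 3)
})

test_that("degenerate data still yields an invertible prior covariance", {
  x <- matrix(1, nrow = 5, ncol = 2)  # identical rows: zero raw covariance
  pr <- center_prior(x, gamma = 3)
  expect_equal(pr$sigma_raw, matrix(0, 2, 2))
  expect_silent(solve(pr$sigma))
  expect_true(all(eigen(pr$sigma, symmetric = TRUE)$values > 0))
})

test_that("center prior rejects non-finite input", {
  expect_error(center_prior(matrix(c(1, NA), ncol = 1)), class = "owbfc_error_data")
  expect_error(center_prior(matrix(c(1, Inf), ncol = 1)), class = "owbfc_error_data")
})

test_that("log data likelihood matches direct evaluation and is linear in weights", {
  # zero distance
  expect_equal(
    log_data_likelihood(matrix(0), matrix(1), matrix(0), m = 1.7), 0
  )
  # -(1/2) * w * u^m * d^2 = -(1/2) * 2 * 1 * 1 = -1
  expect_equal(
    log_data_likelihood(matrix(1), matrix(1), matrix(0), weights = 2, m = 1.7),
    -1
  )
  set.seed(42)
  x <- matrix(rnorm(12), 4, 3)
  u <- random_membership(4, 2)
  cc <- matrix(rnorm(6), 2, 3)
  w <- runif(4, 0.5, 2)
  expect_equal(
    log_data_likelihood(x, u, cc, weights = 2 * w),
    2 * log_data_likelihood(x, u, cc, weights = w)
  )
})

test_that("membership prior kernel matches direct evaluation", {
  u <- random_membership(5, 3)
  expect_equal(log_membership_prior(u, alpha = 1), 0)  # flat prior
  expect_equal(
    log_membership_prior(matrix(c(0.5, 0.5), 1), alpha = c(2, 2)),
    2 * log(0.5)
  )
  # permutation invariance under simultaneous column permutation
  a <- c(2, 3, 0.5)
  p <- c(3, 1, 2)
  expect_equal(
    log_membership_prior(u[, p], alpha = a[p]),
    log_membership_prior(u, alpha = a)
  )
})

test_that("membership prior rejects non-positive memberships", {
  u <- matrix(c(0, 1), 1)
  expect_error(log_membership_prior(u, 1), class = "owbfc_error_domain")
})

test_that("center prior kernel is a non-positive Mahalanobis form", {
  x <- matrix(c(0, 2), ncol = 1)
  pr <- center_prior(x, gamma = 3)
  expect_equal(log_center_prior(matrix(pr$mu, 1), pr), 0)
  # D = 1, c = mu + 1, sigma = 3 -> -1/6
  expect_equal(log_center_prior(matrix(pr$mu + 1, 1), pr), -1 / 6,
               tolerance = 1e-6)
  set.seed(7)
  for (i in 1:20) {
    cc <- matrix(rnorm(2, sd = 3), 2, 1)
    expect_lte(log_center_prior(cc, pr), 0)
  }
})

test_that("worked joint objective equals 2", {
  x <- matrix(c(0, 2), ncol = 1)
  pr <- center_prior(x, gamma = 3)
  j <- joint_objective(x, matrix(1, 2, 1), matrix(1, 1, 1), prior = pr)
  expect_equal(j, 2)
})

test_that("joint objective is -2 times the sum of the three log kernels", {
  set.seed(11)
  for (i in 1:100) {
    k <- sample(2:8, 1); n <- sample(1:4, 1); d <- sample(1:3, 1)
    x <- matrix(rnorm(k * d, sd = 2), k, d)
    u <- random_membership(k, n)
    cc <- matrix(rnorm(n * d), n, d)
    w <- runif(k, 0.2, 3)
    a <- runif(n, 0.5, 4)
    m <- runif(1, 0.5, 2.5)
    pr <- center_prior(x, gamma = 3)
    lhs <- joint_objective(x, u, cc, w, m, a, pr)
    rhs <- -2 * (log_data_likelihood(x, u, cc, w, m) +
                   log_membership_prior(u, a) +
                   log_center_prior(cc, pr))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("unit weights reduce every weighted term to its unweighted value", {
  set.seed(13)
  x <- matrix(rnorm(20), 10, 2)
  u <- random_membership(10, 3)
  cc <- matrix(rnorm(6), 3, 2)
  pr <- center_prior(x, 3)
  expect_identical(
    log_data_likelihood(x, u, cc, weights = rep(1, 10)),
    log_data_likelihood(x, u, cc)
  )
  expect_identical(
    joint_objective(x, u, cc, weights = rep(1, 10), prior = pr),
    joint_objective(x, u, cc, prior = pr)
  )
})

test_that("joint objective is invariant under simultaneous cluster permutation", {
  set.seed(17)
  x <- matrix(rnorm(24), 8, 3)
  u <- random_membership(8, 4)
  cc <- matrix(rnorm(12), 4, 3)
  a <- c(1, 2, 0.7, 1.5)
  pr <- center_prior(x, 3)
  p <- c(3, 1, 4, 2)
  expect_equal(
    joint_objective(x, u[, p], cc[p, ], alpha = a[p], prior = pr),
    joint_objective(x, u, cc, alpha = a, prior = pr)
  )
})

test_that("sample conditional matches hand values and is monotone in distance", {
  # single cluster: u = 1, value = -(1/2) w d^2
  expect_equal(
    log_sample_conditional(c(0, 0), 1, matrix(c(3, 4), 1), w_k = 2),
    -0.5 * 2 * 25
  )
  # equidistant two-cluster case: -(1/2) * 2 * 0.5^1.7
  expect_equal(
    log_sample_conditional(0, c(0.5, 0.5), matrix(c(-1, 1), 2, 1), m = 1.7),
    -(0.5^1.7),
    tolerance = 1e-12
  )
  vals <- sapply(c(1, 2, 4), function(d) {
    log_sample_conditional(0, c(0.6, 0.4), matrix(c(d, -1), 2, 1))
  })
  expect_true(all(diff(vals) < 0))
})

test_that("center conditional is exactly quadratic in c_n", {
  set.seed(19)
  x <- matrix(rnorm(10), 5, 2)
  u <- random_membership(5, 2)
  pr <- center_prior(x, 3)
  f <- function(c1) log_center_conditional(x, u, c_n = c(c1, 0.3), n = 1,
                                           prior = pr)
  h <- 1e-3
  pts <- seq(-2, 2, length.out = 7)
  second <- sapply(pts, function(p) (f(p + h) - 2 * f(p) + f(p - h)) / h^2)
  expect_equal(max(second) - min(second), 0, tolerance = 1e-4)
})

test_that("shape mismatches raise contract errors", {
  x <- matrix(rnorm(6), 3, 2)
  pr <- center_prior(x, 3)
  expect_error(
    log_data_likelihood(x, random_membership(2, 2), matrix(0, 2, 2)),
    class = "owbfc_error_contract"
  )
  expect_error(
    joint_objective(x, random_membership(3, 2), matrix(0, 2, 2),
                    weights = c(1, 1), prior = pr),
    class = "owbfc_error_contract"
  )
  expect_error(
    log_membership_prior(matrix(c(0.6, 0.6, 0.4, 0.4), 2), alpha = c(1, 1, 1)),
    class = "owbfc_error_contract"
  )
})
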