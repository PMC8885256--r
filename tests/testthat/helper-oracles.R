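# Independent oracles and fixtures shared by the test files.

# Canonical recovery fixture: three well-separated isotropic Gaussian clumps.
# These are make_mixture()'s defaults; spelled out so the tests do not depend
# on the defaults staying in sync silently.
canonical_mixture <- function(seed = 1) {
  make_mixture(
    centers = rbind(c(0, 0), c(3, 0), c(0, 3)),
    spreads = 0.2, sizes = 100, seed = seed
  )
}
canonical_centers <- rbind(c(0, 0), c(3, 0), c(0, 3))

# Full normalized Dirichlet log density (independent of the package's
# unnormalized kernels).
oracle_ddirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Random strictly-positive simplex matrix.
random_membership <- function(k, n) {
  g <- matrix(stats::rgamma(k * n, shape = 1), k, n)
  g <- pmax(g / rowSums(g), 1e-10)
  g / rowSums(g)
}

# ---- brute-force external metrics from raw label vectors --------------------

brute_contingency <- function(truth, estimate) {
  cl <- sort(unique(estimate))
  cs <- sort(unique(truth))
  t(vapply(cl, function(i) {
    vapply(cs, function(j) sum(estimate == i & truth == j), numeric(1))
  }, numeric(length(cs))))
}

brute_accuracy <- function(truth, estimate) {
  tab <- brute_contingency(truth, estimate)
  r <- nrow(tab); c <- ncol(tab)
  if (r < c) tab <- t(tab)
  nr <- nrow(tab); nc <- ncol(tab)
  perms <- gtools_permutations(nr, nc)
  best <- 0
  for (p in seq_len(nrow(perms))) {
    s <- sum(tab[cbind(perms[p, ], seq_len(nc))])
    best <- max(best, s)
  }
  best / sum(tab)
}

# all ordered selections of `take` items from n (plain recursion, small n)
gtools_permutations <- function(n, take) {
  if (take == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- gtools_permutations(n, take - 1L)
    sub <- sub[!apply(sub == i, 1L, any), , drop = FALSE]
    if (nrow(sub) > 0L) out <- rbind(out, cbind(i, sub[, seq_len(take - 1L), drop = FALSE]))
  }
  out
}

brute_purity <- function(truth, estimate) {
  tab <- brute_contingency(truth, estimate)
  sum(apply(tab, 1, max)) / sum(tab)
}

brute_entropy <- function(truth, estimate) {
  tab <- brute_contingency(truth, estimate)
  n <- sum(tab)
  tot <- 0
  for (i in seq_len(nrow(tab))) {
    ni <- sum(tab[i, ])
    h <- 0
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / ni
      if (p > 0) h <- h - p * log(p)
    }
    tot <- tot + ni / n * h
  }
  tot / log(ncol(tab))
}

brute_f_measure <- function(truth, estimate) {
  tab <- brute_contingency(truth, estimate)
  n <- sum(tab)
  tot <- 0
  for (j in seq_len(ncol(tab))) {
    mj <- sum(tab[, j])
    if (mj == 0) next
    fb <- 0
    for (i in seq_len(nrow(tab))) {
      if (tab[i, j] == 0) next
      p <- tab[i, j] / sum(tab[i, ])
      r <- tab[i, j] / mj
      fb <- max(fb, 2 * p * r / (p + r))
    }
    tot <- tot + mj / n * fb
  }
  tot
}
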