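# External clustering validity indices: optimal-assignment accuracy,
# size-weighted normalized cluster entropy, class-weighted best F-measure and
# purity — the quartet conventionally reported together for medical-data
# clustering benchmarks. All four are computed from the cluster-by-class
# contingency table and are invariant under cluster relabelling.

#' Cluster-by-class contingency table
#'
#' Cell (i, j) counts samples placed in cluster i whose true class is j.
#'
#' @param truth Vector of true class labels.
#' @param estimate Vector of predicted cluster labels, same length.
#' @return An object of class `owbfc_contingency`: an integer matrix with
#'   clusters as rows and classes as columns, plus attribute `n`.
#' @examples
#' cluster_contingency(c(1, 2, 1, 2), c(1, 1, 2, 2))
#' @export
cluster_contingency <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop_contract("`truth` and `estimate` must have equal length.")
  }
  if (length(truth) < 1L) stop_contract("Labels must be non-empty.")
  tab <- table(cluster = factor(estimate), class = factor(truth))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(cluster = rownames(tab), class = colnames(tab)))
  structure(m, n = length(truth), class = c("owbfc_contingency", class(m)))
}

as_contingency <- function(truth, estimate = NULL) {
  if (is.null(estimate)) {
    if (!is.matrix(truth)) stop_contract("Supply a contingency matrix or two label vectors.")
    m <- truth
    storage.mode(m) <- "double"
    if (any(m < 0) || any(!is.finite(m)) || sum(m) < 1) {
      stop_contract("Contingency counts must be finite, non-negative and sum to >= 1.")
    }
    m
  } else {
    unclass(cluster_contingency(truth, estimate))
  }
}

#' Clustering accuracy (optimal one-to-one assignment)
#'
#' Fraction of samples correctly classified under the best one-to-one
#' matching of clusters to classes (Hungarian-style optimal assignment,
#' solved exactly by dynamic programming over class subsets). When cluster
#' and class counts differ, unmatched clusters/classes contribute zero.
#'
#' @param truth Contingency matrix (clusters x classes), or a vector of true
#'   labels if `estimate` is given.
#' @param estimate Optional vector of predicted cluster labels.
#' @return Fraction in `[0, 1]`.
#' @examples
#' clustering_accuracy(matrix(c(5, 2, 1, 4), 2)) # 0.75
#' @export
clustering_accuracy <- function(truth, estimate = NULL) {
  tab <- as_contingency(truth, estimate)
  max_assignment(tab) / sum(tab)
}

# Exact maximum-weight one-to-one assignment via bitmask DP over the smaller
# dimension: O(nrow * 2^ncol * ncol). Entries are non-negative so matching
# the whole smaller side is optimal; rows of the larger side may be skipped.
max_assignment <- function(mat) {
  if (nrow(mat) < ncol(mat)) mat <- t(mat)
  nc <- ncol(mat)
  if (nc > 16L) {
    stop_contract("Exact assignment supports at most 16 clusters/classes.")
  }
  nstates <- bitwShiftL(1L, nc)
  f <- rep(-Inf, nstates)
  f[1L] <- 0
  for (i in seq_len(nrow(mat))) {
    g <- f
    for (s in seq_len(nstates) - 1L) {
      if (!is.finite(f[s + 1L])) next
      for (j in seq_len(nc)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) == 0L) {
          v <- f[s + 1L] + mat[i, j]
          if (v > g[bitwOr(s, bit) + 1L]) g[bitwOr(s, bit) + 1L] <- v
        }
      }
    }
    f <- g
  }
  max(f)
}

#' Clustering purity
#'
#' Each cluster votes for its majority class: `sum_i max_j n_ij / n`. Always
#' at least the optimal-assignment accuracy, because the per-cluster maxima
#' ignore the one-to-one constraint.
#'
#' @inheritParams clustering_accuracy
#' @return Fraction in `[0, 1]`.
#' @export
clustering_purity <- function(truth, estimate = NULL) {
  tab <- as_contingency(truth, estimate)
  sum(apply(tab, 1L, max)) / sum(tab)
}

#' Normalized cluster entropy
#'
#' Size-weighted mean entropy of the class distribution within each cluster,
#' normalized by `log(n_classes)` so the value lies in `[0, 1]` (0 = pure
#' clusters, 1 = one cluster with a uniform class mix; lower is better).
#' Requires at least two classes (the normalizer is undefined otherwise).
#'
#' @inheritParams clustering_accuracy
#' @return Value in `[0, 1]`; lower is better.
#' @export
clustering_entropy <- function(truth, estimate = NULL) {
  tab <- as_contingency(truth, estimate)
  if (ncol(tab) < 2L) {
    stop_contract("Entropy needs at least 2 classes (log normalizer undefined).")
  }
  n <- sum(tab)
  ni <- rowSums(tab)
  h <- vapply(seq_len(nrow(tab)), function(i) {
    if (ni[i] == 0) return(0)
    p <- tab[i, ] / ni[i]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1L))
  sum(ni / n * h) / log(ncol(tab))
}

#' Clustering F-measure
#'
#' For each class j, the best harmonic mean of precision
#' (`n_ij / cluster size`) and recall (`n_ij / class size`) over clusters i,
#' averaged with class-size weights: `sum_j (m_j / n) max_i F(i, j)`. Empty
#' classes are skipped; `F(i, j) = 0` when `n_ij = 0`.
#'
#' @inheritParams clustering_accuracy
#' @return Fraction in `[0, 1]`.
#' @export
clustering_f_measure <- function(truth, estimate = NULL) {
  tab <- as_contingency(truth, estimate)
  n <- sum(tab)
  ni <- rowSums(tab)
  mj <- colSums(tab)
  val <- 0
  for (j in seq_len(ncol(tab))) {
    if (mj[j] == 0) next
    f_best <- 0
    for (i in seq_len(nrow(tab))) {
      if (tab[i, j] == 0) next
      p <- tab[i, j] / ni[i]
      r <- tab[i, j] / mj[j]
      f_best <- max(f_best, 2 * p * r / (p + r))
    }
    val <- val + mj[[j]] / n * f_best
  }
  val
}

#' All four external validity indices as a tibble
#'
#' Tidy wrapper computing accuracy, entropy, F-measure and purity in one
#' call, either from two columns of a data frame or from two label vectors.
#'
#' @param data Optional data frame holding the label columns.
#' @param truth True class labels: an unquoted column of `data`, or a vector
#'   when `data` is `NULL`.
#' @param estimate Predicted cluster labels, likewise.
#' @return A tibble with columns `metric` and `value` (four rows). Entropy is
#'   the only index where lower is better.
#' @examples
#' cluster_metrics(truth = c(1, 1, 2, 2), estimate = c(2, 2, 1, 1))
#' @export
cluster_metrics <- function(data = NULL, truth, estimate) {
  if (!is.null(data)) {
    truth <- dplyr::pull(data, {{ truth }})
    estimate <- dplyr::pull(data, {{ estimate }})
  }
  tab <- cluster_contingency(truth, estimate)
  tibble::tibble(
    metric = c("accuracy", "entropy", "f_measure", "purity"),
    value = c(
      clustering_accuracy(unclass(tab)),
      clustering_entropy(unclass(tab)),
      clustering_f_measure(unclass(tab)),
      clustering_purity(unclass(tab))
    )
  )
}
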