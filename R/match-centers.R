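#' Optimally match estimated centers to reference centers
#'
#' Finds the one-to-one pairing of estimated and reference centers that
#' minimises the total Euclidean distance (exact assignment, same dynamic
#' program as [clustering_accuracy()]), e.g. to score recovery of known
#' generative centers irrespective of label switching.
#'
#' @param estimate N x D matrix (or data frame) of estimated centers.
#' @param reference N x D matrix of reference centers.
#' @return A tibble with one row per pair: `estimate` (row index),
#'   `reference` (matched row index) and `distance`.
#' @examples
#' match_centers(rbind(c(3, 0), c(0, 0)), rbind(c(0, 0), c(3, 0)))
#' @export
match_centers <- function(estimate, reference) {
  est <- as_feature_matrix(estimate)
  ref <- as_feature_matrix(reference)
  if (nrow(est) != nrow(ref) || ncol(est) != ncol(ref)) {
    stop_contract("`estimate` and `reference` must have identical shape.")
  }
  dmat <- sqrt(sq_distances(est, ref))
  # minimise cost = maximise (max - cost)
  big <- max(dmat) + 1
  perm <- assignment_permutation(big - dmat)
  tibble::tibble(
    estimate = seq_len(nrow(est)),
    reference = perm,
    distance = dmat[cbind(seq_len(nrow(est)), perm)]
  )
}

# argmax version of max_assignment for square matrices: returns the column
# assigned to each row under the maximum-weight perfect matching.
assignment_permutation <- function(mat) {
  n <- nrow(mat)
  if (n != ncol(mat)) stop_contract("Square matrix required.")
  if (n > 16L) stop_contract("Exact assignment supports at most 16 centers.")
  nstates <- bitwShiftL(1L, n)
  f <- rep(-Inf, nstates)
  choice <- matrix(0L, n, nstates)
  f[1L] <- 0
  # f[s] = best value assigning rows 1..popcount(s) to column subset s
  pop <- vapply(seq_len(nstates) - 1L, bitcount, integer(1L))
  ord <- order(pop)
  for (s in (seq_len(nstates) - 1L)[ord]) {
    if (!is.finite(f[s + 1L])) next
    i <- pop[s + 1L] + 1L
    if (i > n) next
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(s, bit) == 0L) {
        s2 <- bitwOr(s, bit)
        v <- f[s + 1L] + mat[i, j]
        if (v > f[s2 + 1L]) {
          f[s2 + 1L] <- v
          choice[i, s2 + 1L] <- j
        }
      }
    }
  }
  # backtrack
  perm <- integer(n)
  s <- nstates - 1L
  for (i in rev(seq_len(n))) {
    j <- choice[i, s + 1L]
    perm[i] <- j
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  perm
}

bitcount <- function(x) {
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}
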