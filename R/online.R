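# The online block-processing framework (OWBFC): partition the samples into
# blocks, run WBFC on each block (warm-starting each block's centers from the
# previous block's), pool the per-block centers as representative points
# weighted by their total claimed membership mass, cluster the weighted
# representatives into the final Q centers, and finish with one full-data
# membership pass against the frozen final centers.

#' Partition samples into blocks
#'
#' Contiguous split into `d` near-equal blocks (sizes differ by at most one);
#' with `shuffle = TRUE` a permutation from the current RNG stream is applied
#' first, so seed before calling for reproducibility.
#'
#' @param k Sample count K.
#' @param d Block count, `1 <= d <= k`.
#' @param shuffle Permute sample order before splitting? Default `FALSE`.
#' @return An object of class `owbfc_block_plan`: list with `d`, `assignment`
#'   (integer K-vector of block ids) and `block_sizes`.
#' @examples
#' partition_blocks(10, 3)$block_sizes # 4 3 3
#' @export
partition_blocks <- function(k, d, shuffle = FALSE) {
  k <- as.integer(k)
  d <- as.integer(d)
  if (k < 1L) stop_contract("`k` must be >= 1.")
  if (d < 1L || d > k) stop_contract("`d` must satisfy 1 <= d <= K.")
  sizes <- rep(k %/% d, d) + c(rep(1L, k %% d), rep(0L, d - k %% d))
  assignment <- rep(seq_len(d), times = sizes)
  if (shuffle && d > 1L) {
    assignment <- assignment[order(sample.int(k))]
  }
  structure(
    list(d = d, assignment = assignment, block_sizes = sizes),
    class = "owbfc_block_plan"
  )
}

#' @export
print.owbfc_block_plan <- function(x, ...) {
  cat("<owbfc_block_plan> d =", x$d, " sizes:", x$block_sizes, "\n")
  invisible(x)
}

#' Map a block ratio to a block count
#'
#' A split "at a ratio of r" (each block holding a fraction r of the data)
#' corresponds to `d = round(1/r)` blocks; e.g. 25\% gives 4 blocks.
#'
#' @param ratio Block ratio in (0, 1].
#' @return Integer block count.
#' @export
blocks_from_ratio <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1) {
    stop_contract("`ratio` must be in (0, 1].")
  }
  max(1L, as.integer(round(1 / ratio)))
}

#' Representative-point weights of a block
#'
#' The weight of cluster q's representative (its block-level center) is the
#' total membership mass the cluster claimed in the block:
#' `w_q = sum_k u_kq`. Weights of one block always sum to its sample count.
#'
#' @param u_l K_l x Q membership matrix of one block (rows on the simplex).
#' @return Positive Q-vector of weights.
#' @examples
#' block_weights(matrix(0.5, 4, 2)) # 2 2
#' @export
block_weights <- function(u_l) {
  if (is.data.frame(u_l)) u_l <- as.matrix(u_l)
  if (!is.matrix(u_l) || nrow(u_l) < 1L) {
    stop_contract("`u_l` must be a non-empty membership matrix.")
  }
  u_l <- check_membership(u_l, nrow(u_l), ncol(u_l))
  colSums(u_l)
}

#' Online weighted Bayesian fuzzy clustering (OWBFC)
#'
#' Fits WBFC block-wise so data sets that will not fit in memory in one pass
#' can still be clustered: each block is clustered with unit weights (blocks
#' after the first warm-start their centers from the previous block), the
#' `d * Q` per-block centers are pooled as representative points weighted by
#' their claimed membership mass ([block_weights()]), the weighted
#' representatives are clustered into the final `Q` centers, and full-data
#' memberships are obtained by a final membership-only pass with the centers
#' frozen. With `blocks = 1` the fit reduces exactly (bit-for-bit at equal
#' seed) to [wbfc()] on the full data.
#'
#' @inheritParams wbfc
#' @param clusters Number of clusters Q.
#' @param blocks Block count `d`. Default 4 (a 25\% split).
#' @param block_ratio Alternative to `blocks`: fraction of the data per block
#'   (`blocks = round(1 / block_ratio)`).
#' @param shuffle Permute sample order before splitting into contiguous
#'   blocks? Default `FALSE`.
#' @param chain Warm-start each block's centers from the previous block's
#'   fitted centers? Default `TRUE`; `FALSE` fits every block independently
#'   (ablation).
#' @return An object of class `owbfc_fit` (inherits `wbfc_fit`) with the
#'   [wbfc()] elements plus `plan` (the block plan), `representatives`
#'   (tibble of pooled per-block centers with their weights and block of
#'   origin), `block_fits` (list of per-block `wbfc_fit`s) and `chain`.
#' @examples
#' pts <- make_mixture(sizes = c(40, 40, 40), seed = 1)
#' fit <- owbfc(pts, clusters = 3, blocks = 4, seed = 1)
#' tidy(fit)
#' @export
owbfc <- function(data, clusters, blocks = 4, block_ratio = NULL,
                  shuffle = FALSE, chain = TRUE, m = 1.7, alpha = 1,
                  gamma = 3, kappa = 50, n_iter = 200, tol = 1e-6,
                  window = 10, seed = 0) {
  x <- as_feature_matrix(data)
  q <- as.integer(clusters)
  if (!is.null(block_ratio)) blocks <- blocks_from_ratio(block_ratio)
  d <- as.integer(blocks)
  k <- nrow(x)
  if (d > k) stop_contract("`blocks` cannot exceed the sample count.")

  with_fit_seed(seed, {
    if (d == 1L) {
      # exact reduction: identical RNG usage to wbfc() at the same seed
      res <- wbfc_engine(x, q, NULL, m, alpha, gamma, kappa, n_iter, tol, window)
      fit <- new_wbfc_fit(res, x, seed, class = "owbfc_fit")
      fit$plan <- partition_blocks(k, 1L)
      fit$representatives <- NULL
      fit$block_fits <- NULL
      fit$chain <- chain
      return(fit)
    }

    plan <- partition_blocks(k, d, shuffle = shuffle)
    block_fits <- vector("list", d)
    rep_centers <- vector("list", d)
    rep_weights <- vector("list", d)
    prev_centers <- NULL
    for (l in seq_len(d)) {
      xb <- x[plan$assignment == l, , drop = FALSE]
      res <- wbfc_engine(
        xb, q, NULL, m, alpha, gamma, kappa, n_iter, tol, window,
        init_centers = if (chain) prev_centers else NULL
      )
      block_fits[[l]] <- res
      rep_centers[[l]] <- res$centers
      rep_weights[[l]] <- block_weights(res$u)
      prev_centers <- res$centers
    }

    reps <- do.call(rbind, rep_centers)
    w_reps <- unlist(rep_weights, use.names = FALSE)

    # consolidate: weighted WBFC on the pooled representatives; the center
    # prior comes from the (weighted) representative set itself so the full
    # data never needs to be memory-resident at this stage
    rep_prior <- center_prior(reps, gamma = gamma, weights = w_reps)
    final <- wbfc_engine(reps, q, w_reps, m, alpha, gamma, kappa,
                         n_iter, tol, window, prior = rep_prior)

    # full-data memberships against the frozen final centers
    pass <- wbfc_engine(x, q, NULL, m, alpha, gamma, kappa, n_iter, tol,
                        window, init_centers = final$centers,
                        update_centers = FALSE)

    fit <- new_wbfc_fit(pass, x, seed, class = "owbfc_fit")
    fit$centers <- final$centers
    colnames(fit$centers) <- colnames(x)
    fit$plan <- plan
    fit$representatives <- tibble::tibble(
      block = rep(seq_len(d), each = q),
      cluster = rep(seq_len(q), times = d),
      weight = w_reps
    ) |>
      dplyr::bind_cols(tibble::as_tibble(
        `colnames<-`(reps, paste0("dim", seq_len(ncol(reps))))
      ))
    fit$block_fits <- lapply(seq_len(d), function(l) {
      r <- block_fits[[l]]
      list(centers = r$centers, objective = r$objective, sweeps = r$sweeps,
           converged = r$converged, weights = rep_weights[[l]])
    })
    fit$chain <- chain
    fit
  })
}

#' @export
print.owbfc_fit <- function(x, ...) {
  cat("<owbfc_fit> K =", nrow(x$membership), " Q =", ncol(x$membership),
      " blocks =", if (is.null(x$plan)) 1L else x$plan$d, "\n")
  cat("  J =", format(x$objective, digits = 6),
      " sweeps =", x$sweeps, " converged =", x$converged, "\n")
  invisible(x)
}
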