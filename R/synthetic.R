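# Synthetic fixtures that inhabit the model's well-specified regime:
# isotropic Gaussian mixtures (matching the spherical per-cluster precision
# of the fuzzy likelihood) and piecewise-constant phantom images emulating
# grayscale segmentation at desk scale. Generators are pure functions of
# their arguments including the seed.

#' Generate an isotropic Gaussian mixture
#'
#' Draws `sizes[q]` samples from `N(centers[q, ], spreads[q]^2 I)` per
#' cluster and returns them with their generating labels (for evaluation
#' only). The defaults are the package's canonical recovery fixture: three
#' well-separated clusters at (0,0), (3,0), (0,3) with standard deviation
#' 0.2 and 100 samples each.
#'
#' @param centers Q x D matrix of cluster means. Default
#'   `rbind(c(0, 0), c(3, 0), c(0, 3))`.
#' @param spreads Per-cluster isotropic standard deviations (recycled).
#'   Default 0.2.
#' @param sizes Per-cluster sample counts (recycled). Default 100.
#' @param seed Integer RNG seed. Default 0.
#' @return A tibble with feature columns `x1..xD` and an integer `.class`
#'   column giving the generating cluster.
#' @examples
#' pts <- make_mixture(seed = 1)
#' dplyr::count(pts, .class)
#' @export
make_mixture <- function(centers = rbind(c(0, 0), c(3, 0), c(0, 3)),
                         spreads = 0.2, sizes = 100, seed = 0) {
  if (is.data.frame(centers)) centers <- as.matrix(centers)
  if (!is.matrix(centers)) centers <- matrix(centers, ncol = 1L)
  q <- nrow(centers)
  d <- ncol(centers)
  spreads <- rep_len(as.numeric(spreads), q)
  sizes <- rep_len(as.integer(sizes), q)
  if (any(spreads <= 0)) stop_contract("`spreads` must be positive.")
  if (any(sizes < 1L)) stop_contract("`sizes` must be >= 1.")
  with_fit_seed(seed, {
    rows <- lapply(seq_len(q), function(i) {
      z <- matrix(stats::rnorm(sizes[i] * d, sd = spreads[i]), ncol = d)
      sweep(z, 2L, centers[i, ], `+`)
    })
    x <- do.call(rbind, rows)
    colnames(x) <- paste0("x", seq_len(d))
    out <- tibble::as_tibble(x)
    out$.class <- rep(seq_len(q), times = sizes)
    out
  })
}

#' Generate a phantom image with piecewise-constant regions
#'
#' Builds a concentric-ring phantom: pixels are banded by their radial
#' distance from the image center into `length(levels)` equal-width bands,
#' each painted at its grayscale level, plus optional Gaussian noise clipped
#' to `[0, 1]`. Per-pixel region labels are returned for evaluation.
#'
#' @param height,width Image size in pixels. Default 48 x 48.
#' @param levels Grayscale intensities in `[0, 1]`, one per region, at least
#'   two. Default `c(0.2, 0.5, 0.8)`.
#' @param noise_sd Standard deviation of additive Gaussian noise (0 = clean).
#'   Default 0.
#' @param seed Integer RNG seed. Default 0.
#' @return An object of class `owbfc_phantom`: list with `image` and
#'   `labels` (height x width matrices) and `pixels`, a tibble with columns
#'   `row`, `col`, `intensity`, `.region` in row-major pixel order.
#' @examples
#' ph <- make_phantom(noise_sd = 0.05, seed = 1)
#' table(ph$pixels$.region)
#' @export
make_phantom <- function(height = 48, width = 48, levels = c(0.2, 0.5, 0.8),
                         noise_sd = 0, seed = 0) {
  height <- as.integer(height)
  width <- as.integer(width)
  levels <- as.numeric(levels)
  if (height < 2L || width < 2L) stop_contract("Phantom must be at least 2 x 2.")
  if (length(levels) < 2L) stop_contract("At least 2 region levels required.")
  if (any(levels < 0 | levels > 1)) stop_contract("`levels` must lie in [0, 1].")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_contract("`noise_sd` must be >= 0.")
  nr <- length(levels)
  rr <- (seq_len(height) - (height + 1) / 2) / (height / 2)
  cc <- (seq_len(width) - (width + 1) / 2) / (width / 2)
  radius <- sqrt(outer(rr^2, cc^2, `+`))
  bands <- pmin(nr, 1L + floor(radius / (max(radius) * (1 + 1e-12)) * nr))
  labels <- matrix(as.integer(bands), height, width)
  image <- matrix(levels[labels], height, width)
  with_fit_seed(seed, {
    if (noise_sd > 0) {
      image <- image + matrix(stats::rnorm(height * width, sd = noise_sd),
                              height, width)
      image <- pmin(pmax(image, 0), 1)
    }
    pixels <- tibble::tibble(
      row = rep(seq_len(height), each = width),
      col = rep(seq_len(width), times = height),
      intensity = as.numeric(t(image)),
      .region = as.integer(t(labels))
    )
    structure(
      list(image = image, labels = labels, pixels = pixels,
           levels = levels, noise_sd = noise_sd, seed = seed),
      class = "owbfc_phantom"
    )
  })
}

#' @export
print.owbfc_phantom <- function(x, ...) {
  cat("<owbfc_phantom>", nrow(x$image), "x", ncol(x$image),
      " levels:", x$levels, " noise_sd:", x$noise_sd, "\n")
  invisible(x)
}
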