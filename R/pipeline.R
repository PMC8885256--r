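# End-to-end pipeline: read features (table or image), fit OWBFC, write a
# reproducible result bundle. This is what the command-line entry point
# (inst/cli/owbfc) drives.

#' Build a pipeline configuration
#'
#' Collects every knob of a clustering run with the model's default settings
#' (`m = 1.7`, `alpha = 1`, `gamma = 3`). The manifest written by
#' [run_pipeline()] echoes this configuration, so a run is reproducible from
#' its manifest alone.
#'
#' @param input Path to the input CSV table or PNG/TIFF image.
#' @param mode `"tabular"` or `"image"`.
#' @param clusters Number of clusters Q.
#' @param blocks Block count `d` (default 1 = no online splitting).
#' @param block_ratio Optional fraction per block; overrides `blocks` via
#'   `d = round(1 / ratio)`.
#' @param m,alpha,gamma Model hyperparameters.
#' @param kappa,n_iter,tol,window Sampler settings.
#' @param seed Integer RNG seed (default 0).
#' @param label_column Optional label column name (tabular mode; evaluation
#'   only).
#' @param scale Min-max scale each feature column to `[0, 1]` before
#'   clustering? Default `FALSE`.
#' @param chain Warm-start blocks from the previous block's centers?
#' @param out_dir Output directory for the result bundle.
#' @return A list of class `owbfc_config`.
#' @export
pipeline_config <- function(input, mode = c("tabular", "image"), clusters,
                            blocks = 1, block_ratio = NULL, m = 1.7,
                            alpha = 1, gamma = 3, kappa = 50, n_iter = 200,
                            tol = 1e-6, window = 10, seed = 0,
                            label_column = NULL, scale = FALSE, chain = TRUE,
                            out_dir) {
  mode <- match.arg(mode)
  if (!is.null(block_ratio)) blocks <- blocks_from_ratio(block_ratio)
  structure(
    list(input = input, mode = mode, clusters = as.integer(clusters),
         blocks = as.integer(blocks), block_ratio = block_ratio, m = m,
         alpha = alpha, gamma = gamma, kappa = kappa,
         n_iter = as.integer(n_iter), tol = tol, window = as.integer(window),
         seed = as.integer(seed), label_column = label_column, scale = scale,
         chain = chain, out_dir = out_dir),
    class = "owbfc_config"
  )
}

#' Run the full clustering pipeline and write a result bundle
#'
#' Reads the input, fits [owbfc()] (which reduces to [wbfc()] at one block),
#' and writes to `out_dir`: `centers.csv`, `membership.csv`, `labels.csv`,
#' `trace.csv`, `metrics.csv` (when labels were supplied), `labels.png`
#' (image mode), and `manifest.json` echoing the configuration. Per-block
#' progress is logged with [message()].
#'
#' @param config An [pipeline_config()] object (or a list coercible to one).
#' @return Invisibly, a list with the fitted object (`fit`), the output
#'   `paths`, and `metrics` (tibble or `NULL`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!inherits(cfg, "owbfc_config")) {
    cfg <- do.call(pipeline_config, cfg)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  labels_true <- NULL
  shape <- NULL
  if (cfg$mode == "tabular") {
    inp <- read_features(cfg$input, cfg$label_column)
    feats <- inp$features
    labels_true <- inp$labels
  } else {
    feats <- read_grayscale(cfg$input)
    shape <- attr(feats, "shape")
    feats <- feats["intensity"]
  }
  if (isTRUE(cfg$scale)) {
    feats <- dplyr::mutate(feats, dplyr::across(
      dplyr::everything(),
      function(v) if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else v * 0
    ))
  }

  message("owbfc: ", nrow(feats), " samples, ", ncol(feats), " features, Q = ",
          cfg$clusters, ", d = ", cfg$blocks)
  fit <- owbfc(feats, clusters = cfg$clusters, blocks = cfg$blocks,
               chain = cfg$chain, m = cfg$m, alpha = cfg$alpha,
               gamma = cfg$gamma, kappa = cfg$kappa, n_iter = cfg$n_iter,
               tol = cfg$tol, window = cfg$window, seed = cfg$seed)
  if (!is.null(fit$block_fits)) {
    for (l in seq_along(fit$block_fits)) {
      b <- fit$block_fits[[l]]
      message(sprintf("  block %d: sweeps = %d, J = %.4f, converged = %s",
                      l, b$sweeps, b$objective, b$converged))
    }
  }
  message(sprintf("  final: sweeps = %d, J = %.4f, mean acceptance = %.3f",
                  fit$sweeps, fit$objective, mean(fit$trace$accept_rate)))

  paths <- list(
    centers = file.path(cfg$out_dir, "centers.csv"),
    membership = file.path(cfg$out_dir, "membership.csv"),
    labels = file.path(cfg$out_dir, "labels.csv"),
    trace = file.path(cfg$out_dir, "trace.csv"),
    manifest = file.path(cfg$out_dir, "manifest.json")
  )
  readr::write_csv(tidy(fit), paths$centers, progress = FALSE)
  memb <- tibble::as_tibble(
    `colnames<-`(fit$membership, paste0("u", seq_len(ncol(fit$membership))))
  )
  readr::write_csv(memb, paths$membership, progress = FALSE)
  readr::write_csv(tibble::tibble(label = fit$labels), paths$labels, progress = FALSE)
  readr::write_csv(fit$trace, paths$trace, progress = FALSE)

  metrics <- NULL
  truth <- if (cfg$mode == "image") NULL else labels_true
  if (!is.null(truth)) {
    metrics <- cluster_metrics(truth = truth, estimate = fit$labels)
    paths$metrics <- file.path(cfg$out_dir, "metrics.csv")
    readr::write_csv(metrics, paths$metrics, progress = FALSE)
  }
  if (cfg$mode == "image") {
    paths$label_image <- file.path(cfg$out_dir, "labels.png")
    write_label_image(fit$labels, shape, paths$label_image)
  }

  manifest <- unclass(cfg)
  manifest$package_version <- as.character(utils::packageVersion("owbfc"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(list(fit = fit, paths = paths, metrics = metrics))
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over [run_pipeline()] and the fixture
#' generators, used by the `inst/cli/owbfc` script:
#' `owbfc fit --input F --mode tabular --clusters Q --blocks d ...` and
#' `owbfc simulate mixture|phantom --out F ...`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
owbfc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("The CLI requires the 'optparse' package.")
  }
  if (length(args) < 1L || !args[[1L]] %in% c("fit", "simulate")) {
    message("usage: owbfc fit|simulate [options]; see --help of each command")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  rest <- args[-1L]
  status <- tryCatch({
    if (cmd == "fit") cli_fit(rest) else cli_simulate(rest)
    0L
  }, error = function(e) {
    message("owbfc: error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_fit <- function(args) {
  ol <- list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--mode", type = "character", default = "tabular"),
    optparse::make_option("--clusters", type = "integer"),
    optparse::make_option("--blocks", type = "integer", default = 1L),
    optparse::make_option("--block-ratio", type = "double", default = NA,
                          dest = "block_ratio"),
    optparse::make_option("--m", type = "double", default = 1.7),
    optparse::make_option("--alpha", type = "double", default = 1),
    optparse::make_option("--gamma", type = "double", default = 3),
    optparse::make_option("--kappa", type = "double", default = 50),
    optparse::make_option("--n-iter", type = "integer", default = 200L,
                          dest = "n_iter"),
    optparse::make_option("--seed", type = "integer", default = 0L),
    optparse::make_option("--label-column", type = "character", default = NULL,
                          dest = "label_column"),
    optparse::make_option("--scale", action = "store_true", default = FALSE),
    optparse::make_option("--no-chain", action = "store_false", default = TRUE,
                          dest = "chain"),
    optparse::make_option("--out", type = "character", default = "owbfc-out")
  )
  op <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                             args = args)
  cfg <- pipeline_config(
    input = op$input, mode = op$mode, clusters = op$clusters,
    blocks = op$blocks,
    block_ratio = if (is.na(op$block_ratio)) NULL else op$block_ratio,
    m = op$m, alpha = op$alpha, gamma = op$gamma, kappa = op$kappa,
    n_iter = op$n_iter, seed = op$seed, label_column = op$label_column,
    scale = op$scale, chain = op$chain, out_dir = op$out
  )
  run_pipeline(cfg)
}

cli_simulate <- function(args) {
  if (length(args) < 1L || !args[[1L]] %in% c("mixture", "phantom")) {
    stop("simulate needs a kind: mixture or phantom")
  }
  kind <- args[[1L]]
  ol <- list(
    optparse::make_option("--seed", type = "integer", default = 0L),
    optparse::make_option("--noise-sd", type = "double", default = 0,
                          dest = "noise_sd"),
    optparse::make_option("--out", type = "character")
  )
  op <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                             args = args[-1L])
  if (kind == "mixture") {
    pts <- make_mixture(seed = op$seed)
    write_features(pts, op$out)
    message("wrote ", nrow(pts), " samples to ", op$out)
  } else {
    ph <- make_phantom(noise_sd = op$noise_sd, seed = op$seed)
    png::writePNG(ph$image, op$out)
    message("wrote ", nrow(ph$image), "x", ncol(ph$image),
            " phantom to ", op$out)
  }
}
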