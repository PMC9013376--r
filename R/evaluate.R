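# PSNR / SSIM metrics and the baseline-vs-network comparison protocol.
#
# data_range is fixed at 1.0 throughout the pipeline (images are
# normalized to [0, 1] by their own maximum before degradation); it is
# echoed in every report because PSNR is meaningless without it.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB, with `Inf` as the sentinel for
#' identical images.
#'
#' @param ref,test Numeric matrices of equal size.
#' @param data_range Intensity range of the data (default 1).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 8, 8), matrix(0.1, 8, 8)) # MSE 0.01 -> 20 dB
#' @export
psnr <- function(ref, test, data_range = 1) {
  if (!identical(dim(ref), dim(test))) stop("psnr: shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2L
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'valid' weighted local moments via separable filtering (double precision)
filter_valid <- function(x, g) {
  n <- length(g)
  H <- nrow(x); W <- ncol(x)
  oh <- H - n + 1L; ow <- W - n + 1L
  tmp <- matrix(0, oh, W)
  for (d in seq_len(n)) {
    tmp <- tmp + g[d] * x[(d - 1L) + seq_len(oh), , drop = FALSE]
  }
  out <- matrix(0, oh, ow)
  for (d in seq_len(n)) {
    out <- out + g[d] * tmp[, (d - 1L) + seq_len(ow), drop = FALSE]
  }
  out
}

#' Structural similarity index
#'
#' Mean local SSIM over valid window positions, with a Gaussian weighting
#' window (11x11, sigma 1.5 by default) and stabilisation constants
#' `C1 = (K1 * data_range)^2`, `C2 = (K2 * data_range)^2`,
#' `K1 = 0.01`, `K2 = 0.03`.  Symmetric in its two arguments; identical
#' images score exactly 1.
#'
#' @param ref,test Numeric matrices of equal size, at least as large as the
#'   window.
#' @param data_range Intensity range (default 1).
#' @param window_size,window_sigma Gaussian window parameters.
#' @param K1,K2 Stabilisation constants.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(ref, test, data_range = 1, window_size = 11L,
                 window_sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(ref), dim(test))) stop("ssim: shape mismatch")
  if (nrow(ref) < window_size || ncol(ref) < window_size) {
    stop("image smaller than the SSIM window")
  }
  r <- (window_size - 1L) / 2L
  g <- exp(-(-r:r)^2 / (2 * window_sigma^2))
  g <- g / sum(g)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu1 <- filter_valid(ref, g)
  mu2 <- filter_valid(test, g)
  s11 <- filter_valid(ref * ref, g) - mu1^2
  s22 <- filter_valid(test * test, g) - mu2^2
  s12 <- filter_valid(ref * test, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Evaluate reconstructions on a dataset split
#'
#' For every HR/LR pair of the split, computes PSNR and SSIM of the
#' zero-filling baseline and, when a model is given, of the network
#' reconstruction (clamped to `[0, 1]` before metrics) against the HR
#' reference.  Per-image rows are written as `metrics.csv` and aggregate
#' mean +/- sd per method as `summary.yaml` when `out` is given.
#'
#' @param path Dataset directory from [build_dataset()].
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @param model An `srdn_model`, or `NULL` for the baseline only.
#' @param out Optional output directory for `metrics.csv`/`summary.yaml`.
#' @param data_range PSNR/SSIM data range (default 1).
#' @return A `metrics_report`: data frame with columns `id`, `method`
#'   (`zero_fill` or `network`), `psnr`, `ssim`, with the aggregate table
#'   in `attr(, "aggregate")` and the configuration echo in
#'   `attr(, "config")`.
#' @export
evaluate_sr <- function(path, split = "test", model = NULL, out = NULL,
                        data_range = 1) {
  man <- read_manifest(path)
  ids <- vapply(man$items, function(x) x$id, "")
  ids <- ids[vapply(man$items, function(x) x$split, "") == split]
  if (length(ids) == 0L) stop("split '", split, "' is empty")
  rows <- list()
  for (id in ids) {
    pair <- load_pair(path, id)
    target <- dim(pair$hr)
    zf <- zero_fill_sr(pair$lr, target)
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, method = "zero_fill",
      psnr = psnr(pair$hr, clamp01(zf), data_range),
      ssim = ssim(pair$hr, clamp01(zf), data_range))
    if (!is.null(model)) {
      sr <- clamp01(forward(model, pair$lr))
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, method = "network",
        psnr = psnr(pair$hr, sr, data_range),
        ssim = ssim(pair$hr, sr, data_range))
    }
  }
  report <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(report, report$method), function(d) {
    data.frame(method = d$method[1], n = nrow(d),
               psnr_mean = mean(d$psnr), psnr_sd = sd(d$psnr),
               ssim_mean = mean(d$ssim), ssim_sd = sd(d$ssim))
  }))
  rownames(agg) <- NULL
  cfg <- list(data_range = data_range, ssim_window = 11L,
              ssim_sigma = 1.5, split = split,
              model = !is.null(model))
  attr(report, "aggregate") <- agg
  attr(report, "config") <- cfg
  class(report) <- c("metrics_report", "data.frame")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(report), file.path(out, "metrics.csv"),
              row.names = FALSE)
    yaml::write_yaml(c(cfg, list(aggregate = lapply(
      seq_len(nrow(agg)), function(i) as.list(agg[i, ])))),
      file.path(out, "summary.yaml"), precision = 17L)
  }
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  agg <- attr(x, "aggregate")
  cfg <- attr(x, "config")
  cat("<metrics_report> ", nrow(x), " rows, split '", cfg$split,
      "', data_range ", cfg$data_range, "\n", sep = "")
  print.data.frame(agg, row.names = FALSE)
  invisible(x)
}

#' Recompute aggregate metrics from a written metrics.csv
#'
#' @param out Directory containing `metrics.csv`.
#' @return Data frame of per-method mean and sd.
#' @export
read_metrics_aggregate <- function(out) {
  d <- read.csv(file.path(out, "metrics.csv"))
  agg <- do.call(rbind, lapply(split(d, d$method), function(g) {
    data.frame(method = g$method[1], n = nrow(g),
               psnr_mean = mean(g$psnr), psnr_sd = sd(g$psnr),
               ssim_mean = mean(g$ssim), ssim_sd = sd(g$ssim))
  }))
  rownames(agg) <- NULL
  agg
}
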