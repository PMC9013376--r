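# Synthetic brain-like phantoms and paired HR/LR dataset construction.
#
# The generator emulates the piecewise-smooth anatomy of 2-D MR brain
# slices: an outer "skull" ellipse enclosing nested elliptical structures
# of differing intensity, smoothed region boundaries, and a gentle
# low-frequency multiplicative texture.  Intensity-level diversity stands
# in for the T1/T2/FLAIR contrast variety of a real training database; no
# tissue-contrast physics is attempted.

#' Phantom generator configuration
#'
#' @param size Integer pair, image size (default `c(128, 128)`).
#' @param n_inner_ellipses Integer range `(min, max)` of inner structures
#'   per phantom (default `c(3L, 8L)`).
#' @param intensity_levels Range in `[0, 1]` that region intensities are
#'   drawn from (default `c(0.15, 1)`; a positive lower bound keeps the
#'   head interior visibly above background).
#' @param smooth_sigma Gaussian smoothing of region boundaries, in pixels
#'   (default 1; 0 gives a piecewise-constant phantom).
#' @param texture_amp Amplitude of the low-frequency multiplicative texture
#'   (default 0.1; 0 disables texture).
#' @param seed Integer master seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(size = c(128L, 128L),
                           n_inner_ellipses = c(3L, 8L),
                           intensity_levels = c(0.15, 1),
                           smooth_sigma = 1,
                           texture_amp = 0.1,
                           seed = 1L) {
  size <- as.integer(size)
  n_inner_ellipses <- as.integer(n_inner_ellipses)
  stopifnot(length(size) == 2L, all(size >= 8L),
            length(n_inner_ellipses) == 2L, n_inner_ellipses[1] >= 0L,
            n_inner_ellipses[1] <= n_inner_ellipses[2],
            length(intensity_levels) == 2L, intensity_levels[1] >= 0,
            intensity_levels[2] <= 1,
            intensity_levels[1] <= intensity_levels[2],
            smooth_sigma >= 0, texture_amp >= 0)
  structure(list(size = size, n_inner_ellipses = n_inner_ellipses,
                 intensity_levels = intensity_levels,
                 smooth_sigma = smooth_sigma, texture_amp = texture_amp,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  y <- matrix(seq_len(H) - 1, H, W) - cy
  x <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) - cx
  u <- (x * cos(theta) + y * sin(theta)) / a
  v <- (-x * sin(theta) + y * cos(theta)) / b
  u * u + v * v <= 1
}

# separable Gaussian blur with symmetric (reflected) boundary handling
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  blur1 <- function(m) { # along rows, edge-inclusive symmetric padding
    H <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(H), H + 1 - seq_len(r))
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, H, ncol(m))
    for (d in seq_along(g)) {
      out <- out + g[d] * padded[(d - 1) + seq_len(H), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(x))))
}

#' Generate a synthetic brain-like phantom
#'
#' Deterministic given the seed.  The phantom is an outer ellipse (always
#' fully inside the frame) painted with a base intensity, overpainted by a
#' random number of inner ellipses with their own intensities, then
#' boundary-smoothed and modulated by low-frequency texture.  Background is
#' exactly zero outside the head and values lie in `[0, 1]`.
#'
#' @param cfg A [phantom_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return Numeric matrix of size `cfg$size` with values in `[0, 1]`.
#' @examples
#' p <- generate_phantom(phantom_config(), seed = 3)
#' range(p)
#' mean(p > 0) > 0.2
#' @export
generate_phantom <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  H <- cfg$size[1]; W <- cfg$size[2]
  lv <- cfg$intensity_levels
  with_seed(seed, {
    # outer ellipse: generous head that always clears the frame border
    a <- runif(1, 0.34, 0.44) * W
    b <- runif(1, 0.38, 0.47) * H
    cy <- H / 2 + runif(1, -0.015, 0.015) * H
    cx <- W / 2 + runif(1, -0.015, 0.015) * W
    theta <- runif(1, -0.15, 0.15)
    head <- ellipse_mask(H, W, cy, cx, a, b, theta)
    img <- matrix(0, H, W)
    img[head] <- runif(1, max(lv[1], 0.25), lv[2])
    n <- if (cfg$n_inner_ellipses[1] == cfg$n_inner_ellipses[2]) {
      cfg$n_inner_ellipses[1]
    } else {
      sample(cfg$n_inner_ellipses[1]:cfg$n_inner_ellipses[2], 1)
    }
    for (i in seq_len(n)) {
      ia <- runif(1, 0.06, 0.45) * a
      ib <- runif(1, 0.06, 0.45) * b
      # keep the structure comfortably inside the head
      icy <- cy + runif(1, -0.5, 0.5) * (b - ib)
      icx <- cx + runif(1, -0.5, 0.5) * (a - ia)
      m <- ellipse_mask(H, W, icy, icx, ia, ib, runif(1, 0, pi)) & head
      img[m] <- runif(1, lv[1], lv[2])
    }
    if (cfg$texture_amp > 0) {
      field <- gaussian_blur(matrix(rnorm(H * W), H, W), min(H, W) / 16)
      field <- field / max(sd(field), 1e-12)
      img <- img * (1 + cfg$texture_amp * field)
    }
    if (cfg$smooth_sigma > 0) img <- gaussian_blur(img, cfg$smooth_sigma)
  })
  img[!head] <- 0
  pmin(pmax(img, 0), 1)
}

#' Build a paired HR/LR dataset on disk
#'
#' Generates `n` phantoms, normalizes each by its own maximum, degrades it
#' with a per-image noise level `rho` drawn uniformly from
#' `dcfg$noise_rho_range`, and writes `hr/*.npy`, `lr/*.npy` and a
#' `manifest.yaml` recording every seed and rho so any stored LR image is
#' exactly reproducible from its HR image.  The split is assigned at the
#' phantom level, so no image contributes to more than one split.
#'
#' @param n Number of image pairs (>= 1).
#' @param pcfg A [phantom_config()].
#' @param dcfg A [degradation_config()].
#' @param path Output directory (created if missing).
#' @param seed Master seed; fans out per-image via [seed_stream()].
#' @param split Numeric triple of train/val/test fractions summing to 1.
#' @return The manifest, invisibly (a list; also written as YAML).
#' @export
build_dataset <- function(n, pcfg, dcfg, path, seed = 1L,
                          split = c(0.8, 0.1, 0.1)) {
  stopifnot(n >= 1, inherits(pcfg, "phantom_config"),
            inherits(dcfg, "degradation_config"),
            length(split) == 3L, abs(sum(split) - 1) < 1e-8,
            all(split >= 0))
  dir.create(file.path(path, "hr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "lr"), recursive = TRUE, showWarnings = FALSE)
  counts <- diff(c(0, round(cumsum(split) * n)))
  labels <- rep(c("train", "val", "test"), counts)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- seed_stream(seed, "phantom", i)
    ns <- seed_stream(seed, "noise", i)
    rs <- seed_stream(seed, "rho", i)
    rho <- with_seed(rs, runif(1, dcfg$noise_rho_range[1],
                               dcfg$noise_rho_range[2]))
    hr <- normalize_max(generate_phantom(pcfg, seed = ps))
    lr <- degrade(hr, dcfg, rho = rho, seed = ns)
    id <- sprintf("img%05d", i)
    write_npy(hr, file.path(path, "hr", paste0(id, ".npy")))
    write_npy(lr, file.path(path, "lr", paste0(id, ".npy")))
    items[[i]] <- list(id = id, split = labels[i], phantom_seed = ps,
                       noise_seed = ns, rho = rho)
  }
  manifest <- list(
    n = as.integer(n), master_seed = as.integer(seed),
    split = as.numeric(split),
    phantom_config = unclass(pcfg), degradation_config = unclass(dcfg),
    items = items
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"),
                   precision = 17L)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path Dataset directory written by [build_dataset()].
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(file.path(path, "manifest.yaml"))
}

#' Load one HR/LR image pair from a dataset directory
#'
#' @param path Dataset directory.
#' @param id Image id (e.g. `"img00001"`).
#' @return List with elements `hr`, `lr`.
#' @export
load_pair <- function(path, id) {
  list(hr = read_npy(file.path(path, "hr", paste0(id, ".npy"))),
       lr = read_npy(file.path(path, "lr", paste0(id, ".npy"))))
}

#' Extract aligned HR/LR training patches from an image pair
#'
#' Samples `k` high-resolution 32x32 patches at uniformly random even
#' origins (with replacement) and cuts the matching 16x16 low-resolution
#' patch from the full degraded LR image at the halved origin.  LR patches
#' are cut, not re-degraded: degrading a 32x32 patch in its own k-space is
#' a different (periodic-boundary) operator than degrading the full image.
#'
#' @param pair List with `hr` and `lr` matrices (LR half the HR size).
#' @param k Number of patches.
#' @param seed Integer seed.
#' @param hr_patch HR patch side (default 32; LR patch side is half).
#' @return List of length `k`; each element has `hr`, `lr`, and the 0-based
#'   even `origin` (row, col) in the HR image.
#' @export
extract_patches <- function(pair, k, seed = 1L, hr_patch = 32L) {
  hr <- pair$hr; lr <- pair$lr
  check_image(hr); check_image(lr)
  hr_patch <- as.integer(hr_patch)
  if (nrow(hr) < hr_patch || ncol(hr) < hr_patch) {
    stop("HR image smaller than the patch size")
  }
  if (2L * nrow(lr) != nrow(hr) || 2L * ncol(lr) != ncol(hr)) {
    stop("LR image must be exactly half the HR size")
  }
  lp <- hr_patch %/% 2L
  with_seed(seed, {
    r <- 2L * sample.int((nrow(hr) - hr_patch) %/% 2L + 1L, k,
                         replace = TRUE) - 2L
    c <- 2L * sample.int((ncol(hr) - hr_patch) %/% 2L + 1L, k,
                         replace = TRUE) - 2L
  })
  lapply(seq_len(k), function(i) {
    list(hr = hr[r[i] + seq_len(hr_patch), c[i] + seq_len(hr_patch)],
         lr = lr[r[i] / 2L + seq_len(lp), c[i] / 2L + seq_len(lp)],
         origin = c(r[i], c[i]))
  })
}

#' Materialize a patch set from a dataset split
#'
#' Draws `ceiling(total / n_images)` patches from every pair in the split
#' (so the pool slightly exceeds `total` when it does not divide evenly)
#' and truncates to `total`.
#'
#' @param path Dataset directory.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @param total Total number of patch pairs wanted.
#' @param seed Integer seed.
#' @return List of patch pairs as in [extract_patches()].
#' @export
sample_patch_set <- function(path, split, total, seed = 1L) {
  man <- read_manifest(path)
  ids <- vapply(man$items, function(x) x$id, "")
  ids <- ids[vapply(man$items, function(x) x$split, "") == split]
  if (length(ids) == 0L) stop("split '", split, "' is empty")
  per <- ceiling(total / length(ids))
  out <- vector("list", 0L)
  for (i in seq_along(ids)) {
    pair <- load_pair(path, ids[i])
    out <- c(out, extract_patches(pair, per,
                                  seed = seed_stream(seed, "patch", i)))
  }
  out[seq_len(min(total, length(out)))]
}
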