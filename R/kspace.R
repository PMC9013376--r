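# Centered orthonormal Fourier operators and the acquisition-consistent
# degradation model
#
#   y = F_LR^{-1} D F_HR x + n
#
# where F_HR is the centered orthonormal 2-D FFT on the high-resolution
# grid, D keeps the centred low-frequency block of k-space (64x64 from
# 128x128 at the defaults), F_LR^{-1} is the inverse FFT on the
# low-resolution grid, and n is circular complex Gaussian k-space noise.
#
# Conventions (fixed across the package):
#  * DC sits at index floor(N/2) (0-based) in every k-space grid.
#  * Transforms are orthonormal (unitary), so Parseval holds exactly.
#  * Cropping keeps the half-open centred window
#    [N/2 - n/2, N/2 + n/2) per dimension (frequencies -n/2 .. n/2 - 1).
#  * A grid-size rescaling factor sqrt(hw / HW) is applied after cropping
#    (and its inverse after padding) so that a noise-free constant image
#    maps to the same constant at every resolution.

fftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(seq_len(ceiling(h / 2)) + floor(h / 2), seq_len(floor(h / 2))),
    c(seq_len(ceiling(w / 2)) + floor(w / 2), seq_len(floor(w / 2)))]
}

ifftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(seq_len(floor(h / 2)) + ceiling(h / 2), seq_len(ceiling(h / 2))),
    c(seq_len(floor(w / 2)) + ceiling(w / 2), seq_len(ceiling(w / 2)))]
}

#' Centered orthonormal 2-D FFT
#'
#' Maps an image to its centred spatial-frequency (k-space) representation.
#' The DC coefficient sits at 0-based index `(floor(H/2), floor(W/2))` and
#' the transform is unitary, so image and k-space energies agree (Parseval)
#' and [ifft2c()] is its exact inverse.
#'
#' @param img Real or complex matrix, at least 8x8.
#' @return Complex matrix of the same size.
#' @examples
#' k <- fft2c(matrix(0.5, 16, 16))
#' Mod(k[9, 9]) # DC magnitude = 0.5 * 16 under the orthonormal convention
#' @export
fft2c <- function(img) {
  check_image(img)
  k <- fftshift2(fft(ifftshift2(img))) / sqrt(length(img))
  check_image(k, what = "k-space grid")
  k
}

#' Centered orthonormal inverse 2-D FFT
#'
#' Exact inverse of [fft2c()] on the same grid.  The result is complex in
#' general; taking the magnitude is the caller's decision (see
#' [degrade()]).
#'
#' @param k Complex matrix (centred k-space grid).
#' @return Complex matrix of the same size.
#' @export
ifft2c <- function(k) {
  check_image(k, what = "k-space grid")
  fftshift2(fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

# 0-based first index of the centred half-open window of length n inside N
crop_start <- function(N, n) floor(N / 2) - floor(n / 2)

#' Keep the centred low-frequency block of k-space
#'
#' The low-frequency selection operator `D`: returns the `target` centred
#' sub-block, i.e. rows/columns `[N/2 - n/2, N/2 + n/2)` (0-based) for even
#' sizes.  The DC coefficient is preserved bit-exactly.
#'
#' @param k Complex k-space matrix.
#' @param target Integer pair `(h, w)`, each no larger than the source.
#' @return `h x w` complex matrix.
#' @export
central_crop <- function(k, target) {
  check_image(k, min_size = 1L, what = "k-space grid")
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L)) {
    stop("target must be two positive integers")
  }
  if (target[1] > nrow(k) || target[2] > ncol(k)) {
    stop("crop target larger than source grid")
  }
  r0 <- crop_start(nrow(k), target[1])
  c0 <- crop_start(ncol(k), target[2])
  k[r0 + seq_len(target[1]), c0 + seq_len(target[2]), drop = FALSE]
}

#' Embed a k-space grid in a larger zero grid
#'
#' Zero-padding: the source block is placed at the centred position defined
#' by the [central_crop()] convention, all other coefficients are exactly
#' zero, so `central_crop(zero_pad(k, S), dim(k))` is the identity
#' bit-for-bit and padding adds no energy.
#'
#' @param k Complex k-space matrix.
#' @param target Integer pair `(H, W)`, each at least the source size.
#' @return `H x W` complex matrix.
#' @export
zero_pad <- function(k, target) {
  check_image(k, min_size = 1L, what = "k-space grid")
  target <- as.integer(target)
  if (target[1] < nrow(k) || target[2] < ncol(k)) {
    stop("pad target smaller than source grid")
  }
  out <- matrix(0 + 0i, target[1], target[2])
  r0 <- crop_start(target[1], nrow(k))
  c0 <- crop_start(target[2], ncol(k))
  out[r0 + seq_len(nrow(k)), c0 + seq_len(ncol(k))] <- k
  out
}

#' Add circular complex Gaussian noise to a k-space grid
#'
#' Adds independent draws with real and imaginary parts each
#' `N(0, sigma^2 / 2)`, so `E|n|^2 = sigma^2` per coefficient.  This is the
#' thermal-noise model of MR acquisition; after the inverse FFT and the
#' magnitude step it produces the Rician-like image-domain noise
#' characteristic of low-field scans.
#'
#' @param k Complex k-space matrix.
#' @param sigma Noise standard deviation per complex coefficient (>= 0).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Complex matrix of the same size.
#' @export
add_complex_noise <- function(k, sigma, seed) {
  check_image(k, min_size = 1L, what = "k-space grid")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("sigma must be a single non-negative number")
  }
  if (sigma == 0) return(k)
  n <- length(k)
  with_seed(seed, {
    noise <- complex(real = rnorm(n, 0, sigma / sqrt(2)),
                     imaginary = rnorm(n, 0, sigma / sqrt(2)))
  })
  k + matrix(noise, nrow(k), ncol(k))
}

#' Degradation configuration
#'
#' Describes the acquisition-consistent high-to-low resolution degradation:
#' the retained k-space block size, the per-image relative noise level
#' range, and whether the low-resolution image is the complex magnitude of
#' the inverse FFT (how MR images are displayed) or kept complex.
#'
#' The noise is parameterised relative to signal strength:
#' `sigma = rho * RMS(|cropped k-space coefficients|)` with `rho` drawn
#' uniformly from `noise_rho_range` once per image.  The default range
#' (0.02, 0.20) stands in for the unrecorded noise levels of practical
#' low-field acquisitions and is a configuration field, not a constant.
#'
#' @param lr_size Integer pair, low-resolution grid (default `c(64, 64)`).
#' @param hr_size Integer pair, high-resolution grid (default `c(128, 128)`).
#' @param noise_rho_range Numeric pair `(rho_min, rho_max)`,
#'   `0 <= rho_min <= rho_max`.
#' @param magnitude_output Take the complex magnitude after the inverse FFT
#'   (default `TRUE`).
#' @param seed Integer master seed for noise draws.
#' @return An object of class `degradation_config`.
#' @export
degradation_config <- function(lr_size = c(64L, 64L),
                               hr_size = c(128L, 128L),
                               noise_rho_range = c(0.02, 0.20),
                               magnitude_output = TRUE,
                               seed = 1L) {
  lr_size <- as.integer(lr_size); hr_size <- as.integer(hr_size)
  stopifnot(length(lr_size) == 2L, length(hr_size) == 2L,
            all(lr_size >= 1L), all(lr_size <= hr_size),
            length(noise_rho_range) == 2L,
            noise_rho_range[1] >= 0,
            noise_rho_range[1] <= noise_rho_range[2],
            is.logical(magnitude_output))
  structure(list(lr_size = lr_size, hr_size = hr_size,
                 noise_rho_range = noise_rho_range,
                 magnitude_output = isTRUE(magnitude_output),
                 seed = as.integer(seed)),
            class = "degradation_config")
}

# shared core: crop + optional noise + rescale + inverse FFT
kspace_downsample <- function(hr, lr_size, rho = 0, seed = 1L,
                              magnitude = TRUE) {
  k <- central_crop(fft2c(hr), lr_size)
  if (rho > 0) {
    sigma <- rho * sqrt(mean(Mod(k)^2))
    k <- add_complex_noise(k, sigma, seed)
  }
  scale <- sqrt(prod(lr_size) / length(hr))
  y <- ifft2c(k * scale)
  if (magnitude) Mod(y) else y
}

kspace_upsample <- function(lr, target, magnitude = TRUE) {
  k <- zero_pad(fft2c(lr), target)
  scale <- sqrt(prod(as.integer(target)) / length(lr))
  y <- ifft2c(k * scale)
  if (magnitude) Mod(y) else y
}

#' Degrade a high-resolution image to a noisy low-resolution image
#'
#' Applies the acquisition model: centred FFT, low-frequency selection,
#' complex Gaussian k-space noise with `sigma = rho * RMS(|cropped
#' coefficients|)`, grid-size rescaling and inverse FFT on the
#' low-resolution grid.  With `cfg$magnitude_output` the complex magnitude
#' is taken at the end, which yields Rician-like image-domain noise; a
#' noise-free constant image maps to the same constant.
#'
#' @param hr Numeric matrix of size `cfg$hr_size`.
#' @param cfg A [degradation_config()].
#' @param rho Relative noise level for this image (default 0, noise-free).
#' @param seed Integer seed for the noise draw (default `cfg$seed`).
#' @return Matrix of size `cfg$lr_size` (numeric when
#'   `cfg$magnitude_output`, complex otherwise).
#' @examples
#' cfg <- degradation_config()
#' lr <- degrade(matrix(0.4, 128, 128), cfg)
#' dim(lr)          # 64 64
#' max(abs(lr - 0.4)) < 1e-10
#' @export
degrade <- function(hr, cfg, rho = 0, seed = cfg$seed) {
  stopifnot(inherits(cfg, "degradation_config"))
  check_image(hr)
  if (nrow(hr) != cfg$hr_size[1] || ncol(hr) != cfg$hr_size[2]) {
    stop("hr has size ", nrow(hr), "x", ncol(hr), " but cfg$hr_size is ",
         cfg$hr_size[1], "x", cfg$hr_size[2])
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0) {
    stop("rho must be a single non-negative number")
  }
  kspace_downsample(hr, cfg$lr_size, rho = rho, seed = seed,
                    magnitude = cfg$magnitude_output)
}

#' Zero-filling super-resolution baseline
#'
#' The classical reconstruction the network is compared against: embed the
#' low-resolution k-space in a larger zero grid, rescale, inverse FFT and
#' take the magnitude.  Band-limited images are reproduced exactly.
#'
#' @param lr Numeric matrix (low-resolution image).
#' @param target Integer pair `(H, W)`, at least the input size.
#' @return `H x W` numeric matrix.
#' @export
zero_fill_sr <- function(lr, target) {
  check_image(lr)
  target <- as.integer(target)
  if (target[1] < nrow(lr) || target[2] < ncol(lr)) {
    stop("target smaller than input")
  }
  kspace_upsample(lr, target, magnitude = TRUE)
}

#' Resize an image through k-space
#'
#' Per dimension, crops k-space when the target is smaller and zero-pads
#' when it is larger (e.g. 160x120 to 128x128 crops rows and pads columns),
#' with the grid-size rescaling applied so constants are preserved.  This
#' is the resize used to bring database images to the working resolution.
#'
#' @param img Numeric matrix.
#' @param target Integer pair `(H, W)`.
#' @return `H x W` numeric matrix.
#' @export
resize_via_kspace <- function(img, target) {
  check_image(img)
  target <- as.integer(target)
  src <- dim(img)
  if (all(target <= src)) return(kspace_downsample(img, target))
  if (all(target >= src)) return(kspace_upsample(img, target))
  k <- fft2c(img)
  mid <- pmin(src, target)
  k <- central_crop(k, mid)
  k <- zero_pad(k, pmax(mid, target))
  scale <- sqrt(prod(target) / prod(src))
  Mod(ifft2c(k * scale))
}
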