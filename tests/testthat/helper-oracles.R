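# Independent oracles and fixture builders.  Everything here is written
# against the documented conventions, not against the package internals, so
# agreement is evidence rather than tautology.

rand_img <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Brute-force O(N^4) direct-sum DFT with the centred orthonormal
# convention: K[u, v] = (HW)^(-1/2) sum_{m,n} x[m, n]
#   exp(-2*pi*i*((u - cu)(m - cm)/H + (v - cv)(n - cn)/W)),
# cu = floor(H/2) etc., all indices 0-based.
dft2c_ref <- function(x, inverse = FALSE) {
  H <- nrow(x); W <- ncol(x)
  cr <- floor(H / 2); cc <- floor(W / 2)
  sgn <- if (inverse) 1 else -1
  out <- matrix(0 + 0i, H, W)
  for (u in 0:(H - 1)) {
    for (v in 0:(W - 1)) {
      acc <- 0 + 0i
      for (m in 0:(H - 1)) {
        for (n in 0:(W - 1)) {
          ph <- sgn * 2 * pi * ((u - cr) * (m - cr) / H +
                                (v - cc) * (n - cc) / W)
          acc <- acc + x[m + 1, n + 1] * exp(1i * ph)
        }
      }
      out[u + 1, v + 1] <- acc
    }
  }
  out / sqrt(H * W)
}

# A strictly positive HR image whose k-space support (including the
# Hermitian reflection introduced by taking the real part) lies well inside
# the central lr-size block, so crop-then-pad reconstructs it exactly and
# the magnitude step in degrade() never flips a sign.
band_limited_img <- function(hr_size = c(64L, 64L), lr_size = hr_size / 2L,
                             seed = 1L) {
  r <- rand_img(hr_size[1], hr_size[2], seed)
  keep <- pmax(lr_size - 8L, 4L)
  k <- zero_pad(central_crop(fft2c(r), keep), hr_size)
  x <- Re(ifft2c(k))
  normalize_max(x - min(x) + 0.05 * (max(x) - min(x)))
}

# R double-precision reference forward pass for an srdn_model, looped
# directly from the weight-layout definition (independent of src/).
ref_forward <- function(model, x) {
  layers <- model$spec$layers
  tensors <- list(array(x, c(nrow(x), ncol(x), 1L)))
  shift_pad <- function(m, dr, dc) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    W <- model$params[[L$wi + 1L]]
    bias <- if (L$bi >= 0) model$params[[L$bi + 1L]] else NULL
    if (L$type == 0L) {
      inp <- array(0, c(dim(tensors[[L$inputs[1] + 1L]])[1:2], L$cin))
      off <- 0L
      for (id in L$inputs) {
        t <- tensors[[id + 1L]]
        inp[, , off + seq_len(dim(t)[3])] <- t
        off <- off + dim(t)[3]
      }
      H <- dim(inp)[1]; Wd <- dim(inp)[2]
      out <- array(0, c(H, Wd, L$cout))
      for (co in seq_len(L$cout)) {
        acc <- matrix(0, H, Wd)
        for (c in seq_len(L$cin)) {
          for (dj in 0:(L$k - 1L)) {
            for (di in 0:(L$k - 1L)) {
              row <- ((c - 1L) * L$k + dj) * L$k + di + 1L
              if (W[row, co] == 0) next
              acc <- acc + W[row, co] *
                shift_pad(inp[, , c], di - L$pb, dj - L$pb)
            }
          }
        }
        if (!is.null(bias)) acc <- acc + bias[1, co]
        out[, , co] <- acc
      }
    } else {
      inp <- tensors[[L$inputs[1] + 1L]]
      h <- dim(inp)[1]; w <- dim(inp)[2]
      OH <- h * L$stride; OW <- w * L$stride
      out <- array(0, c(OH, OW, L$cout))
      for (co in seq_len(L$cout)) {
        acc <- matrix(0, OH, OW)
        for (c in seq_len(L$cin)) {
          for (dj in 0:(L$k - 1L)) {
            for (di in 0:(L$k - 1L)) {
              col <- ((co - 1L) * L$k + dj) * L$k + di + 1L
              wgt <- W[c, col]
              if (wgt == 0) next
              for (i in 0:(h - 1L)) {
                for (j in 0:(w - 1L)) {
                  oi <- L$stride * i + di - L$pb
                  oj <- L$stride * j + dj - L$pb
                  if (oi >= 0 && oi < OH && oj >= 0 && oj < OW) {
                    acc[oi + 1L, oj + 1L] <- acc[oi + 1L, oj + 1L] +
                      wgt * inp[i + 1L, j + 1L, c]
                  }
                }
              }
            }
          }
        }
        if (!is.null(bias)) acc <- acc + bias[1, co]
        out[, , co] <- acc
      }
    }
    if (L$relu) out <- pmax(out, 0)
    tensors[[li + 1L]] <- out
  }
  tensors[[length(tensors)]][, , 1]
}

# toy configuration used across engine tests
toy_model_config <- function(biases = TRUE, ...) {
  model_config(n_blocks = 1L, layers_per_block = 2L, growth = 2L,
               bottleneck_out = 4L, deconv_kernel = 2L, deconv_out = 4L,
               initial_conv_out = NA, biases = biases, ...)
}

# write a minimal dataset directory from explicit HR/LR pairs
write_manual_dataset <- function(path, pairs, split = "test") {
  dir.create(file.path(path, "hr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "lr"), recursive = TRUE, showWarnings = FALSE)
  items <- lapply(seq_along(pairs), function(i) {
    id <- sprintf("img%05d", i)
    write_npy(pairs[[i]]$hr, file.path(path, "hr", paste0(id, ".npy")))
    write_npy(pairs[[i]]$lr, file.path(path, "lr", paste0(id, ".npy")))
    list(id = id, split = split, phantom_seed = i, noise_seed = i, rho = 0)
  })
  yaml::write_yaml(list(n = length(pairs), master_seed = 0L,
                        split = c(0, 0, 1), items = items),
                   file.path(path, "manifest.yaml"))
  invisible(path)
}

# small synthetic patch set for training tests
toy_patches <- function(n, seed = 1L, lr_side = 16L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    hr <- band_limited_img(c(2L * lr_side, 2L * lr_side), seed = seed + i)
    lr <- degrade(hr, degradation_config(lr_size = c(lr_side, lr_side),
                                         hr_size = dim(hr)),
                  rho = 0.05, seed = seed + i)
    list(hr = hr, lr = lr)
  })
}
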