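# Patch-based supervised training.
#
# One epoch is a pass over the training patches in seeded shuffled order,
# in batches of `batch_size`, with Adam updates.  After every epoch the
# validation loss is recorded; the returned model is the checkpoint with
# the smallest validation loss (ties broken by the earliest epoch).

#' Training configuration
#'
#' @param loss One of `"mse"` (default), `"l1"`, `"hfen"`.
#' @param learning_rate Adam learning rate (default `1e-3`).
#' @param batch_size Patches per gradient step (default 20).
#' @param max_epochs Number of epochs (default 74; the validation-loss
#'   minimum, not the final epoch, is returned).
#' @param seed Integer seed controlling shuffling.
#' @param checkpoint_every Epoch interval for on-disk checkpoints when a
#'   `checkpoint_path` is given to [train_srdn()] (default 1).
#' @param patience Stop after this many epochs without validation
#'   improvement, or `NA` for a fixed epoch budget (default `NA`).
#' @param stop_loss Stop as soon as the epoch training loss falls below
#'   this value, or `NA` to never stop early (default `NA`); useful for
#'   fit-to-criterion smoke runs.
#' @param hfen_kernel,hfen_sigma Laplacian-of-Gaussian filter of the HFEN
#'   loss (defaults 15 and 1.5).
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = c("mse", "l1", "hfen"),
                         learning_rate = 1e-3, batch_size = 20L,
                         max_epochs = 74L, seed = 1L,
                         checkpoint_every = 1L, patience = NA,
                         stop_loss = NA, hfen_kernel = 15L,
                         hfen_sigma = 1.5) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, batch_size >= 1L, max_epochs >= 0L,
            hfen_kernel %% 2L == 1L, hfen_sigma > 0)
  structure(list(loss = loss, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 patience = if (is.na(patience)) NA_integer_
                            else as.integer(patience),
                 stop_loss = if (is.na(stop_loss)) NA_real_
                             else as.numeric(stop_loss),
                 hfen_kernel = as.integer(hfen_kernel),
                 hfen_sigma = hfen_sigma),
            class = "train_config")
}

#' Laplacian-of-Gaussian kernel
#'
#' Discrete LoG filter normalised to exact zero sum, so that constant
#' offsets between two images contribute nothing to the HFEN loss.
#'
#' @param size Odd kernel side (default 15).
#' @param sigma Gaussian scale in pixels (default 1.5).
#' @return `size x size` numeric matrix summing to zero.
#' @export
log_kernel <- function(size = 15L, sigma = 1.5) {
  stopifnot(size %% 2L == 1L, sigma > 0)
  r <- (size - 1L) / 2L
  d2 <- outer((-r:r)^2, (-r:r)^2, "+")
  k <- (d2 - 2 * sigma^2) / sigma^4 * exp(-d2 / (2 * sigma^2))
  k - mean(k)
}

sym_pad_index <- function(n, r) {
  c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
}

# 2-D correlation with edge-inclusive symmetric boundary padding
filter2_sym <- function(x, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  p <- x[sym_pad_index(H, r), sym_pad_index(W, r), drop = FALSE]
  out <- matrix(0, H, W)
  for (dj in seq_len(ncol(kern))) {
    for (di in seq_len(nrow(kern))) {
      if (kern[di, dj] == 0) next
      out <- out + kern[di, dj] *
        p[(di - 1L) + seq_len(H), (dj - 1L) + seq_len(W), drop = FALSE]
    }
  }
  out
}

# exact adjoint of filter2_sym: scatter onto the padded grid with the
# kernel, then fold padded rows/columns back through the reflection map
filter2_sym_adj <- function(z, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  H <- nrow(z); W <- ncol(z)
  acc <- matrix(0, H + 2L * r, W + 2L * r)
  for (dj in seq_len(ncol(kern))) {
    for (di in seq_len(nrow(kern))) {
      if (kern[di, dj] == 0) next
      rows <- (di - 1L) + seq_len(H)
      cols <- (dj - 1L) + seq_len(W)
      acc[rows, cols] <- acc[rows, cols] + kern[di, dj] * z
    }
  }
  ri <- sym_pad_index(H, r); ci <- sym_pad_index(W, r)
  tmp <- matrix(0, H, W + 2L * r)
  for (p in seq_along(ri)) tmp[ri[p], ] <- tmp[ri[p], ] + acc[p, ]
  out <- matrix(0, H, W)
  for (q in seq_along(ci)) out[, ci[q]] <- out[, ci[q]] + tmp[, q]
  out
}

loss_pair <- function(kind, p, t, cfg = NULL) {
  switch(kind,
    mse = mean((p - t)^2),
    l1 = mean(abs(p - t)),
    hfen = {
      kern <- log_kernel(if (is.null(cfg)) 15L else cfg$hfen_kernel,
                         if (is.null(cfg)) 1.5 else cfg$hfen_sigma)
      num <- filter2_sym(p, kern) - filter2_sym(t, kern)
      den <- sqrt(sum(filter2_sym(t, kern)^2))
      if (den == 0) sqrt(sum(num^2)) else sqrt(sum(num^2)) / den
    },
    stop("unknown loss kind: ", kind))
}

#' Evaluate a training loss
#'
#' `mse` is the mean squared difference, `l1` the mean absolute
#' difference, and `hfen` the High-Frequency Error Norm: the L2 norm of
#' the difference of Laplacian-of-Gaussian filtered images divided by the
#' L2 norm of the filtered target (15x15 kernel, sigma 1.5 by default).
#' Batches (lists of matrices) are averaged.
#'
#' @param kind `"mse"`, `"l1"` or `"hfen"`.
#' @param prediction,target Numeric matrix or list of matrices of equal
#'   shapes.
#' @param cfg Optional [train_config()] supplying the HFEN filter
#'   parameters.
#' @return Single numeric loss value.
#' @export
loss_value <- function(kind, prediction, target, cfg = NULL) {
  if (is.list(prediction) != is.list(target)) {
    stop("prediction and target must both be matrices or both be lists")
  }
  if (!is.list(prediction)) {
    prediction <- list(prediction); target <- list(target)
  }
  if (length(prediction) != length(target)) stop("batch lengths differ")
  vals <- mapply(function(p, t) {
    if (!identical(dim(p), dim(t))) stop("shape mismatch in loss_value")
    loss_pair(kind, p, t, cfg)
  }, prediction, target)
  mean(vals)
}

# gradient of the HFEN loss w.r.t. the prediction:
# d/dp ||A(p - t)|| / ||A t|| = A^T A (p - t) / (||A(p - t)|| ||A t||)
hfen_grad <- function(p, t, cfg) {
  kern <- log_kernel(cfg$hfen_kernel, cfg$hfen_sigma)
  d <- filter2_sym(p, kern) - filter2_sym(t, kern)
  num <- sqrt(sum(d^2))
  den <- sqrt(sum(filter2_sym(t, kern)^2))
  if (num == 0) return(matrix(0, nrow(p), ncol(p)))
  filter2_sym_adj(d, kern) / (num * max(den, .Machine$double.eps))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

batch_loss_grad <- function(model, batch, cfg) {
  inputs <- lapply(batch, `[[`, "lr")
  targets <- lapply(batch, `[[`, "hr")
  if (cfg$loss %in% c("mse", "l1")) {
    r <- cpp_net_grad_batch(model$params, model$spec$layers, inputs, targets,
                            if (cfg$loss == "mse") 0L else 1L)
    return(list(loss = r$loss, grads = r$grads))
  }
  # hfen: forward, loss gradient on the R side, then a backward pass
  preds <- lapply(inputs, function(x) {
    cpp_net_forward(model$params, model$spec$layers, x)
  })
  n <- length(batch)
  loss <- mean(mapply(function(p, t) loss_pair("hfen", p, t, cfg),
                      preds, targets))
  dpreds <- mapply(function(p, t) hfen_grad(p, t, cfg) / n,
                   preds, targets, SIMPLIFY = FALSE)
  grads <- cpp_net_backward_batch(model$params, model$spec$layers, inputs,
                                  dpreds)
  list(loss = loss, grads = grads)
}

validation_loss <- function(model, patches, cfg) {
  preds <- lapply(patches, function(p) {
    cpp_net_forward(model$params, model$spec$layers, p$lr)
  })
  loss_value(cfg$loss, preds, lapply(patches, `[[`, "hr"), cfg)
}

#' Train a super-resolution network on patch pairs
#'
#' Adam optimisation (beta1 0.9, beta2 0.999, eps 1e-8) of the configured
#' loss over HR/LR patch pairs.  Bit-reproducible given the seed on a
#' fixed CPU.  Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model An `srdn_model` from [build_model()].
#' @param data List with `train` and `val` elements, each a list of patch
#'   pairs (`list(hr =, lr =)`) as produced by [extract_patches()].
#' @param cfg A [train_config()].
#' @param checkpoint_path Optional RDS path; the running best checkpoint
#'   (config echo, weights, optimizer state, epoch, loss history) is saved
#'   every `cfg$checkpoint_every` epochs.
#' @param verbose Print per-epoch losses (default `FALSE`).
#' @return List with `model` (at the best validation epoch) and `history`
#'   (data frame: epoch, train_loss, val_loss, wall_time).
#' @export
train_srdn <- function(model, data, cfg, checkpoint_path = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(model, "srdn_model"), inherits(cfg, "train_config"))
  if (cfg$max_epochs > 0L &&
      (length(data$train) == 0L || length(data$val) == 0L)) {
    stop("training requires non-empty train and val patch sets")
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), wall_time = numeric(0))
  if (cfg$max_epochs == 0L) {
    return(list(model = model, history = history))
  }
  state <- adam_init(model$params)
  best <- list(params = model$params, val = Inf, epoch = 0L)
  n <- length(data$train)
  since_best <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- with_seed(seed_stream(cfg$seed, "shuffle", epoch),
                     sample.int(n, n))
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      bg <- batch_loss_grad(model, data$train[idx], cfg)
      if (!is.finite(bg$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; reduce the learning rate or inspect the data")
      }
      upd <- adam_step(model$params, bg$grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bg$loss * length(idx)
    }
    vl <- validation_loss(model, data$val, cfg)
    history[epoch, ] <- list(epoch, ep_loss / n, vl,
                             proc.time()[["elapsed"]] - t0)
    if (verbose) {
      message(sprintf("epoch %d  train %.6g  val %.6g", epoch,
                      ep_loss / n, vl))
    }
    if (vl < best$val) {
      best <- list(params = model$params, val = vl, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (!is.null(checkpoint_path) && epoch %% cfg$checkpoint_every == 0L) {
      saveRDS(list(config = model$config, train_config = unclass(cfg),
                   params = best$params, adam_state = state,
                   epoch = epoch, best_epoch = best$epoch,
                   history = history),
              checkpoint_path)
    }
    if (!is.na(cfg$patience) && since_best >= cfg$patience) break
    if (!is.na(cfg$stop_loss) && ep_loss / n < cfg$stop_loss) break
  }
  model$params <- best$params
  list(model = model, history = history)
}

#' Index of the best epoch in a training history
#'
#' The epoch with minimal validation loss; ties are broken by the earliest
#' epoch.
#'
#' @param history Data frame with a `val_loss` column (one row per epoch).
#' @return 1-based epoch index.
#' @export
select_best_epoch <- function(history) {
  if (is.null(history$val_loss) || nrow(history) == 0L) {
    stop("empty training history")
  }
  which.min(history$val_loss)
}
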