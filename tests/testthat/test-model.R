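# Network construction, parameter counting and the forward engine.

test_that("the toy configuration matches the independent hand count", {
  # per layer: k^2 * c_in * c_out weights + c_out biases
  #   block layer 1: 9*1*2  + 2 =  20
  #   block layer 2: 9*3*2  + 2 =  56   (input = block input ++ layer 1)
  #   bottleneck   : 1*4*4  + 4 =  20   (concat of 2 layers x growth 2)
  #   deconv (k=2) : 4*4*4  + 4 =  68
  #   final  (k=3) : 9*4*1  + 1 =  37
  cfg <- toy_model_config()
  expect_identical(analytic_param_count(cfg), 201L)
  expect_identical(count_trainable_parameters(build_model(cfg, 1)), 201L)
})

test_that("disabling biases removes exactly one parameter per output channel", {
  with_b <- analytic_param_count(toy_model_config())
  no_b <- analytic_param_count(toy_model_config(biases = FALSE))
  out_channels <- 2L + 2L + 4L + 4L + 1L
  expect_identical(with_b - no_b, out_channels)
})

test_that("the calibrated default reproduces the reference parameter count", {
  cfg <- model_config()
  expect_identical(analytic_param_count(cfg), 1910689L)
  expect_identical(count_trainable_parameters(build_model(cfg, 1)),
                   1910689L)
})

test_that("model building is deterministic given the seed", {
  cfg <- toy_model_config()
  x <- rand_img(16, 16, 1)
  m1 <- build_model(cfg, seed = 7)
  m2 <- build_model(cfg, seed = 7)
  expect_identical(forward(m1, x), forward(m2, x))
  m3 <- build_model(cfg, seed = 8)
  expect_false(identical(forward(m1, x), forward(m3, x)))
})

test_that("the network is fully convolutional with upsampling factor 2", {
  m <- build_model(toy_model_config(), seed = 2)
  expect_identical(dim(forward(m, rand_img(16, 16, 1))), c(32L, 32L))
  expect_identical(dim(forward(m, rand_img(20, 24, 2))), c(40L, 48L))
  batch <- lapply(1:3, function(i) rand_img(16, 16, i))
  outs <- forward(m, batch)
  expect_length(outs, 3)
  expect_identical(dim(outs[[2]]), c(32L, 32L))
  expect_error(forward(m, rand_img(8, 8, 3)), "at least")
})

test_that("a zeroed final layer maps any input to zero", {
  m <- build_model(toy_model_config(), seed = 3)
  nfinal <- length(m$params)
  # final conv has a bias parameter after its weights in this config
  m$params[[nfinal - 1L]][] <- 0
  m$params[[nfinal]][] <- 0
  expect_identical(max(abs(forward(m, rand_img(16, 16, 9)))), 0)
})

test_that("dense blocks emit growth x layers new maps and the bottleneck its width", {
  m <- build_model(model_config(), seed = 1)
  ts <- lofisr:::cpp_net_tensors(m$params, m$spec$layers,
                                 rand_img(16, 16, 5))
  cfg <- m$config
  # per-block new-feature channels
  layer_ids <- seq_len(cfg$n_blocks * cfg$layers_per_block) +
    (!is.na(cfg$initial_conv_out))
  ch <- vapply(ts[layer_ids + 1L], function(a) dim(a)[3], 1L)
  per_block <- tapply(ch, rep(seq_len(cfg$n_blocks),
                              each = cfg$layers_per_block), sum)
  expect_true(all(per_block == cfg$growth * cfg$layers_per_block))
  expect_identical(unname(per_block[1]), 128L)
  bottleneck <- ts[[m$spec$bottleneck_tensor + 1L]]
  expect_identical(dim(bottleneck)[3], 256L)
})

test_that("the engine forward pass matches a double-precision R reference", {
  cfg <- model_config(n_blocks = 2L, layers_per_block = 2L, growth = 3L,
                      bottleneck_out = 5L, deconv_kernel = 3L,
                      deconv_out = 4L, initial_conv_out = 2L,
                      include_initial_in_concat = TRUE, biases = TRUE)
  m <- build_model(cfg, seed = 11)
  x <- rand_img(12, 16, 3) # engine itself has no minimum-size rule
  got <- lofisr:::cpp_net_forward(m$params, m$spec$layers, x)
  want <- ref_forward(m, x)
  expect_lt(max(abs(got - want)), 1e-4)

  # deconv kernel 2 (non-overlapping) path too
  cfg2 <- toy_model_config()
  m2 <- build_model(cfg2, seed = 12)
  x2 <- rand_img(16, 16, 4)
  expect_lt(max(abs(lofisr:::cpp_net_forward(m2$params, m2$spec$layers, x2) -
                      ref_forward(m2, x2))), 1e-4)
})

test_that("analytic gradients match finite differences on the reference forward", {
  cfg <- model_config(n_blocks = 1L, layers_per_block = 2L, growth = 2L,
                      bottleneck_out = 3L, deconv_kernel = 2L,
                      deconv_out = 3L, initial_conv_out = 2L, biases = TRUE)
  m <- build_model(cfg, seed = 21)
  # evaluate at a generic point: zero-initialised biases can leave
  # pre-activations exactly at the ReLU kink (where the one-sided
  # subgradient and a two-sided difference quotient legitimately differ)
  set.seed(22)
  for (i in seq_along(m$params)) {
    if (nrow(m$params[[i]]) == 1L) {
      m$params[[i]][] <- runif(length(m$params[[i]]), -0.05, 0.05)
    }
  }
  x <- rand_img(10, 10, 6)
  tgt <- rand_img(20, 20, 7)
  g <- lofisr:::cpp_net_grad_batch(m$params, m$spec$layers, list(x),
                                   list(tgt), 0L)
  ref_loss <- function(params) {
    mm <- m; mm$params <- params
    mean((ref_forward(mm, x) - tgt)^2)
  }
  set.seed(31)
  for (pi in seq_along(m$params)) {
    for (e in sample(length(m$params[[pi]]),
                     min(2L, length(m$params[[pi]])))) {
      h <- 1e-5
      pp <- m$params; pp[[pi]][e] <- pp[[pi]][e] + h
      pm <- m$params; pm[[pi]][e] <- pm[[pi]][e] - h
      num <- (ref_loss(pp) - ref_loss(pm)) / (2 * h)
      expect_equal(g$grads[[pi]][e], num, tolerance = 5e-3)
    }
  }
})

test_that("a single-pixel change only reaches the theoretical receptive field", {
  cfg <- model_config(n_blocks = 2L, layers_per_block = 2L,
                      initial_conv_out = 8L, deconv_out = 8L,
                      bottleneck_out = 16L)
  m <- build_model(cfg, seed = 5)
  x <- rand_img(48, 48, 8)
  y0 <- forward(m, x)
  x2 <- x; x2[25, 25] <- x2[25, 25] + 1
  dy <- abs(forward(m, x2) - y0)
  # trunk: 6 conv layers of radius 1 -> 6; deconv doubles coordinates and
  # final conv adds 1: radius <= 2*6 + 2 + 1 = 15 around output pixel 49
  changed <- which(dy > 1e-7, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  expect_true(all(abs(changed[, 1] - 49.5) <= 16))
  expect_true(all(abs(changed[, 2] - 49.5) <= 16))
})

test_that("calibrate_wiring returns matches and cross-checks the counts", {
  # a one-variant grid that matches its own count
  g1 <- data.frame(initial_conv_out = NA_integer_,
                   include_initial_in_concat = FALSE,
                   skip = "bottleneck", deconv_kernel = 2L,
                   deconv_out = 16L, biases = TRUE)
  cfg1 <- model_config(deconv_kernel = 2L, deconv_out = 16L,
                       initial_conv_out = NA, biases = TRUE)
  cal1 <- calibrate_wiring(analytic_param_count(cfg1), knob_grid = g1,
                           build_check = 1L)
  expect_identical(nrow(cal1$matches), 1L)
  expect_identical(cal1$gap, 0L)

  # random variants: analytic formula equals built-model introspection
  set.seed(6)
  grid <- default_knob_grid(initial_widths = c(NA, sample(1:128, 4)),
                            deconv_kernels = 2:3,
                            deconv_outs = c(8L, 24L, 64L))
  cal <- calibrate_wiring(1910689, knob_grid = grid, build_check = 10L)
  expect_true(all(cal$cross_check$analytic == cal$cross_check$built))
  expect_error(calibrate_wiring(1910689, knob_grid = grid[0, ]),
               "non-empty")
})
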