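# SRDenseNet-style super-resolution network.
#
# Architecture: an optional initial 3x3 convolution, 8 dense blocks of 8
# convolutional layers (3x3, growth 16: every layer receives the block
# input concatenated with all preceding layer outputs and contributes 16
# new feature maps, so a block yields 128 new maps), skip connections that
# carry every block's output to the reconstruction stage, a 1x1 bottleneck
# to 256 maps, a single stride-2 transpose convolution (upsampling factor
# 2), and a final 3x3 convolution to one channel with no activation.  All
# other layers use ReLU.  There is no normalization layer anywhere.
#
# The prose description of this architecture leaves several wiring
# details open (initial
# convolution and its width, transpose-conv kernel and width, whether
# skips also feed each block's input, bias usage).  These are free knobs of
# `model_config()`; `calibrate_wiring()` enumerates a knob grid against a
# target trainable-parameter count.  The shipped defaults are the unique
# grid member reproducing the reference count of 1,910,689 parameters:
# initial conv 65 maps (kept out of the bottleneck concatenation),
# chained blocks with all block outputs concatenated into the bottleneck,
# no biases, transpose-conv kernel 2 with 24 output maps.

#' Network architecture configuration
#'
#' Free knobs not fixed by the architecture description are exposed here;
#' see [calibrate_wiring()] for resolving them against a trainable-parameter
#' target.  Defaults are the calibrated wiring (1,910,689 parameters).
#'
#' @param n_blocks Number of dense blocks (default 8).
#' @param layers_per_block Convolutional layers per block (default 8).
#' @param growth Feature maps added by each layer (default 16).
#' @param block_kernel Kernel size inside blocks (default 3).
#' @param bottleneck_out Bottleneck output maps (default 256).
#' @param bottleneck_kernel Bottleneck kernel (default 1).
#' @param deconv_kernel Transpose-convolution kernel (default 2).
#' @param deconv_stride Transpose-convolution stride = upsampling factor
#'   (default 2).
#' @param deconv_out Transpose-convolution output maps (default 24).
#' @param final_kernel Final reconstruction kernel (default 3).
#' @param initial_conv_out Width of the initial 3x3 convolution, or `NA`
#'   for none (default 65).
#' @param include_initial_in_concat Feed the initial features into the
#'   bottleneck concatenation (default `FALSE`).
#' @param skip One of `"bottleneck"` (blocks chained; every block output
#'   concatenated into the bottleneck) or `"cumulative"` (block inputs also
#'   accumulate all previous block outputs).
#' @param biases Use bias terms (default `FALSE`).
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_blocks = 8L, layers_per_block = 8L, growth = 16L,
                         block_kernel = 3L, bottleneck_out = 256L,
                         bottleneck_kernel = 1L, deconv_kernel = 2L,
                         deconv_stride = 2L, deconv_out = 24L,
                         final_kernel = 3L, initial_conv_out = 65L,
                         include_initial_in_concat = FALSE,
                         skip = c("bottleneck", "cumulative"),
                         biases = FALSE) {
  skip <- match.arg(skip)
  cfg <- list(n_blocks = as.integer(n_blocks),
              layers_per_block = as.integer(layers_per_block),
              growth = as.integer(growth),
              block_kernel = as.integer(block_kernel),
              bottleneck_out = as.integer(bottleneck_out),
              bottleneck_kernel = as.integer(bottleneck_kernel),
              deconv_kernel = as.integer(deconv_kernel),
              deconv_stride = as.integer(deconv_stride),
              deconv_out = as.integer(deconv_out),
              final_kernel = as.integer(final_kernel),
              initial_conv_out = if (is.na(initial_conv_out)) NA_integer_
                                 else as.integer(initial_conv_out),
              include_initial_in_concat = isTRUE(include_initial_in_concat),
              skip = skip, biases = isTRUE(biases))
  with(cfg, stopifnot(n_blocks >= 1L, layers_per_block >= 1L, growth >= 1L,
                      block_kernel >= 1L, bottleneck_out >= 1L,
                      deconv_kernel >= deconv_stride - 1L, deconv_stride >= 1L,
                      deconv_out >= 1L, final_kernel >= 1L,
                      is.na(initial_conv_out) || initial_conv_out >= 1L))
  structure(cfg, class = "model_config")
}

# Flat layer list over the tensor graph: tensor 0 is the input, layer l
# produces tensor l + 1.  Each entry records kernel geometry, the tensor
# ids it concatenates, and indices into the parameter list.
srdn_layerspec <- function(cfg) {
  layers <- list()
  shapes <- list()   # weight (and bias) shapes, same order as params
  np <- 0L
  add_layer <- function(type, k, stride, relu, inputs, in_ch, cout) {
    cin <- sum(in_ch)
    wi <- np
    if (type == 0L) {
      shapes[[np + 1L]] <<- c(k * k * cin, cout)
    } else {
      shapes[[np + 1L]] <<- c(cin, k * k * cout)
    }
    np <<- np + 1L
    bi <- -1L
    if (cfg$biases) {
      shapes[[np + 1L]] <<- c(1L, cout)
      bi <- np
      np <<- np + 1L
    }
    pb <- if (type == 0L) (k - 1L) %/% 2L else (k - stride) %/% 2L
    layers[[length(layers) + 1L]] <<-
      list(type = type, k = k, stride = stride, pb = pb, relu = relu,
           inputs = as.integer(inputs), in_ch = as.integer(in_ch),
           cin = cin, cout = cout, wi = wi, bi = bi)
    length(layers)  # tensor id produced
  }
  ch <- integer(0)   # channels per tensor id (tensor 0 handled inline)
  tensor_ch <- function(ids) {
    vapply(ids, function(i) if (i == 0L) 1L else ch[i], 1L)
  }
  initial_id <- 0L
  if (!is.na(cfg$initial_conv_out)) {
    initial_id <- add_layer(0L, 3L, 1L, TRUE, 0L, 1L, cfg$initial_conv_out)
    ch[initial_id] <- cfg$initial_conv_out
  }
  block_in <- initial_id      # ids forming the next block's input
  block_outputs <- integer(0) # one id per layer output, all blocks
  for (b in seq_len(cfg$n_blocks)) {
    this_block <- integer(0)
    for (j in seq_len(cfg$layers_per_block)) {
      ins <- c(block_in, this_block)
      id <- add_layer(0L, cfg$block_kernel, 1L, TRUE, ins,
                      tensor_ch(ins), cfg$growth)
      ch[id] <- cfg$growth
      this_block <- c(this_block, id)
    }
    block_outputs <- c(block_outputs, this_block)
    block_in <- if (cfg$skip == "cumulative") {
      c(block_in, this_block)
    } else {
      this_block
    }
  }
  cat_ids <- block_outputs
  if (initial_id > 0L && cfg$include_initial_in_concat) {
    cat_ids <- c(initial_id, cat_ids)
  }
  bid <- add_layer(0L, cfg$bottleneck_kernel, 1L, TRUE, cat_ids,
                   tensor_ch(cat_ids), cfg$bottleneck_out)
  ch[bid] <- cfg$bottleneck_out
  did <- add_layer(1L, cfg$deconv_kernel, cfg$deconv_stride, TRUE, bid,
                   cfg$bottleneck_out, cfg$deconv_out)
  ch[did] <- cfg$deconv_out
  fid <- add_layer(0L, cfg$final_kernel, 1L, FALSE, did, cfg$deconv_out, 1L)
  ch[fid] <- 1L
  list(layers = layers, shapes = shapes,
       bottleneck_tensor = bid, deconv_tensor = did)
}

#' Analytic trainable-parameter count for a configuration
#'
#' Per-layer closed form (`k^2 * c_in * c_out` weights plus `c_out` biases
#' when enabled) summed over the wiring implied by `cfg`, without building
#' the network.  Cross-checked against [count_trainable_parameters()] on
#' built models by [calibrate_wiring()].
#'
#' @param cfg A [model_config()].
#' @return Integer parameter count.
#' @export
analytic_param_count <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  b <- as.integer(cfg$biases)
  total <- 0
  c0 <- 1L
  if (!is.na(cfg$initial_conv_out)) {
    total <- total + 9 * cfg$initial_conv_out + b * cfg$initial_conv_out
    c0 <- cfg$initial_conv_out
  }
  g <- cfg$growth; L <- cfg$layers_per_block; k2 <- cfg$block_kernel^2
  bin <- c0
  for (blk in seq_len(cfg$n_blocks)) {
    for (j in seq_len(L) - 1L) {
      total <- total + k2 * (bin + g * j) * g + b * g
    }
    bin <- if (cfg$skip == "cumulative") bin + g * L else g * L
  }
  cat_in <- cfg$n_blocks * g * L +
    if (!is.na(cfg$initial_conv_out) && cfg$include_initial_in_concat) {
      cfg$initial_conv_out
    } else 0L
  total <- total + cfg$bottleneck_kernel^2 * cat_in * cfg$bottleneck_out +
    b * cfg$bottleneck_out
  total <- total + cfg$deconv_kernel^2 * cfg$bottleneck_out * cfg$deconv_out +
    b * cfg$deconv_out
  total <- total + cfg$final_kernel^2 * cfg$deconv_out + b
  as.integer(total)
}

#' Build a super-resolution network
#'
#' Instantiates the architecture described by `cfg` with He-uniform
#' (fan-in) weight initialisation, deterministic given the seed.  The
#' network is fully convolutional: it accepts any input of at least 16x16
#' and produces an output `deconv_stride` times larger.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `srdn_model`.
#' @examples
#' m <- build_model(model_config(n_blocks = 1, layers_per_block = 2),
#'                  seed = 1)
#' dim(forward(m, matrix(0.5, 16, 16)))  # 32 32
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  spec <- srdn_layerspec(cfg)
  params <- vector("list", length(spec$shapes))
  with_seed(seed, {
    for (i in seq_along(spec$shapes)) {
      sh <- spec$shapes[[i]]
      if (is_bias_index(spec, i - 1L)) {
        params[[i]] <- matrix(0, sh[1], sh[2])
        next
      }
      lay <- layer_of_param(spec, i - 1L)
      fan_in <- if (lay$type == 0L) {
        lay$k^2 * lay$cin
      } else {
        lay$k^2 * lay$cin / lay$stride^2
      }
      lim <- sqrt(6 / fan_in)
      params[[i]] <- matrix(runif(prod(sh), -lim, lim), sh[1], sh[2])
    }
  })
  structure(list(config = cfg, spec = spec, params = params,
                 seed = as.integer(seed)),
            class = "srdn_model")
}

is_bias_index <- function(spec, idx) {
  any(vapply(spec$layers, function(l) l$bi == idx, TRUE))
}

layer_of_param <- function(spec, idx) {
  for (l in spec$layers) if (l$wi == idx || l$bi == idx) return(l)
  stop("no layer owns parameter index ", idx)
}

#' @export
print.srdn_model <- function(x, ...) {
  cfg <- x$config
  cat("<srdn_model> ", cfg$n_blocks, " dense blocks x ",
      cfg$layers_per_block, " layers, growth ", cfg$growth,
      ", bottleneck ", cfg$bottleneck_out,
      ", deconv k", cfg$deconv_kernel, "s", cfg$deconv_stride,
      " -> ", cfg$deconv_out, " maps\n", sep = "")
  cat("  trainable parameters: ",
      format(count_trainable_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Count trainable parameters by model introspection
#'
#' Exact count of scalar trainable values (weights, plus biases when
#' enabled) obtained from the instantiated tensors, independently of the
#' analytic formula.
#'
#' @param m An `srdn_model`.
#' @return Integer count.
#' @export
count_trainable_parameters <- function(m) {
  stopifnot(inherits(m, "srdn_model"))
  as.integer(sum(vapply(m$params, length, 1L)))
}

#' Forward pass
#'
#' Runs the network on a single image or a list of images.  Output values
#' are not clamped; clamping to `[0, 1]` happens only at export or before
#' metric computation.
#'
#' @param m An `srdn_model`.
#' @param lr Numeric matrix (at least 16x16) or list of matrices.
#' @return Matrix (or list of matrices) of `deconv_stride` times the input
#'   size.
#' @export
forward <- function(m, lr) {
  stopifnot(inherits(m, "srdn_model"))
  if (is.list(lr)) return(lapply(lr, function(x) forward(m, x)))
  check_image(lr, min_size = 16L)
  cpp_net_forward(m$params, m$spec$layers, lr)
}

#' @export
predict.srdn_model <- function(object, newdata, ...) forward(object, newdata)

#' Default knob grid for wiring calibration
#'
#' Enumerates the free wiring knobs: initial-convolution width (including
#' none), whether the initial features join the bottleneck concatenation,
#' skip composition, transpose-convolution kernel and width, and bias
#' usage.  Analytic counting makes exhaustive enumeration cheap, so the
#' initial width is swept densely.
#'
#' @param initial_widths Integer vector of initial-conv widths; `NA` means
#'   no initial convolution (default `c(NA, 1:128)`).
#' @param deconv_kernels Candidate transpose-conv kernels (default `2:4`).
#' @param deconv_outs Candidate transpose-conv widths (default
#'   `seq(8, 256, by = 8)`).
#' @return Data frame of knob combinations.
#' @export
default_knob_grid <- function(initial_widths = c(NA, 1:128),
                              deconv_kernels = 2:4,
                              deconv_outs = seq(8L, 256L, by = 8L)) {
  g <- expand.grid(initial_conv_out = initial_widths,
                   include_initial_in_concat = c(FALSE, TRUE),
                   skip = c("bottleneck", "cumulative"),
                   deconv_kernel = deconv_kernels,
                   deconv_out = deconv_outs,
                   biases = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  g <- g[!(is.na(g$initial_conv_out) & g$include_initial_in_concat), ,
         drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Resolve the free wiring knobs against a parameter-count target
#'
#' Computes the analytic trainable-parameter count for every knob
#' combination in the grid, flags the combinations matching
#' `target_count`, and cross-checks the analytic formula against
#' [count_trainable_parameters()] on built models for every match plus a
#' seeded random sample of non-matching variants.
#'
#' @param target_count Target trainable-parameter count (the reference
#'   architecture prints 1,910,689).
#' @param knob_grid Data frame of knob combinations
#'   (default [default_knob_grid()]).
#' @param build_check Number of additional variants to instantiate for the
#'   analytic-vs-introspection cross-check (default 10).
#' @param seed Seed for the cross-check sample.
#' @return List with `matches` (data frame of exact matches), `report`
#'   (the full grid with counts and the absolute gap), `best` (the
#'   [model_config()] of the exact match, or of the nearest variant when no
#'   exact match exists), `gap` (best count minus target) and
#'   `cross_check` (data frame comparing analytic and built counts).
#' @export
calibrate_wiring <- function(target_count, knob_grid = default_knob_grid(),
                             build_check = 10L, seed = 1L) {
  if (!is.data.frame(knob_grid) || nrow(knob_grid) == 0L) {
    stop("knob_grid must be a non-empty data frame")
  }
  cfg_of <- function(row) {
    model_config(deconv_kernel = row$deconv_kernel,
                 deconv_out = row$deconv_out,
                 initial_conv_out = row$initial_conv_out,
                 include_initial_in_concat = row$include_initial_in_concat,
                 skip = row$skip, biases = row$biases)
  }
  counts <- vapply(seq_len(nrow(knob_grid)), function(i) {
    analytic_param_count(cfg_of(knob_grid[i, ]))
  }, 1L)
  report <- knob_grid
  rownames(report) <- NULL
  report$count <- counts
  report$gap <- counts - as.integer(target_count)
  match_idx <- which(report$gap == 0L)
  matches <- report[match_idx, , drop = FALSE]
  best_i <- if (length(match_idx) > 0L) {
    match_idx[1]
  } else {
    which.min(abs(report$gap))
  }
  check_rows <- unique(c(
    match_idx,
    with_seed(seed, sample(nrow(report), min(build_check, nrow(report))))
  ))
  cross <- do.call(rbind, lapply(check_rows, function(i) {
    cfg <- cfg_of(knob_grid[i, ])
    built <- count_trainable_parameters(build_model(cfg, seed = 1L))
    data.frame(row = i, analytic = report$count[i], built = built)
  }))
  if (any(cross$analytic != cross$built)) {
    stop("analytic and introspected parameter counts disagree")
  }
  list(matches = matches, report = report,
       best = cfg_of(knob_grid[best_i, ]),
       gap = report$gap[best_i], cross_check = cross)
}
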