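# Phantom generation and paired dataset construction.

test_that("phantoms are deterministic given the seed", {
  cfg <- phantom_config()
  expect_identical(generate_phantom(cfg, seed = 12),
                   generate_phantom(cfg, seed = 12))
  expect_false(identical(generate_phantom(cfg, seed = 12),
                         generate_phantom(cfg, seed = 13)))
})

test_that("without texture and smoothing the phantom is piecewise constant", {
  n <- 5L
  cfg <- phantom_config(n_inner_ellipses = c(n, n), smooth_sigma = 0,
                        texture_amp = 0)
  p <- generate_phantom(cfg, seed = 4)
  expect_lte(length(unique(as.vector(p))), n + 2L)
})

test_that("phantoms satisfy range, support and background invariants", {
  cfg <- phantom_config()
  for (seed in 1:200) {
    p <- generate_phantom(cfg, seed = seed)
    expect_gte(min(p), 0)
    expect_lte(max(p), 1)
    expect_gt(mean(p > 0), 0.2)
    # the head ellipse stays inside the frame: the border is background
    expect_identical(unique(c(p[1, ], p[128, ], p[, 1], p[, 128])), 0)
  }
})

test_that("build_dataset writes the requested split with a reproducible manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  pcfg <- phantom_config()
  dcfg <- degradation_config()
  man <- build_dataset(10, pcfg, dcfg, d1, seed = 99,
                       split = c(0.8, 0.1, 0.1))
  splits <- vapply(man$items, function(x) x$split, "")
  expect_identical(as.vector(table(factor(splits,
                                          c("train", "val", "test")))),
                   c(8L, 1L, 1L))
  seeds <- vapply(man$items, function(x) x$phantom_seed, 1)
  expect_identical(length(unique(seeds)), 10L)

  build_dataset(10, pcfg, dcfg, d2, seed = 99, split = c(0.8, 0.1, 0.1))
  expect_identical(readLines(file.path(d1, "manifest.yaml")),
                   readLines(file.path(d2, "manifest.yaml")))
  for (f in list.files(file.path(d1, "hr"))) {
    expect_identical(readBin(file.path(d1, "hr", f), "raw", 1e6),
                     readBin(file.path(d2, "hr", f), "raw", 1e6))
  }
})

test_that("every stored LR image is reproducible from its manifest record", {
  d <- withr::local_tempdir()
  dcfg <- degradation_config()
  man <- build_dataset(4, phantom_config(), dcfg, d, seed = 5)
  for (it in man$items) {
    pair <- load_pair(d, it$id)
    redone <- degrade(pair$hr, dcfg, rho = it$rho, seed = it$noise_seed)
    expect_identical(pair$lr, redone)
  }
})

test_that("train/val/test phantom seeds never overlap", {
  d <- withr::local_tempdir()
  man <- build_dataset(20, phantom_config(), degradation_config(), d,
                       seed = 17, split = c(0.5, 0.25, 0.25))
  seeds <- split(vapply(man$items, function(x) x$phantom_seed, 1),
                 vapply(man$items, function(x) x$split, ""))
  expect_length(intersect(seeds$train, seeds$val), 0)
  expect_length(intersect(seeds$train, seeds$test), 0)
  expect_length(intersect(seeds$val, seeds$test), 0)
})

test_that("extract_patches aligns LR patches with halved even origins", {
  hr <- normalize_max(generate_phantom(phantom_config(), seed = 8))
  lr <- degrade(hr, degradation_config(), rho = 0.05, seed = 8)
  ps <- extract_patches(list(hr = hr, lr = lr), 5, seed = 3)
  expect_length(ps, 5)
  for (p in ps) {
    expect_identical(p$origin %% 2L, c(0L, 0L))
    expect_identical(dim(p$hr), c(32L, 32L))
    expect_identical(dim(p$lr), c(16L, 16L))
    expect_true(all(p$origin >= 0) && all(p$origin + 32L <= 128L))
    # definition instance: LR patch is cut from the full LR image
    expect_identical(p$lr,
                     lr[p$origin[1] / 2 + 1:16, p$origin[2] / 2 + 1:16])
    expect_identical(p$hr,
                     hr[p$origin[1] + 1:32, p$origin[2] + 1:32])
  }
  expect_error(extract_patches(list(hr = hr[1:20, 1:20], lr = lr[1:10, 1:10]),
                               1),
               "smaller")
})

test_that("patch means match the coverage-weighted image mean", {
  # uniform random origins cover border pixels less often; the expected
  # patch mean is the image mean weighted by per-pixel coverage counts
  cover <- function(N, P) {
    origins <- seq(0L, N - P, by = 2L)
    vapply(0:(N - 1), function(i) {
      sum(origins >= i - P + 1L & origins <= i)
    }, 1)
  }
  w_r <- cover(128, 32); w_c <- cover(128, 32)
  wmat <- outer(w_r, w_c)
  got <- c(); want <- c()
  for (s in 1:10) {
    hr <- normalize_max(generate_phantom(phantom_config(), seed = 100 + s))
    lr <- degrade(hr, degradation_config(), rho = 0, seed = s)
    ps <- extract_patches(list(hr = hr, lr = lr), 1000, seed = s)
    got <- c(got, mean(vapply(ps, function(p) mean(p$hr), 1)))
    want <- c(want, sum(hr * wmat) / sum(wmat))
  }
  expect_equal(mean(got), mean(want), tolerance = 0.05)
})

test_that("zero-filled LR patches track HR patches away from patch borders", {
  hr <- normalize_max(generate_phantom(phantom_config(), seed = 55))
  dcfg <- degradation_config()
  lr <- degrade(hr, dcfg, rho = 0)
  full_rec <- zero_fill_sr(lr, c(128, 128))
  interior <- 9:24
  ps <- extract_patches(list(hr = hr, lr = lr), 50, seed = 2)
  patch_err <- mean(vapply(ps, function(p) {
    rec <- zero_fill_sr(p$lr, c(32, 32))
    mean(abs(rec[interior, interior] - p$hr[interior, interior]))
  }, 1))
  full_err <- mean(vapply(ps, function(p) {
    rec <- full_rec[p$origin[1] + 1:32, p$origin[2] + 1:32]
    mean(abs(rec[interior, interior] - p$hr[interior, interior]))
  }, 1))
  # patch-boundary leakage is bounded: interior error within 3x the
  # full-image reconstruction error over the same pixels
  expect_lt(patch_err, 3 * max(full_err, 1e-6))
})
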