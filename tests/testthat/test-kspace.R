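# Centered orthonormal FFT operators and the degradation model.

test_that("fft2c matches the closed forms for constants and impulses", {
  N <- 16L
  c0 <- 0.37
  k <- fft2c(matrix(c0, N, N))
  dc <- floor(N / 2) + 1L
  expect_equal(Mod(k[dc, dc]), c0 * N, tolerance = 1e-12)
  off <- Mod(k); off[dc, dc] <- 0
  expect_lt(max(off), 1e-12)

  imp <- matrix(0, N, N); imp[dc, dc] <- 1
  expect_lt(max(abs(Mod(fft2c(imp)) - 1 / N)), 1e-12)
})

test_that("fft2c and ifft2c agree with the brute-force DFT oracle", {
  for (seed in 1:3) {
    x <- rand_img(8, 8, seed)
    expect_lt(max(Mod(fft2c(x) - dft2c_ref(x))), 1e-10)
    k <- dft2c_ref(x)
    expect_lt(max(Mod(ifft2c(k) - dft2c_ref(k, inverse = TRUE))), 1e-10)
  }
  # non-square grid
  x <- rand_img(8, 12, 9)
  expect_lt(max(Mod(fft2c(x) - dft2c_ref(x))), 1e-10)
})

test_that("ifft2c inverts fft2c and maps a DC coefficient to a constant", {
  x <- rand_img(16, 16, 4)
  expect_lt(max(Mod(ifft2c(fft2c(x)) - x)), 1e-10)
  N <- 12L
  k <- matrix(0 + 0i, N, N)
  k[floor(N / 2) + 1L, floor(N / 2) + 1L] <- 0.8 * N
  expect_lt(max(Mod(ifft2c(k) - 0.8)), 1e-12)
})

test_that("transforms are unitary (Parseval) across random fixtures", {
  set.seed(11)
  for (i in 1:100) {
    h <- sample(8:24, 1); w <- sample(8:24, 1)
    x <- matrix(runif(h * w), h, w)
    e_img <- sum(x^2)
    e_k <- sum(Mod(fft2c(x))^2)
    expect_lt(abs(e_img - e_k) / e_img, 1e-8)
  }
})

test_that("central_crop keeps the documented frequency window", {
  k <- matrix(complex(real = seq_len(128 * 128)), 128, 128)
  cr <- central_crop(k, c(64, 64))
  # rows and columns 32..95 inclusive (0-based)
  expect_identical(cr, k[33:96, 33:96])
  # DC preserved bit-exactly
  expect_identical(cr[33, 33], k[65, 65])
  expect_identical(central_crop(k, c(128, 128)), k)
  expect_error(central_crop(cr, c(128, 128)), "larger")
})

test_that("zero_pad places the block centrally, adds no energy, and inverts crop", {
  set.seed(2)
  k <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  p <- zero_pad(k, c(128, 128))
  expect_identical(p[33:96, 33:96], k)
  support <- Mod(p) > 0
  expect_true(all(which(support, arr.ind = TRUE) >= 33))
  expect_true(all(which(support, arr.ind = TRUE) <= 96))
  expect_equal(sum(Mod(p)^2), sum(Mod(k)^2), tolerance = 0)
  expect_identical(zero_pad(k, c(64, 64)), k)
  expect_error(zero_pad(p, c(64, 64)), "smaller")
  # crop-of-pad identity, bit-exact, for several sizes
  for (s in c(16L, 32L, 64L)) {
    ks <- central_crop(k, c(s, s))
    expect_identical(central_crop(zero_pad(ks, c(128, 128)), c(s, s)), ks)
  }
})

test_that("add_complex_noise has the stated variance and is seed-deterministic", {
  k <- matrix(0 + 0i, 64, 64)
  expect_identical(add_complex_noise(k, 0, 1), k)
  n1 <- add_complex_noise(k, 1, 123)
  expect_equal(mean(Mod(n1)^2), 1, tolerance = 0.05)
  expect_identical(n1, add_complex_noise(k, 1, 123))
  expect_false(identical(n1, add_complex_noise(k, 1, 124)))
  expect_error(add_complex_noise(k, -1, 1), "non-negative")
})

test_that("degrade yields the LR grid size and preserves constants", {
  cfg <- degradation_config()
  hr <- matrix(0.63, 128, 128)
  lr <- degrade(hr, cfg)
  expect_identical(dim(lr), c(64L, 64L))
  expect_lt(max(abs(lr - 0.63)), 1e-10)
  expect_error(degrade(matrix(0.5, 64, 64), cfg), "size")
})

test_that("noise-free band-limited images are fixed points of degrade + zero-fill", {
  cfg <- degradation_config()
  x <- band_limited_img(c(128L, 128L), c(64L, 64L), seed = 5)
  rec <- zero_fill_sr(degrade(x, cfg), c(128, 128))
  expect_lt(max(abs(rec - x)), 1e-10)
})

test_that("noise-free degradation is linear before the magnitude step", {
  cfg <- degradation_config(magnitude_output = FALSE)
  x1 <- rand_img(128, 128, 21)
  x2 <- rand_img(128, 128, 22)
  a <- 0.7; b <- -1.3
  lhs <- degrade(a * x1 + b * x2, cfg)
  rhs <- a * degrade(x1, cfg) + b * degrade(x2, cfg)
  expect_lt(max(Mod(lhs - rhs)), 1e-8)
})

test_that("zero_fill_sr upsamples, preserves constants and is exact on band-limited input", {
  lr <- matrix(0.5, 64, 64)
  up <- zero_fill_sr(lr, c(128, 128))
  expect_identical(dim(up), c(128L, 128L))
  expect_lt(max(abs(up - 0.5)), 1e-10)
  expect_error(zero_fill_sr(lr, c(32, 32)), "smaller")
})

test_that("resize_via_kspace crops and pads per dimension", {
  x <- rand_img(160, 120, 31)
  y <- resize_via_kspace(x, c(128, 128))
  expect_identical(dim(y), c(128L, 128L))
  # same-size resize is the identity up to the magnitude step
  z <- rand_img(32, 32, 32)
  expect_lt(max(abs(resize_via_kspace(z, c(32, 32)) - z)), 1e-10)
  # constant survives the mixed crop/pad path
  cst <- resize_via_kspace(matrix(0.4, 160, 120), c(128, 128))
  expect_lt(max(abs(cst - 0.4)), 1e-8)
})

test_that("resize down-then-up equals the degrade/zero-fill composition bit-for-bit", {
  x <- rand_img(128, 128, 41)
  cfg <- degradation_config()
  via_resize <- resize_via_kspace(resize_via_kspace(x, c(64, 64)),
                                  c(128, 128))
  via_degrade <- zero_fill_sr(degrade(x, cfg), c(128, 128))
  expect_identical(via_resize, via_degrade)
})

test_that("degradation is deterministic for identical input, config and seed", {
  cfg <- degradation_config()
  hr <- normalize_max(generate_phantom(phantom_config(), seed = 3))
  a <- degrade(hr, cfg, rho = 0.1, seed = 7)
  b <- degrade(hr, cfg, rho = 0.1, seed = 7)
  expect_identical(a, b)
})
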