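test_that("basic features match closed forms and the brute-force oracle", {
  u <- matrix(runif(30), 5, 6)
  # 1x1 kernel is a pointwise affine map
  expect_equal(basic_features(u, matrix(2), 0.5), 2 * u + 0.5)
  # delta kernel reproduces the input
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  expect_equal(basic_features(u, delta, 0), u)
  # all-ones 3x3 on [[1,2],[3,4]]: every window sums the whole image
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(basic_features(x, matrix(1, 3, 3), 0), matrix(10, 2, 2))
  # against the independent sliding-window oracle
  set.seed(4)
  xc <- matrix(rnorm(63), 7, 9); k <- matrix(rnorm(15), 3, 5)
  xt <- array(xc, c(1, 7, 9)); wt <- array(k, c(1, 1, 3, 5))
  expect_equal(basic_features(xc, k, 0.3), brute_conv(xt, wt, 0.3)[1, , ],
               tolerance = 1e-12)
})

test_that("even kernels and non-finite inputs are rejected", {
  u <- matrix(1, 4, 4)
  expect_error(basic_features(u, matrix(1, 2, 2), 0), "odd")
  expect_error(basic_features(matrix(c(1, NA, 1, 1), 2, 2), matrix(1), 0), "non-finite")
  expect_error(conv_bank(array(1, c(1, 1, 4, 4)), 0), "odd")
})

test_that("advanced features decompose exactly into summed basic features", {
  set.seed(11)
  # single-kernel filter: advanced == basic
  bank1 <- random_bank(2, 1)
  u1 <- random_tensor(1, 6, 6)
  expect_identical(advanced_features(u1, bank1, 1),
                   basic_features(u1[1, , ], bank1$weights[1, 1, , ], bank1$bias[1]))
  # opposite kernels on identical channels cancel
  k <- matrix(rnorm(9), 3, 3)
  w <- array(0, c(1, 2, 3, 3)); w[1, 1, , ] <- k; w[1, 2, , ] <- -k
  bank2 <- conv_bank(w, 0)
  ch <- matrix(rnorm(25), 5, 5)
  u2 <- array(0, c(2, 5, 5)); u2[1, , ] <- ch; u2[2, , ] <- ch
  expect_equal(advanced_features(u2, bank2, 1), matrix(0, 5, 5), tolerance = 1e-12)
  # decomposition is the same arithmetic path: identical, not just close
  for (case in 1:5) {
    bank <- random_bank(3, 3)
    u <- random_tensor(3, 7, 8)
    n <- sample(3, 1)
    oracle <- 0
    for (m in 1:3)
      oracle <- oracle + basic_features(u[m, , ], bank$weights[n, m, , ], bank$bias[n] / 3)
    expect_identical(advanced_features(u, bank, n), oracle)
    # and agrees with the full-layer convolution
    expect_equal(advanced_features(u, bank, n), conv_forward(u, bank)[n, , ],
                 tolerance = 1e-9)
  }
})

test_that("conv_forward matches the brute-force oracle", {
  set.seed(21)
  for (case in 1:4) {
    N <- sample(1:3, 1); M <- sample(1:4, 1); k <- sample(c(1, 3, 5), 1)
    bank <- random_bank(N, M, k)
    u <- random_tensor(M, 6, 7)
    expect_equal(conv_forward(u, bank), brute_conv(u, bank$weights, bank$bias),
                 tolerance = 1e-12)
  }
})

test_that("identity factors reproduce the plain convolution", {
  set.seed(31)
  bank <- random_bank(4, 3)
  u <- random_tensor(3, 10, 10)
  expect_equal(ss_forward(u, bank, ss_factors(bank)), conv_forward(u, bank),
               tolerance = 1e-10)
  expect_equal(rft_forward(u, bank, row_factors(bank)), conv_forward(u, bank),
               tolerance = 1e-10)
  # folding identity factors returns the bank unchanged
  folded <- fold_ss(bank, ss_factors(bank))
  expect_equal(folded$weights, bank$weights)
  expect_equal(folded$bias, bank$bias)
})

test_that("uniform scaling is homogeneous", {
  set.seed(32)
  bank <- random_bank(3, 2)
  bank$bias[] <- 0
  u <- random_tensor(2, 8, 8)
  f2 <- ss_factors(bank, scale = matrix(2, 3, 2))
  expect_equal(ss_forward(u, bank, f2), 2 * conv_forward(u, bank), tolerance = 1e-10)
})

test_that("folding factors into the weights is equivalent to SS-modulated convolution", {
  set.seed(33)
  for (case in 1:10) {
    bank <- random_bank(sample(1:4, 1), sample(1:4, 1), sample(c(1, 3, 5), 1))
    f <- random_factors(bank)
    u <- random_tensor(dim(bank$weights)[2], 9, 9)
    expect_lt(max(abs(ss_forward(u, bank, f) - conv_forward(u, fold_ss(bank, f)))), 1e-10)
  }
  # scaling one kernel of ones by 3 yields a kernel of threes
  bank <- conv_bank(array(1, c(2, 2, 3, 3)), c(0, 0))
  f <- ss_factors(bank); f$scale[1, 1] <- 3
  expect_equal(fold_ss(bank, f)$weights[1, 1, , ], matrix(3, 3, 3))
  # fold does not modify its inputs
  expect_equal(bank$weights[1, 1, 1, 1], 1)
})

test_that("row factors interpolate between per-kernel factors and full freedom", {
  set.seed(34)
  bank <- random_bank(2, 3)
  u <- random_tensor(3, 8, 8)
  # all rows sharing one scale degenerates to the per-kernel factor
  s <- 1.7
  rf <- row_factors(bank, row_scale = array(s, c(2, 3, 3)))
  sf <- ss_factors(bank, scale = matrix(s, 2, 3))
  expect_equal(rft_forward(u, bank, rf), ss_forward(u, bank, sf), tolerance = 1e-10)
  # random row factors match an explicit row-wise fold
  rf2 <- row_factors(bank, row_scale = array(rnorm(18, 1, 0.4), c(2, 3, 3)),
                     shift = matrix(rnorm(6, sd = 0.2), 2, 3))
  wfold <- bank$weights
  for (n in 1:2) for (m in 1:3) for (r in 1:3)
    wfold[n, m, r, ] <- wfold[n, m, r, ] * rf2$row_scale[n, m, r]
  oracle <- conv_forward(u, conv_bank(wfold, bank$bias + rowSums(rf2$shift)))
  expect_equal(rft_forward(u, bank, rf2), oracle, tolerance = 1e-10)
})

test_that("trainable-parameter accounting follows the strategy contracts", {
  layer <- list(c(1, 4, 3, 3))
  expect_identical(count_trainable("FT", layer), 37L)
  expect_identical(count_trainable("DT", layer), 37L)
  expect_identical(count_trainable("LFT", layer), 8L)
  expect_identical(count_trainable("RFT", layer), 16L)
  expect_identical(count_trainable("PT", layer), 0L)
  expect_error(count_trainable("XX", layer), "unknown strategy")
  # ordering LFT < RFT < FT whenever the kernel has more than two weights
  set.seed(35)
  for (case in 1:10) {
    shape <- list(c(sample(1:8, 1), sample(1:8, 1), 3, sample(c(3, 5), 1)))
    expect_lt(count_trainable("LFT", shape), count_trainable("RFT", shape))
    expect_lt(count_trainable("RFT", shape), count_trainable("FT", shape))
  }
})

test_that("shape mismatches raise configuration errors", {
  bank <- random_bank(2, 3)
  other <- random_bank(3, 3)
  u <- random_tensor(2, 6, 6)  # wrong channel count
  expect_error(ss_forward(u, bank, ss_factors(bank)), "channel")
  expect_error(ss_forward(random_tensor(3, 6, 6), bank, ss_factors(other)),
               "configuration")
  expect_error(fold_ss(bank, ss_factors(other)), "configuration")
  expect_error(advanced_features(u, bank, 1), "channels")
})

test_that("banks and factors round-trip through the portable container", {
  set.seed(36)
  bank <- random_bank(3, 2, 5)
  f <- random_factors(bank)
  path <- tempfile(fileext = ".json")
  write_bank(bank, path, factors = f)
  back <- read_bank(path)
  expect_equal(back$bank$weights, bank$weights)
  expect_equal(back$bank$bias, bank$bias)
  expect_equal(back$factors$scale, f$scale)
  expect_equal(back$factors$shift, f$shift)
})
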