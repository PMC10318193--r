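test_that("generator construction is seeded and identity at initialization", {
  spec <- network_spec(depth = 2, base_channels = 4)
  a <- build_generator(spec, seed = 5)
  b <- build_generator(spec, seed = 5)
  expect_identical(lapply(a$layers, `[[`, "w"), lapply(b$layers, `[[`, "w"))
  expect_false(identical(lapply(a$layers, `[[`, "w"),
                         lapply(build_generator(spec, seed = 6)$layers, `[[`, "w")))
  # zero-initialized final layer: the untrained network is the identity map
  set.seed(1)
  x <- random_tensor(2, 16, 16)
  expect_equal(net_forward(a, x), x, tolerance = 1e-14)
  # chaining doubles the layer count
  c2 <- build_generator(network_spec(depth = 2, base_channels = 4, chain_length = 2), 1)
  expect_equal(length(c2$layers), 2 * length(a$layers))
  expect_equal(net_forward(c2, x), x, tolerance = 1e-14)
})

test_that("input sizes must match the downsampling depth", {
  net <- build_generator(network_spec(depth = 2, base_channels = 4), 1)
  expect_error(net_forward(net, random_tensor(2, 10, 10)), "divisible")
  expect_error(net_forward(net, random_tensor(2, 10, 10)), "pad")
})

test_that("factor insertion preserves outputs and counts parameters correctly", {
  net <- build_generator(network_spec(depth = 2, base_channels = 4), seed = 2)
  # make the net non-trivial so preservation is meaningful
  for (i in seq_along(net$layers))
    net$layers[[i]]$w <- net$layers[[i]]$w +
      array(rnorm(length(net$layers[[i]]$w), sd = 0.05), dim(net$layers[[i]]$w))
  set.seed(3)
  x <- random_tensor(2, 16, 16)
  base_out <- net_forward(net, x)
  lft_net <- insert_ss(net, "kernel")
  expect_lt(max(abs(net_forward(lft_net, x) - base_out)), 1e-12)
  rft_net <- insert_ss(net, "row")
  expect_lt(max(abs(net_forward(rft_net, x) - base_out)), 1e-12)
  expect_error(insert_ss(lft_net), "state error")
  # trainer bookkeeping equals the per-layer formulas
  shapes <- lapply(net$layers, function(l) dim(l$w))
  expect_equal(net_trainable_count(lft_net, "LFT"), count_trainable("LFT", shapes))
  expect_equal(net_trainable_count(rft_net, "RFT"), count_trainable("RFT", shapes))
  expect_equal(net_trainable_count(net, "FT"), count_trainable("FT", shapes))
  # row factors without trainable shift drop the per-kernel shift count
  rft_ns <- insert_ss(net, "row", include_shift = FALSE)
  expect_equal(net_trainable_count(rft_ns, "RFT"),
               count_trainable("RFT", shapes) - sum(vapply(shapes, function(s)
                 s[1] * s[2], numeric(1))))
})

test_that("layerwise folding yields an equivalent plain network", {
  net <- insert_ss(build_generator(network_spec(depth = 2, base_channels = 4), seed = 4))
  # perturb the factors away from identity
  set.seed(7)
  for (i in seq_along(net$layers)) {
    d <- dim(net$layers[[i]]$w)
    net$layers[[i]]$ss$scale <- matrix(rnorm(d[1] * d[2], 1, 0.3), d[1], d[2])
    net$layers[[i]]$ss$shift <- matrix(rnorm(d[1] * d[2], 0, 0.1), d[1], d[2])
  }
  folded <- fold_network(net)
  expect_false(net_has_ss <- any(vapply(folded$layers, function(l) !is.null(l$ss), logical(1))))
  for (rep in 1:3) {
    x <- random_tensor(2, 16, 16)
    expect_lt(max(abs(net_forward(net, x) - net_forward(folded, x))), 1e-10)
  }
})

test_that("forward outputs stay finite over random networks and inputs", {
  for (s in 1:30) {
    net <- build_generator(network_spec(depth = 1, base_channels = 4), seed = s)
    set.seed(s)
    x <- random_tensor(2, 8, 8)
    y <- net_forward(net, x)
    expect_true(all(is.finite(y)))
    expect_identical(dim(y), dim(x))
  }
})

test_that("networks round-trip through the JSON checkpoint format", {
  net <- insert_ss(build_generator(network_spec(depth = 1, base_channels = 4), seed = 9))
  set.seed(10)
  for (i in seq_along(net$layers)) {
    d <- dim(net$layers[[i]]$w)
    net$layers[[i]]$ss$scale <- matrix(rnorm(d[1] * d[2], 1, 0.2), d[1], d[2])
  }
  path <- tempfile(fileext = ".json")
  save_network(net, path)
  back <- load_network(path)
  x <- random_tensor(2, 8, 8)
  expect_equal(net_forward(back, x), net_forward(net, x), tolerance = 1e-12)
  expect_equal(back$layers[[2]]$ss$scale, net$layers[[2]]$ss$scale)
})

test_that("describe_net tabulates per-strategy parameter counts", {
  net <- build_generator(network_spec(depth = 2, base_channels = 4), 1)
  df <- describe_net(net)
  expect_equal(nrow(df), length(net$layers))
  expect_true(all(df$lft_params < df$rft_params))
  expect_true(all(df$rft_params < df$ft_params))
  expect_equal(sum(df$ft_params), net_trainable_count(net, "FT"))
})

test_that("invalid network specs are rejected", {
  expect_error(network_spec(depth = 0), "depth")
  expect_error(network_spec(base_channels = 2), "base_channels")
  expect_error(network_spec(chain_length = 3), "chain_length")
})
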