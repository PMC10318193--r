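test_that("datasets split in ratio proportions with largest-remainder rounding", {
  imgs <- as.list(1:25)
  s <- split_dataset(imgs, split_spec(), seed = 1)
  expect_equal(lengths(s), c(train = 16, val = 5, test = 4))
  s100 <- split_dataset(as.list(1:100), split_spec(), seed = 2)
  expect_equal(lengths(s100), c(train = 64, val = 20, test = 16))
  # partition is disjoint and exhaustive
  expect_setequal(unlist(s100), 1:100)
  # training subset leaves val/test untouched
  sub <- split_dataset(as.list(1:100), split_spec(train_subset_size = 20), seed = 2)
  expect_equal(lengths(sub), c(train = 20, val = 20, test = 16))
  expect_identical(sub$val, s100$val)
  expect_identical(sub$test, s100$test)
  # deterministic given the seed
  expect_identical(split_dataset(imgs, split_spec(), seed = 1), s)
  expect_error(split_dataset(as.list(1:10), split_spec()), "size error")
  expect_error(split_dataset(as.list(1:100), split_spec(train_subset_size = 65), seed = 1),
               "size error")
})

test_that("early stopping requires strict improvement within the patience window", {
  h <- function(psnr) {
    df <- data.frame(epoch = seq_along(psnr), train_loss = 0, val_psnr = psnr)
    df
  }
  # strictly increasing: never stops
  expect_false(early_stop_check(h(1:30), 15))
  # constant after epoch 1: stops at epoch 16 with best_epoch 1
  const16 <- h(rep(25, 16))
  expect_false(early_stop_check(h(rep(25, 15)), 15))
  expect_true(early_stop_check(const16, 15))
  expect_equal(const16$epoch[which.max(const16$val_psnr)], 1)
  # strictly decreasing from epoch 1: same stopping epoch
  expect_true(early_stop_check(h(seq(30, by = -0.5, length.out = 16)), 15))
  # an improvement at epoch 14 of the window restarts the counter
  psnr <- c(25, rep(24, 13), 26, rep(24, 10))
  expect_false(early_stop_check(h(psnr[1:24]), 15))
  expect_true(early_stop_check(h(c(psnr, 24, 24, 24, 24, 24)), 15))
})

test_that("strategy configs validate and pick per-strategy learning rates", {
  expect_equal(strategy_config("FT")$learning_rate, 1e-5)
  expect_equal(strategy_config("LFT")$learning_rate, 1e-4)
  expect_equal(strategy_config("DT")$learning_rate, 1e-4)
  expect_equal(strategy_config("LFT")$patience, 15)
  expect_error(strategy_config("QT"), "unknown strategy")
  expect_error(strategy_config("FT", learning_rate = -1), "learning_rate")
  expect_error(strategy_config("FT", patience = 0), "patience")
})

test_that("a vanishing learning rate leaves the model unchanged", {
  imgs <- toy_images(25, size = 16, seed = 1)
  split <- split_dataset(imgs, split_spec(), seed = 1)
  mask <- generate_cartesian_mask(16, 0.5, center_fraction = 0.1, seed = 1)
  net <- build_generator(network_spec(depth = 1, base_channels = 4), seed = 1)
  cfg <- strategy_config("DT", learning_rate = 1e-30, max_epochs = 1, seed = 1)
  out <- pretrain(net, split, cfg, mask)
  for (i in seq_along(net$layers))
    expect_equal(out$net$layers[[i]]$w, net$layers[[i]]$w, tolerance = 1e-12)
  # validation PSNR equals the untrained network's
  expect_equal(out$history$val_psnr[1], attr(out$history, "initial_val_psnr"),
               tolerance = 1e-9)
})

test_that("training histories are reproducible under a fixed seed", {
  imgs <- toy_images(25, size = 16, seed = 2)
  split <- split_dataset(imgs, split_spec(), seed = 2)
  mask <- generate_cartesian_mask(16, 0.5, center_fraction = 0.1, seed = 2)
  run <- function() {
    net <- build_generator(network_spec(depth = 1, base_channels = 4), seed = 3)
    pretrain(net, split, strategy_config("DT", max_epochs = 3, seed = 4), mask)
  }
  a <- run(); b <- run()
  expect_identical(a$history$train_loss, b$history$train_loss)
  expect_identical(a$history$val_psnr, b$history$val_psnr)
  expect_identical(lapply(a$net$layers, `[[`, "w"), lapply(b$net$layers, `[[`, "w"))
})

test_that("the returned checkpoint is the best validation epoch", {
  imgs <- toy_images(25, size = 16, seed = 5)
  split <- split_dataset(imgs, split_spec(), seed = 5)
  mask <- generate_cartesian_mask(16, 0.5, center_fraction = 0.1, seed = 5)
  net <- build_generator(network_spec(depth = 1, base_channels = 4), seed = 5)
  out <- pretrain(net, split, strategy_config("DT", max_epochs = 5, seed = 5), mask)
  h <- out$history
  expect_equal(attr(h, "best_epoch"), h$epoch[which.max(h$val_psnr)])
  expect_equal(attr(h, "best_val_psnr"), max(h$val_psnr))
  # the returned model reproduces that validation PSNR
  val_ex <- lftmri:::prepare_examples(split$val, mask)
  expect_equal(lftmri:::validation_psnr(out$net, val_ex), max(h$val_psnr),
               tolerance = 1e-12)
})

test_that("transfer strategies honor their freezing contracts", {
  fix <- toy_pretrained(size = 32, epochs = 2, seed = 6)
  tgt <- split_dataset(toy_images(25, size = 32, seed = 7, contrast = "t2"),
                       split_spec(), seed = 7)
  # PT: zero training steps, evaluation only
  pt <- transfer(build_generator(fix$spec, seed = 6), fix$checkpoint, tgt,
                 strategy_config("PT", seed = 6), fix$mask)
  expect_equal(nrow(pt$history), 0)
  expect_identical(lapply(pt$net$layers, `[[`, "w"),
                   lapply(fix$checkpoint, `[[`, "w"))
  # LFT: backbone bitwise frozen after training
  lft_net <- insert_ss(build_generator(fix$spec, seed = 6))
  lft <- transfer(lft_net, fix$checkpoint, tgt,
                  strategy_config("LFT", max_epochs = 2, seed = 6), fix$mask)
  expect_identical(lapply(lft$net$layers, `[[`, "w"), lapply(fix$checkpoint, `[[`, "w"))
  expect_identical(lapply(lft$net$layers, `[[`, "b"), lapply(fix$checkpoint, `[[`, "b"))
  # ... but the factors moved
  expect_false(all(lft$net$layers[[1]]$ss$scale == 1))
  # RFT: same contract with row factors
  rft <- transfer(insert_ss(build_generator(fix$spec, seed = 6), "row"), fix$checkpoint,
                  tgt, strategy_config("RFT", max_epochs = 1, seed = 6), fix$mask)
  expect_identical(lapply(rft$net$layers, `[[`, "w"), lapply(fix$checkpoint, `[[`, "w"))
  # FT with a vanishing learning rate degenerates to PT
  ft0 <- transfer(build_generator(fix$spec, seed = 6), fix$checkpoint, tgt,
                  strategy_config("FT", learning_rate = 1e-30, max_epochs = 1, seed = 6),
                  fix$mask)
  ev_pt <- evaluate_model(pt$net, tgt$test, fix$mask, "PT", metrics = "psnr")
  ev_ft0 <- evaluate_model(ft0$net, tgt$test, fix$mask, "FT", metrics = "psnr")
  expect_equal(ev_ft0$psnr, ev_pt$psnr, tolerance = 1e-9)
  # LFT without SS blocks is a state error
  expect_error(transfer(build_generator(fix$spec, seed = 6), fix$checkpoint, tgt,
                        strategy_config("LFT", seed = 6), fix$mask), "state error")
  # architecture mismatch is a compatibility error
  other <- build_generator(network_spec(depth = 1, base_channels = 4), seed = 1)
  expect_error(transfer(other, fix$checkpoint, tgt, strategy_config("FT", seed = 1),
                        fix$mask), "compatibility")
})

test_that("LFT starts from the pre-trained model's validation performance", {
  fix <- toy_pretrained(size = 32, epochs = 2, seed = 8)
  tgt <- split_dataset(toy_images(25, size = 32, seed = 9, contrast = "t2"),
                       split_spec(), seed = 9)
  pt <- transfer(build_generator(fix$spec, seed = 8), fix$checkpoint, tgt,
                 strategy_config("PT", seed = 8), fix$mask)
  lft <- transfer(insert_ss(build_generator(fix$spec, seed = 8)), fix$checkpoint, tgt,
                  strategy_config("LFT", max_epochs = 1, seed = 8), fix$mask)
  expect_equal(attr(lft$history, "initial_val_psnr"),
               attr(pt$history, "initial_val_psnr"), tolerance = 1e-6)
})
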