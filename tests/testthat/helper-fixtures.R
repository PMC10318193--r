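# Shared fixture builders: everything is generated in code under fixed seeds.

random_bank <- function(N, M, kh = 3, kw = kh) {
  conv_bank(array(rnorm(N * M * kh * kw), c(N, M, kh, kw)), rnorm(N))
}

random_tensor <- function(M, H, W) array(rnorm(M * H * W), c(M, H, W))

random_factors <- function(bank) {
  d <- dim(bank$weights)
  ss_factors(bank, scale = matrix(rnorm(d[1] * d[2], mean = 1, sd = 0.5), d[1], d[2]),
             shift = matrix(rnorm(d[1] * d[2], sd = 0.3), d[1], d[2]))
}

# Independent brute-force oracle for the convolution: explicit sliding-window
# quadruple loop, no shared code with the package's compiled path.
brute_conv <- function(x, w, b) {
  d <- dim(w); di <- dim(x); ph <- d[3] %/% 2; pw <- d[4] %/% 2
  y <- array(0, c(d[1], di[2], di[3]))
  for (n in seq_len(d[1])) for (i in seq_len(di[2])) for (j in seq_len(di[3])) {
    acc <- b[n]
    for (m in seq_len(d[2])) for (p in seq_len(d[3])) for (q in seq_len(d[4])) {
      ii <- i + p - 1 - ph; jj <- j + q - 1 - pw
      if (ii >= 1 && ii <= di[2] && jj >= 1 && jj <= di[3])
        acc <- acc + x[m, ii, jj] * w[n, m, p, q]
    }
    y[n, i, j] <- acc
  }
  y
}

# Small phantom image lists for training tests.
toy_images <- function(n, size = 32, seed = 0, template = "brain_sagittal",
                       contrast = "t1") {
  spec <- phantom_spec(size = size, template = template, contrast = contrast, seed = seed)
  lapply(seq_len(n), function(i) generate_slice(spec, i)$image)
}

# A tiny pretrain -> checkpoint pipeline shared by transfer-contract tests.
toy_pretrained <- function(size = 32, n_source = 25, epochs = 3, seed = 0) {
  imgs <- toy_images(n_source, size = size, seed = seed)
  split <- split_dataset(imgs, split_spec(), seed = seed)
  mask <- generate_cartesian_mask(size, 0.3, seed = seed)
  net <- build_generator(network_spec(depth = 2, base_channels = 4), seed = seed)
  cfg <- strategy_config("DT", max_epochs = epochs, seed = seed)
  pre <- pretrain(net, split, cfg, mask)
  list(net = pre$net, checkpoint = net_checkpoint(pre$net), history = pre$history,
       split = split, mask = mask, size = size,
       spec = network_spec(depth = 2, base_channels = 4), seed = seed)
}
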