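#' Reconstruction network specification
#'
#' A compact residual U-net generator built entirely from plain convolution
#' banks, leaky-ReLU activations, 2x2 average-pool downsampling, and
#' nearest-neighbor upsampling, with a global residual skip (output = input +
#' correction). Keeping every learnable layer a stride-1 convolution bank
#' means the scaling/shifting factors can be inserted into any layer
#' plug-and-play. Two U-nets can be chained to mimic a refinement cascade.
#'
#' @param depth encoder/decoder levels per U-net (default 2; input sizes must
#'   be divisible by `2^depth`).
#' @param base_channels channels at the full-resolution level (>= 4); channel
#'   counts double at each level.
#' @param chain_length number of chained U-nets (1 or 2).
#' @param in_channels input/output channels (2 = real/imaginary).
#' @param use_adversarial reserved flag for an adversarial training term
#'   (off by default; the default objective is pixelwise L1 on magnitude).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(depth = 2, base_channels = 8, chain_length = 1,
                         in_channels = 2, use_adversarial = FALSE) {
  if (depth < 1) stop("depth must be >= 1 (configuration error)", call. = FALSE)
  if (base_channels < 4) stop("base_channels must be >= 4 (configuration error)", call. = FALSE)
  if (!chain_length %in% 1:2) stop("chain_length must be 1 or 2 (configuration error)", call. = FALSE)
  structure(list(depth = as.integer(depth), base_channels = as.integer(base_channels),
                 chain_length = as.integer(chain_length), in_channels = as.integer(in_channels),
                 use_adversarial = isTRUE(use_adversarial)), class = "network_spec")
}

new_conv_layer <- function(n_out, n_in, k = 3L, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") array(0, c(n_out, n_in, k, k)) else
    array(rnorm(n_out * n_in * k * k, sd = sqrt(2 / (n_in * k * k))), c(n_out, n_in, k, k))
  list(w = w, b = numeric(n_out), ss = NULL, rft = NULL)
}

#' Build a residual U-net reconstruction generator
#'
#' Construction is fully deterministic given `(spec, seed)`. The final
#' convolution of each chained U-net is zero-initialized, so the untrained
#' network is the identity map: its output equals its input, and training
#' learns only the correction.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight initialization.
#' @return An object of class `recon_network`.
#' @export
build_generator <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "network_spec"))
  layers <- list(); steps <- list(); nb <- 1L
  add_layer <- function(l) { layers[[length(layers) + 1L]] <<- l; length(layers) }
  add_step <- function(op, in1, in2 = NA_integer_, layer = NA_integer_, alpha = NA_real_) {
    nb <<- nb + 1L
    steps[[length(steps) + 1L]] <<- list(op = op, in1 = in1, in2 = in2,
                                         layer = layer, alpha = alpha, out = nb)
    nb
  }
  ch <- spec$base_channels * 2^(0:spec$depth)
  with_seed(seed, {
    chain_in <- 1L
    for (chain in seq_len(spec$chain_length)) {
      cur <- add_step("conv", chain_in, layer = add_layer(new_conv_layer(ch[1], spec$in_channels)))
      cur <- add_step("lrelu", cur, alpha = 0.2)
      skips <- integer(spec$depth)
      skips[1] <- cur
      for (l in seq_len(spec$depth)) {
        cur <- add_step("pool", cur)
        cur <- add_step("conv", cur, layer = add_layer(new_conv_layer(ch[l + 1], ch[l])))
        cur <- add_step("lrelu", cur, alpha = 0.2)
        if (l < spec$depth) skips[l + 1] <- cur
      }
      for (l in rev(seq_len(spec$depth))) {
        cur <- add_step("up", cur)
        cur <- add_step("concat", skips[l], cur)
        cur <- add_step("conv", cur, layer = add_layer(new_conv_layer(ch[l], ch[l] + ch[l + 1])))
        cur <- add_step("lrelu", cur, alpha = 0.2)
      }
      cur <- add_step("conv", cur, layer = add_layer(new_conv_layer(spec$in_channels, ch[1], init = "zero")))
      cur <- add_step("add", chain_in, cur)
      chain_in <- cur
    }
  })
  structure(list(spec = spec, layers = layers, steps = steps,
                 n_buffers = nb, out_buffer = nb, seed = as.integer(seed)),
            class = "recon_network")
}

#' @export
print.recon_network <- function(x, ...) {
  cat(sprintf("<recon_network> depth %d, base %d, chain %d: %d conv layers\n",
              x$spec$depth, x$spec$base_channels, x$spec$chain_length, length(x$layers)))
  invisible(x)
}

net_has_ss <- function(net) any(vapply(net$layers, function(l) !is.null(l$ss) || !is.null(l$rft), logical(1)))

net_layer_shapes <- function(net) lapply(net$layers, function(l) dim(l$w))

#' Insert identity-initialized factors into every convolution layer
#'
#' Adds per-kernel scaling/shifting factors (`granularity = "kernel"`, the
#' LFT parameterization) or per-row factors (`granularity = "row"`, RFT) to
#' each layer. Factors start at the identity (scale 1, shift 0), so the
#' network's outputs are unchanged by insertion; the pre-existing weights are
#' untouched.
#'
#' @param net a [build_generator()] network without factors.
#' @param granularity `"kernel"` or `"row"`.
#' @param include_shift for `"row"`, whether the per-kernel shift is trainable.
#' @return The network with factors inserted.
#' @export
insert_ss <- function(net, granularity = c("kernel", "row"), include_shift = TRUE) {
  granularity <- match.arg(granularity)
  if (net_has_ss(net)) stop("network already has SS blocks (state error)", call. = FALSE)
  net$layers <- lapply(net$layers, function(l) {
    bank <- conv_bank(l$w, l$b)
    if (granularity == "kernel") l$ss <- ss_factors(bank)
    else l$rft <- row_factors(bank, include_shift = include_shift)
    l
  })
  net
}

# Effective (folded) weights and bias of a layer, honoring any factors.
layer_effective <- function(l) {
  if (!is.null(l$ss)) {
    list(w = l$w * as.vector(l$ss$scale), b = l$b + rowSums(l$ss$shift))
  } else if (!is.null(l$rft)) {
    list(w = l$w * as.vector(l$rft$row_scale), b = l$b + rowSums(l$rft$shift))
  } else list(w = l$w, b = l$b)
}

#' Fold all factors into the weights, yielding a plain network
#'
#' Layerwise weight merging: each layer's factors are absorbed into its
#' weights and bias and then dropped. The folded network computes identical
#' outputs without the factor overhead — the deployment form of an adapted
#' model.
#'
#' @param net a network with factors inserted.
#' @return An equivalent plain `recon_network`.
#' @export
fold_network <- function(net) {
  net$layers <- lapply(net$layers, function(l) {
    eff <- layer_effective(l)
    list(w = eff$w, b = eff$b, ss = NULL, rft = NULL)
  })
  net
}

#' Network forward pass
#'
#' Runs the generator on a 2-channel (real/imaginary) zero-filled image.
#' Spatial dimensions must be divisible by `2^depth` per chained U-net.
#'
#' @param net a `recon_network`.
#' @param x 3D array, dim `(in_channels, H, W)`.
#' @param keep_buffers return intermediate buffers (needed for backprop and
#'   feature-map extraction).
#' @return The output array `(in_channels, H, W)`, or a list
#'   `(out, buffers)` when `keep_buffers = TRUE`.
#' @export
net_forward <- function(net, x, keep_buffers = FALSE) {
  check_feature_tensor(x)
  d <- dim(x)
  div <- 2^net$spec$depth
  if (d[2] %% div != 0 || d[3] %% div != 0)
    stop(sprintf("spatial dims (%d x %d) must be divisible by %d; pad the input first (shape error)",
                 d[2], d[3], div), call. = FALSE)
  bufs <- vector("list", net$n_buffers)
  bufs[[1L]] <- x
  for (s in net$steps) {
    bufs[[s$out]] <- switch(s$op,
      conv = {
        l <- net$layers[[s$layer]]
        eff <- layer_effective(l)
        xin <- bufs[[s$in1]]; di <- dim(xin); dw <- dim(eff$w)
        cc_conv2d(as.numeric(xin), as.numeric(eff$w), eff$b,
                  dw[2], di[2], di[3], dw[1], dw[3], dw[4])
      },
      lrelu = {
        v <- bufs[[s$in1]]
        pmax(v, 0) + s$alpha * pmin(v, 0)
      },
      pool = pool2_avg(bufs[[s$in1]]),
      up = up2_nearest(bufs[[s$in1]]),
      concat = concat_channels(bufs[[s$in1]], bufs[[s$in2]]),
      add = bufs[[s$in1]] + bufs[[s$in2]],
      stop("unknown op: ", s$op))
  }
  if (keep_buffers) list(out = bufs[[net$out_buffer]], buffers = bufs)
  else bufs[[net$out_buffer]]
}

pool2_avg <- function(x) {
  d <- dim(x); oh <- seq(1L, d[2], 2L); ow <- seq(1L, d[3], 2L)
  (x[, oh, ow, drop = FALSE] + x[, oh + 1L, ow, drop = FALSE] +
     x[, oh, ow + 1L, drop = FALSE] + x[, oh + 1L, ow + 1L, drop = FALSE]) / 4
}

up2_nearest <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

# Backward pass through the tape. Returns per-layer gradients w.r.t. the
# *effective* weights/bias; strategy-specific parameter gradients (factors vs
# raw weights) are derived from these at update time.
net_backward <- function(net, bufs, gout) {
  g <- vector("list", net$n_buffers)
  g[[net$out_buffer]] <- gout
  lgrads <- vector("list", length(net$layers))
  acc <- function(id, val) g[[id]] <<- if (is.null(g[[id]])) val else g[[id]] + val
  for (s in rev(net$steps)) {
    gy <- g[[s$out]]
    if (is.null(gy)) next
    switch(s$op,
      conv = {
        l <- net$layers[[s$layer]]
        eff <- layer_effective(l)
        xin <- bufs[[s$in1]]; di <- dim(xin); dw <- dim(eff$w)
        gx <- cc_conv2d_grad_input(as.numeric(gy), as.numeric(eff$w),
                                   dw[2], di[2], di[3], dw[1], dw[3], dw[4])
        gw <- cc_conv2d_grad_weights(as.numeric(xin), as.numeric(gy),
                                     dw[2], di[2], di[3], dw[1], dw[3], dw[4])
        gb <- rowSums(matrix(gy, dw[1]))
        lgrads[[s$layer]] <- list(gw = gw, gb = gb)
        acc(s$in1, gx)
      },
      lrelu = {
        v <- bufs[[s$in1]]
        acc(s$in1, gy * ((v > 0) + s$alpha * (v <= 0)))
      },
      pool = {
        d <- dim(bufs[[s$in1]])
        gx <- array(0, d)
        oh <- seq(1L, d[2], 2L); ow <- seq(1L, d[3], 2L)
        q <- gy / 4
        gx[, oh, ow] <- q; gx[, oh + 1L, ow] <- q
        gx[, oh, ow + 1L] <- q; gx[, oh + 1L, ow + 1L] <- q
        acc(s$in1, gx)
      },
      up = {
        d <- dim(gy); oh <- seq(1L, d[2], 2L); ow <- seq(1L, d[3], 2L)
        acc(s$in1, gy[, oh, ow, drop = FALSE] + gy[, oh + 1L, ow, drop = FALSE] +
              gy[, oh, ow + 1L, drop = FALSE] + gy[, oh + 1L, ow + 1L, drop = FALSE])
      },
      concat = {
        c1 <- dim(bufs[[s$in1]])[1]
        acc(s$in1, gy[seq_len(c1), , , drop = FALSE])
        acc(s$in2, gy[c1 + seq_len(dim(bufs[[s$in2]])[1]), , , drop = FALSE])
      },
      add = {
        acc(s$in1, gy)
        acc(s$in2, gy)
      })
  }
  lgrads
}

#' Extract a checkpoint (deep copy of all layer parameters)
#'
#' @param net a `recon_network`.
#' @return The list of layers (weights, biases, factors).
#' @export
net_checkpoint <- function(net) net$layers

#' Restore layer parameters from a checkpoint
#'
#' @param net a `recon_network` whose architecture matches the checkpoint.
#' @param checkpoint a [net_checkpoint()] result.
#' @param backbone_only restore only weights/biases, keeping any factors the
#'   network currently carries (used when adapting a pre-trained model).
#' @return The network with restored parameters.
#' @export
net_restore <- function(net, checkpoint, backbone_only = FALSE) {
  if (length(checkpoint) != length(net$layers))
    stop("checkpoint layer count does not match the network (compatibility error)", call. = FALSE)
  for (i in seq_along(checkpoint)) {
    if (!identical(dim(checkpoint[[i]]$w), dim(net$layers[[i]]$w)))
      stop("checkpoint layer shapes do not match the network (compatibility error)", call. = FALSE)
    net$layers[[i]]$w <- checkpoint[[i]]$w
    net$layers[[i]]$b <- checkpoint[[i]]$b
    if (!backbone_only) {
      net$layers[[i]]$ss <- checkpoint[[i]]$ss
      net$layers[[i]]$rft <- checkpoint[[i]]$rft
    }
  }
  net
}

#' Trainable parameters of a network under a strategy
#'
#' @param net a `recon_network`.
#' @param strategy `"PT"`, `"DT"`, `"FT"`, `"RFT"`, or `"LFT"`.
#' @return Integer count; equals [count_trainable()] over the layer shapes.
#' @export
net_trainable_count <- function(net, strategy) {
  strategy <- toupper(strategy)
  if (strategy == "RFT") {
    # honor include_shift = FALSE row factors
    n <- 0L
    for (l in net$layers) {
      d <- dim(l$w)
      n <- n + d[1] * d[2] * d[3] +
        if (is.null(l$rft) || isTRUE(l$rft$include_shift)) d[1] * d[2] else 0L
    }
    return(as.integer(n))
  }
  count_trainable(strategy, net_layer_shapes(net))
}

#' Save/load a network as a JSON checkpoint
#'
#' The document holds a JSON architecture descriptor plus, per layer, groups
#' `weights`, `bias` and (if present) `ss/scale`, `ss/shift` in the
#' `layout = "NMHW"` convention used by [write_bank()].
#'
#' @param net a `recon_network`.
#' @param path file to write.
#' @export
save_network <- function(net, path) {
  doc <- list(
    arch = list(depth = net$spec$depth, base_channels = net$spec$base_channels,
                chain_length = net$spec$chain_length, in_channels = net$spec$in_channels,
                seed = net$seed),
    layout = "NMHW",
    layers = lapply(net$layers, function(l) {
      out <- list(dim = as.integer(dim(l$w)), weights = as.numeric(l$w),
                  bias = as.numeric(l$b))
      if (!is.null(l$ss))
        out$ss <- list(scale = as.numeric(l$ss$scale), shift = as.numeric(l$ss$shift))
      if (!is.null(l$rft))
        out$rft <- list(row_scale = as.numeric(l$rft$row_scale),
                        shift = as.numeric(l$rft$shift),
                        include_shift = l$rft$include_shift)
      out
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  arch <- lapply(doc$arch, function(x) unlist(x))
  spec <- network_spec(depth = arch$depth, base_channels = arch$base_channels,
                       chain_length = arch$chain_length, in_channels = arch$in_channels)
  net <- build_generator(spec, seed = arch$seed)
  for (i in seq_along(net$layers)) {
    li <- doc$layers[[i]]
    d <- as.integer(unlist(li$dim))
    net$layers[[i]]$w <- array(as.numeric(unlist(li$weights)), d)
    net$layers[[i]]$b <- as.numeric(unlist(li$bias))
    if (!is.null(li$ss)) {
      bank <- conv_bank(net$layers[[i]]$w, net$layers[[i]]$b)
      net$layers[[i]]$ss <- ss_factors(
        bank, scale = matrix(as.numeric(unlist(li$ss$scale)), d[1], d[2]),
        shift = matrix(as.numeric(unlist(li$ss$shift)), d[1], d[2]))
    }
    if (!is.null(li$rft)) {
      bank <- conv_bank(net$layers[[i]]$w, net$layers[[i]]$b)
      net$layers[[i]]$rft <- row_factors(
        bank, row_scale = array(as.numeric(unlist(li$rft$row_scale)), d[1:3]),
        shift = matrix(as.numeric(unlist(li$rft$shift)), d[1], d[2]),
        include_shift = isTRUE(unlist(li$rft$include_shift)))
    }
  }
  net
}

#' Per-layer table of a network with per-strategy trainable counts
#'
#' @param net a `recon_network`.
#' @return Data frame with one row per convolution layer.
#' @export
describe_net <- function(net) {
  shapes <- net_layer_shapes(net)
  df <- do.call(rbind, lapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    data.frame(layer = i, N = s[1], M = s[2], k_h = s[3], k_w = s[4],
               ft_params = count_trainable("FT", list(s)),
               rft_params = count_trainable("RFT", list(s)),
               lft_params = count_trainable("LFT", list(s)))
  }))
  df
}
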