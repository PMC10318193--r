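#' Training configuration for a transfer strategy
#'
#' Captures which weights train and the optimization protocol: Adam with a
#' constant learning rate, early stopping once the validation PSNR has not
#' strictly improved within `patience` epochs, and the best-validation
#' checkpoint returned. Default learning rates: 1e-4 for pre-training, DT
#' and LFT/RFT; 1e-5 for FT (fewer trainable parameters tolerate larger
#' steps, so the factor-based strategies keep the pre-training rate).
#'
#' @param strategy `"PT"`, `"DT"`, `"FT"`, `"RFT"`, or `"LFT"`.
#' @param learning_rate Adam step size (> 0); `NULL` picks the per-strategy
#'   default.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience in epochs (>= 1, default 15).
#' @param batch_size examples per optimizer step.
#' @param seed integer; all randomness of the run (shuffling, any random
#'   init) flows from it.
#' @param loss `"l2"` (default; squared error on magnitude, matching the
#'   PSNR model-selection criterion) or `"l1"`.
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(strategy = c("LFT", "PT", "DT", "FT", "RFT"),
                            learning_rate = NULL, max_epochs = 100, patience = 15,
                            batch_size = 1, seed = 0, loss = c("l2", "l1")) {
  strategy <- toupper(strategy[1])
  if (!strategy %in% c("PT", "DT", "FT", "RFT", "LFT"))
    stop("unknown strategy: ", strategy, call. = FALSE)
  loss <- match.arg(loss)
  learning_rate <- learning_rate %||% switch(strategy, FT = 1e-5, 1e-4)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (patience < 1) stop("patience must be >= 1", call. = FALSE)
  structure(list(strategy = strategy, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = loss), class = "strategy_config")
}

#' Dataset split specification
#'
#' @param ratio positive integer parts for train:validation:test
#'   (default 16:5:4).
#' @param train_subset_size optionally restrict the training split to its
#'   first `train_subset_size` members (for training-set-size sweeps);
#'   validation and test are unchanged.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(ratio = c(16, 5, 4), train_subset_size = NULL) {
  if (length(ratio) != 3 || any(ratio <= 0)) stop("ratio needs 3 positive parts", call. = FALSE)
  structure(list(ratio = ratio, train_subset_size = train_subset_size),
            class = "split_spec")
}

#' Split a dataset into train/validation/test
#'
#' Disjoint, exhaustive partition in the ratio's proportions using
#' largest-remainder rounding, after a seeded shuffle. With the default
#' 16:5:4 ratio, 25 images split exactly 16/5/4 and 100 split 64/20/16.
#'
#' @param images list of images (or any objects).
#' @param spec a [split_spec()].
#' @param seed integer seed for the shuffle.
#' @return List with `train`, `val`, `test`.
#' @export
split_dataset <- function(images, spec = split_spec(), seed = 0) {
  n <- length(images)
  if (n < sum(spec$ratio))
    stop(sprintf("need at least %d images for ratio %s (size error)",
                 sum(spec$ratio), paste(spec$ratio, collapse = ":")), call. = FALSE)
  quota <- n * spec$ratio / sum(spec$ratio)
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(quota - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  idx <- with_seed(seed, sample(n))
  train <- images[idx[seq_len(counts[1])]]
  val <- images[idx[counts[1] + seq_len(counts[2])]]
  test <- images[idx[counts[1] + counts[2] + seq_len(counts[3])]]
  if (!is.null(spec$train_subset_size)) {
    if (spec$train_subset_size > length(train))
      stop("train_subset_size exceeds the training split (size error)", call. = FALSE)
    train <- train[seq_len(spec$train_subset_size)]
  }
  list(train = train, val = val, test = test)
}

#' Early-stopping decision
#'
#' Stop once `current_epoch - best_epoch >= patience`, i.e. the validation
#' PSNR has not strictly improved within `patience` epochs. Ties do not
#' update the best epoch.
#'
#' @param history a `training_history` (or data frame with `epoch` and
#'   `val_psnr`).
#' @param patience epochs without strict improvement tolerated.
#' @return Logical.
#' @export
early_stop_check <- function(history, patience = 15) {
  if (nrow(history) == 0) stop("history is empty", call. = FALSE)
  best_epoch <- attr(history, "best_epoch") %||% history$epoch[which.max(history$val_psnr)]
  current <- max(history$epoch)
  (current - best_epoch) >= patience
}

# -- internals ---------------------------------------------------------------

# Build (input, target) training pairs: complex zero-filled image in, fully
# sampled magnitude out.
prepare_examples <- function(images, mask) {
  lapply(images, function(img) {
    if (inherits(img, "labeled_slice")) img <- img$image
    list(x = zf_complex(img, mask), target = img)
  })
}

magnitude2 <- function(y) sqrt(y[1, , ]^2 + y[2, , ]^2 + 1e-16)

# L1/L2 loss on magnitude and its gradient w.r.t. the 2-channel output.
loss_and_grad <- function(y, target, loss = "l1") {
  m <- magnitude2(y)
  diff <- m - target
  npix <- length(target)
  if (loss == "l1") {
    l <- mean(abs(diff))
    dm <- sign(diff) / npix
  } else {
    l <- mean(diff^2)
    dm <- 2 * diff / npix
  }
  g <- array(0, dim(y))
  g[1, , ] <- dm * y[1, , ] / m
  g[2, , ] <- dm * y[2, , ] / m
  list(loss = l, grad = g)
}

# Named list of trainable parameter slots for a strategy.
trainable_params <- function(net, strategy) {
  params <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (strategy %in% c("DT", "FT")) {
      params[[length(params) + 1L]] <- list(layer = i, field = "w")
      params[[length(params) + 1L]] <- list(layer = i, field = "b")
    } else if (strategy == "LFT") {
      if (is.null(l$ss)) stop("LFT requires SS blocks (state error)", call. = FALSE)
      params[[length(params) + 1L]] <- list(layer = i, field = "scale")
      params[[length(params) + 1L]] <- list(layer = i, field = "shift")
    } else if (strategy == "RFT") {
      if (is.null(l$rft)) stop("RFT requires row factors (state error)", call. = FALSE)
      params[[length(params) + 1L]] <- list(layer = i, field = "row_scale")
      if (isTRUE(l$rft$include_shift))
        params[[length(params) + 1L]] <- list(layer = i, field = "shift")
    }
  }
  params
}

get_param <- function(net, p) {
  l <- net$layers[[p$layer]]
  switch(p$field, w = l$w, b = l$b, scale = l$ss$scale, shift = l$ss$shift %||% l$rft$shift,
         row_scale = l$rft$row_scale)
}

set_param <- function(net, p, value) {
  switch(p$field,
         w = net$layers[[p$layer]]$w <- value,
         b = net$layers[[p$layer]]$b <- value,
         scale = net$layers[[p$layer]]$ss$scale <- value,
         shift = {
           if (!is.null(net$layers[[p$layer]]$ss)) net$layers[[p$layer]]$ss$shift <- value
           else net$layers[[p$layer]]$rft$shift <- value
         },
         row_scale = net$layers[[p$layer]]$rft$row_scale <- value)
  net
}

# Map effective-weight gradients onto a strategy's parameter gradients.
param_grad <- function(net, p, lgrads) {
  g <- lgrads[[p$layer]]
  if (is.null(g)) return(NULL)
  l <- net$layers[[p$layer]]
  d <- dim(l$w)
  switch(p$field,
    w = g$gw,
    b = g$gb,
    # d(eff_w)/d(scale[n,m]) = w[n,m,,]; chain rule sums over the kernel
    scale = matrix(rowSums(matrix(l$w * g$gw, d[1] * d[2])), d[1], d[2]),
    # d(eff_b)/d(shift[n,m]) = 1 for every m of filter n
    shift = matrix(g$gb, d[1], d[2]),
    row_scale = array(rowSums(matrix(l$w * g$gw, d[1] * d[2] * d[3])), d[1:3]))
}

adam_init <- function(params, net) {
  lapply(params, function(p) {
    v <- get_param(net, p)
    list(m = array(0, dim(v) %||% length(v)), v = array(0, dim(v) %||% length(v)))
  })
}

adam_step <- function(net, params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * as.numeric(g)
    st$v <- beta2 * st$v + (1 - beta2) * as.numeric(g)^2
    state[[i]] <- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    val <- get_param(net, params[[i]])
    upd <- array(lr * mhat / (sqrt(vhat) + eps), dim(val) %||% length(val))
    if (is.null(dim(val))) upd <- as.numeric(upd)
    net <- set_param(net, params[[i]], val - upd)
  }
  list(net = net, state = state)
}

# Mean validation PSNR of a network over (input, target) examples.
validation_psnr <- function(net, examples) {
  vals <- vapply(examples, function(ex) {
    rec <- magnitude2(net_forward(net, ex$x))
    psnr(ex$target, rec, 1)
  }, numeric(1))
  mean(vals[is.finite(vals)])
}

# Core optimization loop shared by pretrain() and transfer(). Returns the
# best-validation checkpoint and the full history.
train_loop <- function(net, train_examples, val_examples, config, strategy) {
  params <- trainable_params(net, strategy)
  state <- adam_init(params, net)
  initial_val <- validation_psnr(net, val_examples)
  best_val <- -Inf
  best_epoch <- 0L
  best_layers <- net$layers
  hist <- data.frame(epoch = integer(), train_loss = numeric(), val_psnr = numeric())
  t_adam <- 0L
  n_train <- length(train_examples)
  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- with_seed(derive_seed(config$seed, 101, epoch), sample(n_train))
    epoch_loss <- 0
    batch_grads <- NULL
    in_batch <- 0L
    for (ii in seq_along(order_idx)) {
      ex <- train_examples[[order_idx[ii]]]
      fw <- net_forward(net, ex$x, keep_buffers = TRUE)
      lg <- loss_and_grad(fw$out, ex$target, config$loss)
      epoch_loss <- epoch_loss + lg$loss
      lgrads <- net_backward(net, fw$buffers, lg$grad)
      pg <- lapply(params, function(p) param_grad(net, p, lgrads))
      batch_grads <- if (is.null(batch_grads)) pg else
        mapply(function(a, b) if (is.null(a)) b else a + b, batch_grads, pg, SIMPLIFY = FALSE)
      in_batch <- in_batch + 1L
      if (in_batch == config$batch_size || ii == n_train) {
        batch_grads <- lapply(batch_grads, function(g) if (is.null(g)) NULL else g / in_batch)
        t_adam <- t_adam + 1L
        stepped <- adam_step(net, params, batch_grads, state, t_adam, config$learning_rate)
        net <- stepped$net; state <- stepped$state
        batch_grads <- NULL; in_batch <- 0L
      }
    }
    val <- validation_psnr(net, val_examples)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = epoch_loss / n_train,
                                   val_psnr = val))
    if (isTRUE(val > best_val) || best_epoch == 0L) {  # strict improvement; ties do not update
      best_val <- val
      best_epoch <- epoch
      best_layers <- net$layers
    }
    attr(hist, "best_epoch") <- best_epoch
    if (early_stop_check(hist, config$patience)) break
  }
  net$layers <- best_layers
  attr(hist, "best_epoch") <- best_epoch
  attr(hist, "stopped_epoch") <- if (nrow(hist)) max(hist$epoch) else 0L
  attr(hist, "initial_val_psnr") <- initial_val
  attr(hist, "best_val_psnr") <- if (is.finite(best_val)) best_val else initial_val
  attr(hist, "trainable_count") <- net_trainable_count(net, strategy)
  class(hist) <- c("training_history", class(hist))
  list(net = net, history = hist)
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("<training_history> %d epochs, best epoch %d (val PSNR %.3f dB), %d trainable params\n",
              nrow(x), attr(x, "best_epoch"), attr(x, "best_val_psnr"),
              attr(x, "trainable_count")))
  invisible(x)
}

#' Pre-train a reconstruction network on source-domain data
#'
#' Classic pre-training: all weights and biases train from their random
#' initialization (the network must not carry SS blocks). The checkpoint
#' with the highest validation PSNR is returned together with the per-epoch
#' history.
#'
#' @param net a plain [build_generator()] network.
#' @param source_data list with `train` and `val` image lists (matrices in
#'   `[0, 1]`, or `labeled_slice`s).
#' @param config a [strategy_config()] (its strategy field is ignored; all
#'   weights train).
#' @param mask the sampling mask defining the undersampling forward model.
#' @return List with `net` (best checkpoint) and `history`.
#' @export
pretrain <- function(net, source_data, config, mask) {
  if (net_has_ss(net)) stop("pre-training expects a network without SS blocks (state error)", call. = FALSE)
  if (!length(source_data$train)) stop("empty training set (size error)", call. = FALSE)
  train_ex <- prepare_examples(source_data$train, mask)
  val_ex <- prepare_examples(source_data$val, mask)
  train_loop(net, train_ex, val_ex, config, strategy = "DT")
}

#' Adapt a pre-trained network to a target domain
#'
#' Applies the configured strategy's freezing contract:
#' * `PT` — no training; the pre-trained checkpoint is evaluated as-is.
#' * `DT` — random re-initialization (from `config$seed`); all weights train.
#' * `FT` — pre-trained initialization; all weights train.
#' * `LFT` — pre-trained initialization; only the per-kernel scale/shift
#'   factors train and the backbone stays bitwise identical.
#' * `RFT` — as LFT with per-row scales.
#'
#' For LFT/RFT the network must already carry identity-initialized factors
#' (see [insert_ss()]).
#'
#' @param net a `recon_network` (with factors inserted for LFT/RFT).
#' @param pretrained_checkpoint a [net_checkpoint()] of the pre-trained model.
#' @param target_data list with `train` and `val` image lists.
#' @param config a [strategy_config()].
#' @param mask the sampling mask.
#' @return List with `net` and `history`.
#' @export
transfer <- function(net, pretrained_checkpoint, target_data, config, mask) {
  strategy <- config$strategy
  if (strategy %in% c("LFT", "RFT")) {
    needed <- if (strategy == "LFT") "ss" else "rft"
    if (!all(vapply(net$layers, function(l) !is.null(l[[needed]]), logical(1))))
      stop(strategy, " requested on a network without the matching factor blocks (state error)",
           call. = FALSE)
    net <- net_restore(net, pretrained_checkpoint, backbone_only = TRUE)
  } else if (strategy %in% c("PT", "FT")) {
    net <- net_restore(net, pretrained_checkpoint)
  } else if (strategy == "DT") {
    net <- build_generator(net$spec, seed = derive_seed(config$seed, 211))
  }
  if (strategy == "PT") {
    val_ex <- prepare_examples(target_data$val, mask)
    initial_val <- validation_psnr(net, val_ex)
    hist <- data.frame(epoch = integer(), train_loss = numeric(), val_psnr = numeric())
    attr(hist, "best_epoch") <- 0L
    attr(hist, "stopped_epoch") <- 0L
    attr(hist, "initial_val_psnr") <- initial_val
    attr(hist, "best_val_psnr") <- initial_val
    attr(hist, "trainable_count") <- 0L
    class(hist) <- c("training_history", class(hist))
    return(list(net = net, history = hist))
  }
  if (!length(target_data$train)) stop("empty training set (size error)", call. = FALSE)
  train_ex <- prepare_examples(target_data$train, mask)
  val_ex <- prepare_examples(target_data$val, mask)
  train_loop(net, train_ex, val_ex, config, strategy)
}

#' Evaluate reconstructions of a model on a test set
#'
#' Computes per-image PSNR/SSIM/WPSNR of the model's reconstruction against
#' the fully-sampled reference. `model = "ZF"` scores the zero-filled
#' baseline instead of a network.
#'
#' @param net a `recon_network`, or `NULL` for the zero-filled baseline.
#' @param images list of reference images.
#' @param mask the sampling mask.
#' @param model label for the output rows.
#' @param metrics subset of `c("psnr", "ssim", "wpsnr")`.
#' @return Data frame with one row per image.
#' @export
evaluate_model <- function(net, images, mask, model = "model",
                           metrics = c("psnr", "ssim", "wpsnr")) {
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    if (inherits(img, "labeled_slice")) img <- img$image
    rec <- if (is.null(net)) zero_filled_recon(undersample(to_kspace(img), mask))
           else magnitude2(net_forward(net, zf_complex(img, mask)))
    out <- data.frame(model = model, image = i)
    if ("psnr" %in% metrics) out$psnr <- psnr(img, rec, 1)
    if ("ssim" %in% metrics) out$ssim <- ssim(img, rec, 1)
    if ("wpsnr" %in% metrics) out$wpsnr <- wpsnr(img, rec, 1)
    out
  })
  do.call(rbind, rows)
}
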