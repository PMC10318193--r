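#' Convolution filter banks and scaling/shifting (SS) factors
#'
#' A convolution layer is viewed as a bank of `N` filters, each holding `M`
#' kernels of size `k_h x k_w` plus one bias per filter. Under linear
#' fine-tuning (LFT) the bank is frozen and a pair of per-kernel factors is
#' learned instead: a scaling factor that multiplies every weight of the
#' kernel, and a shifting factor added to the filter output. Identity factors
#' (scale 1, shift 0) leave the layer's output unchanged, so inserting them
#' into a pre-trained network is output-preserving.
#'
#' @param weights 4D array, dim `(N, M, k_h, k_w)`; kernel sizes must be odd.
#' @param bias numeric vector of length `N` (one bias per filter).
#' @return An object of class `conv_bank`.
#' @examples
#' bank <- conv_bank(array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3)), bias = c(0, 0.1))
#' f <- ss_factors(bank)            # identity factors
#' u <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
#' max(abs(ss_forward(u, bank, f) - conv_forward(u, bank)))  # ~ 0
#' @export
conv_bank <- function(weights, bias) {
  if (!is.array(weights) || length(dim(weights)) != 4L)
    stop("weights must be a 4D array with dim (N, M, k_h, k_w)", call. = FALSE)
  d <- dim(weights)
  if (d[3] %% 2L == 0L || d[4] %% 2L == 0L)
    stop("kernel sizes must be odd (even-sized kernels are rejected)", call. = FALSE)
  stopifnot_finite(weights, "weights")
  bias <- as.numeric(bias)
  if (length(bias) != d[1]) stop("bias must have one entry per filter (length N)", call. = FALSE)
  stopifnot_finite(bias, "bias")
  structure(list(weights = weights, bias = bias), class = "conv_bank")
}

#' @export
print.conv_bank <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<conv_bank> %d filters x %d kernels of %dx%d (%d weights + %d biases)\n",
              d[1], d[2], d[3], d[4], prod(d), d[1]))
  invisible(x)
}

#' Per-kernel scaling and shifting factors
#'
#' One scaling factor and one shifting factor per (filter, input-channel)
#' kernel. The identity state (`scale = 1`, `shift = 0`) is the
#' initialization used when the factors are inserted into a pre-trained
#' network, so that training starts from the pre-trained model's output.
#'
#' @param bank a [conv_bank()] the factors belong to (defines the `(N, M)` shape).
#' @param scale,shift optional `N x M` matrices; default to the identity state.
#' @return An object of class `ss_factors`.
#' @export
ss_factors <- function(bank, scale = NULL, shift = NULL) {
  d <- dim(bank$weights)
  scale <- scale %||% matrix(1, d[1], d[2])
  shift <- shift %||% matrix(0, d[1], d[2])
  if (!identical(dim(scale), d[1:2]) || !identical(dim(shift), d[1:2]))
    stop("factor shapes must match the owning bank's (N, M)", call. = FALSE)
  stopifnot_finite(scale, "scale"); stopifnot_finite(shift, "shift")
  structure(list(scale = scale, shift = shift), class = "ss_factors")
}

#' Row-wise transformation factors
#'
#' Intermediate granularity between full fine-tuning and per-kernel factors:
#' one learned scale for all elements in a single kernel row, plus (by
#' default) one shift per kernel as under LFT. The shift can be dropped with
#' `include_shift = FALSE`, in which case it is kept at zero and not trained.
#'
#' @param bank a [conv_bank()].
#' @param row_scale optional `N x M x k_h` array (identity = all 1).
#' @param shift optional `N x M` matrix (identity = all 0).
#' @param include_shift logical; whether the per-kernel shift is trainable.
#' @return An object of class `row_factors`.
#' @export
row_factors <- function(bank, row_scale = NULL, shift = NULL, include_shift = TRUE) {
  d <- dim(bank$weights)
  row_scale <- row_scale %||% array(1, c(d[1], d[2], d[3]))
  shift <- shift %||% matrix(0, d[1], d[2])
  if (!identical(dim(row_scale), d[1:3]))
    stop("row_scale must have dim (N, M, k_h) matching the bank", call. = FALSE)
  if (!identical(dim(shift), d[1:2]))
    stop("shift must have dim (N, M) matching the bank", call. = FALSE)
  stopifnot_finite(row_scale, "row_scale"); stopifnot_finite(shift, "shift")
  structure(list(row_scale = row_scale, shift = shift,
                 include_shift = isTRUE(include_shift)), class = "row_factors")
}

#' Basic features: the output of a single kernel
#'
#' Cross-correlates one input channel with one odd-sized kernel (zero "same"
#' padding, stride 1) and adds the kernel's bias elementwise. Basic features
#' are the building blocks that per-filter feature maps (advanced features)
#' are linear combinations of.
#'
#' @param input_channel 2D numeric matrix.
#' @param kernel_weights odd-sized `k x k` (or `k_h x k_w`) numeric matrix.
#' @param kernel_bias scalar added to every output pixel.
#' @return Matrix of the same size as `input_channel`.
#' @export
basic_features <- function(input_channel, kernel_weights, kernel_bias = 0) {
  if (!is.matrix(input_channel)) input_channel <- as.matrix(input_channel)
  stopifnot_finite(input_channel, "input channel")
  if (!is.matrix(kernel_weights)) kernel_weights <- as.matrix(kernel_weights)
  kd <- dim(kernel_weights)
  if (kd[1] %% 2L == 0L || kd[2] %% 2L == 0L)
    stop("kernel sizes must be odd (even-sized kernels are rejected)", call. = FALSE)
  h <- nrow(input_channel); w <- ncol(input_channel)
  y <- cc_conv2d(as.numeric(input_channel), as.numeric(kernel_weights),
                 as.numeric(kernel_bias), 1L, h, w, 1L, kd[1], kd[2])
  matrix(y, h, w)
}

#' Advanced features: the feature map of one filter
#'
#' The per-filter output channel, computed explicitly as the sum over input
#' channels of the per-kernel basic features (the same summation order the
#' decomposition states), with the filter's bias distributed equally across
#' its kernels so that the per-kernel biases add back up to the filter bias.
#'
#' @param input 3D array, dim `(M, H, W)`.
#' @param filterbank a [conv_bank()] with `M` kernels per filter.
#' @param filter_index which filter (1-based, `1..N`).
#' @return `H x W` matrix, channel `filter_index` of the layer output.
#' @export
advanced_features <- function(input, filterbank, filter_index) {
  check_feature_tensor(input)
  d <- dim(filterbank$weights)
  if (dim(input)[1] != d[2])
    stop(sprintf("input has %d channels but the bank expects M = %d",
                 dim(input)[1], d[2]), call. = FALSE)
  if (filter_index < 1L || filter_index > d[1])
    stop("filter_index out of range", call. = FALSE)
  b_per_kernel <- filterbank$bias[filter_index] / d[2]
  out <- NULL
  for (m in seq_len(d[2])) {
    vb <- basic_features(input[m, , ], filterbank$weights[filter_index, m, , ],
                         b_per_kernel)
    out <- if (is.null(out)) vb else out + vb
  }
  out
}

#' Plain convolution with a filter bank
#'
#' Cross-correlation of a multi-channel input with every filter of the bank
#' (zero "same" padding, stride 1), adding the per-filter bias.
#'
#' @param input 3D array, dim `(M, H, W)`.
#' @param filterbank a [conv_bank()].
#' @return 3D array, dim `(N, H, W)`.
#' @export
conv_forward <- function(input, filterbank) {
  check_feature_tensor(input)
  d <- dim(filterbank$weights); di <- dim(input)
  if (di[1] != d[2])
    stop(sprintf("input has %d channels but the bank expects M = %d", di[1], d[2]),
         call. = FALSE)
  cc_conv2d(as.numeric(input), as.numeric(filterbank$weights), filterbank$bias,
            d[2], di[2], di[3], d[1], d[3], d[4])
}

#' SS-modulated convolution (the LFT forward pass)
#'
#' Output channel `n` is `sum_m U_m (x) (scale[n,m] * W[n,m]) + b[n] +
#' sum_m shift[n,m]`: each kernel's contribution is scaled by its factor and
#' the per-kernel shifts accumulate on top of the frozen filter bias. This
#' routine follows the per-kernel route deliberately; [fold_ss()] followed by
#' [conv_forward()] is the algebraically equivalent folded route.
#'
#' @param input 3D array, dim `(M, H, W)`.
#' @param filterbank a [conv_bank()].
#' @param factors an [ss_factors()] whose shape matches the bank.
#' @return 3D array, dim `(N, H, W)`.
#' @export
ss_forward <- function(input, filterbank, factors) {
  check_feature_tensor(input)
  d <- dim(filterbank$weights)
  if (!inherits(factors, "ss_factors") || !identical(dim(factors$scale), d[1:2]))
    stop("factor shapes do not match the bank (configuration error)", call. = FALSE)
  if (dim(input)[1] != d[2]) stop("input channel count must equal M", call. = FALSE)
  H <- dim(input)[2]; W <- dim(input)[3]
  out <- array(0, c(d[1], H, W))
  for (n in seq_len(d[1])) {
    acc <- matrix(filterbank$bias[n] + sum(factors$shift[n, ]), H, W)
    for (m in seq_len(d[2])) {
      k <- factors$scale[n, m] * filterbank$weights[n, m, , ]
      acc <- acc + basic_features(input[m, , ], matrix(k, d[3], d[4]), 0)
    }
    out[n, , ] <- acc
  }
  out
}

#' Row-factor convolution (the RFT forward pass)
#'
#' As [ss_forward()] but each kernel row `r` is scaled by `row_scale[n,m,r]`
#' before convolution; the per-kernel shift behaves as under LFT (and is held
#' at zero when the factors were built with `include_shift = FALSE`).
#'
#' @inheritParams ss_forward
#' @param factors a [row_factors()] whose shape matches the bank.
#' @return 3D array, dim `(N, H, W)`.
#' @export
rft_forward <- function(input, filterbank, factors) {
  check_feature_tensor(input)
  d <- dim(filterbank$weights)
  if (!inherits(factors, "row_factors") || !identical(dim(factors$row_scale), d[1:3]))
    stop("factor shapes do not match the bank (configuration error)", call. = FALSE)
  if (dim(input)[1] != d[2]) stop("input channel count must equal M", call. = FALSE)
  H <- dim(input)[2]; W <- dim(input)[3]
  out <- array(0, c(d[1], H, W))
  for (n in seq_len(d[1])) {
    acc <- matrix(filterbank$bias[n] + sum(factors$shift[n, ]), H, W)
    for (m in seq_len(d[2])) {
      k <- filterbank$weights[n, m, , ] * factors$row_scale[n, m, ]
      acc <- acc + basic_features(input[m, , ], matrix(k, d[3], d[4]), 0)
    }
    out[n, , ] <- acc
  }
  out
}

#' Fold SS factors into an equivalent plain filter bank
#'
#' Absorbs the factors into the weights and bias: the scaling factor
#' uniformly scales all weights of its kernel, and the shifts accumulate onto
#' the filter bias. The returned bank reproduces [ss_forward()] with a plain
#' convolution, which is how an LFT-adapted model is deployed without any
#' runtime overhead. Inputs are not modified.
#'
#' @param filterbank a [conv_bank()].
#' @param factors an [ss_factors()] or [row_factors()].
#' @return A new [conv_bank()].
#' @export
fold_ss <- function(filterbank, factors) {
  d <- dim(filterbank$weights)
  if (inherits(factors, "ss_factors")) {
    if (!identical(dim(factors$scale), d[1:2]))
      stop("factor shapes do not match the bank (configuration error)", call. = FALSE)
    w <- filterbank$weights * as.vector(factors$scale)  # recycles over (k_h, k_w)
  } else if (inherits(factors, "row_factors")) {
    if (!identical(dim(factors$row_scale), d[1:3]))
      stop("factor shapes do not match the bank (configuration error)", call. = FALSE)
    w <- filterbank$weights * as.vector(factors$row_scale)  # recycles over k_w
  } else stop("factors must be ss_factors or row_factors", call. = FALSE)
  conv_bank(w, filterbank$bias + rowSums(factors$shift))
}

#' Trainable-parameter count per transfer strategy
#'
#' For layer shapes `(N, M, k_h, k_w)`: PT trains nothing; DT and FT train
#' every weight and bias, `sum N (M k_h k_w + 1)`; LFT trains two factors per
#' kernel, `sum 2 N M`; RFT trains one scale per kernel row plus one shift
#' per kernel, `sum N M (k_h + 1)`.
#'
#' @param strategy one of `"PT"`, `"DT"`, `"FT"`, `"RFT"`, `"LFT"`.
#' @param layer_shapes list of integer vectors `c(N, M, k_h, k_w)`.
#' @return Integer count.
#' @export
count_trainable <- function(strategy, layer_shapes) {
  strategy <- toupper(strategy)
  if (!strategy %in% c("PT", "DT", "FT", "RFT", "LFT"))
    stop("unknown strategy: ", strategy, call. = FALSE)
  if (!length(layer_shapes)) return(0L)
  per_layer <- vapply(layer_shapes, function(s) {
    s <- as.numeric(s)
    if (length(s) != 4 || any(s < 1)) stop("layer shape must be (N, M, k_h, k_w), all >= 1", call. = FALSE)
    switch(strategy,
           PT = 0,
           DT = ,
           FT = s[1] * (s[2] * s[3] * s[4] + 1),
           LFT = 2 * s[1] * s[2],
           RFT = s[1] * s[2] * (s[3] + 1))
  }, numeric(1))
  as.integer(sum(per_layer))
}

#' Serialize a filter bank (and optional factors) to a portable container
#'
#' Writes a JSON document with groups `weights`, `bias` and, when factors are
#' given, `ss/scale` and `ss/shift`, plus a `layout = "NMHW"` attribute, so
#' banks round-trip across languages with plain text.
#'
#' @param filterbank a [conv_bank()].
#' @param path file to write.
#' @param factors optional [ss_factors()].
#' @export
write_bank <- function(filterbank, path, factors = NULL) {
  d <- dim(filterbank$weights)
  doc <- list(layout = "NMHW", dim = as.integer(d),
              weights = as.numeric(filterbank$weights),
              bias = as.numeric(filterbank$bias))
  if (!is.null(factors))
    doc$ss <- list(scale = as.numeric(factors$scale),
                   shift = as.numeric(factors$shift))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bank
#' @return `read_bank()` returns a list with elements `bank` and (possibly
#'   `NULL`) `factors`.
#' @export
read_bank <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(doc$dim)
  bank <- conv_bank(array(doc$weights, d), doc$bias)
  factors <- NULL
  if (!is.null(doc$ss))
    factors <- ss_factors(bank, scale = matrix(doc$ss$scale, d[1], d[2]),
                          shift = matrix(doc$ss$shift, d[1], d[2]))
  list(bank = bank, factors = factors)
}
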