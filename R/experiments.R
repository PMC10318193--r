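#' Scenario configuration for the end-to-end comparison protocol
#'
#' Describes one grid of transfer experiments: a domain-shift scenario, the
#' sampling rates, the target training-set sizes, the model roster, and the
#' seeds. Defaults are desk-scale: 64x64 slices, a depth-2 generator, and an
#' 80-source / 32-target fixture, so the source domain has ample data
#' relative to the target (the premise of transfer) and the 16:5:4 target
#' split leaves at least 20 training slices.
#'
#' @param scenario `"contrast"`, `"direction"`, or `"anatomy"`.
#' @param rates sampling rates in (0, 1] (the study grid is 0.3/0.4/0.5).
#' @param train_sizes target training-set sizes; `NULL` = the full train split.
#' @param roster models to run, subset of `c("ZF","PT","DT","FT","RFT","LFT")`.
#' @param seeds integer vector; each seed is one independent replicate.
#' @param n_source,n_target slices generated per domain.
#' @param size slice side length (divisible by `2^depth`).
#' @param depth,base_channels generator architecture.
#' @param max_epochs,patience training protocol.
#' @param metrics metric columns to compute.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("contrast", "direction", "anatomy"),
                            rates = 0.3, train_sizes = NULL,
                            roster = c("ZF", "PT", "DT", "FT", "LFT"),
                            seeds = 0L, n_source = 80, n_target = 32, size = 64,
                            depth = 2, base_channels = 8,
                            max_epochs = 60, patience = 15,
                            metrics = c("psnr", "ssim")) {
  scenario <- match.arg(scenario)
  if (!length(rates) || any(rates <= 0 | rates > 1)) stop("rates must be in (0, 1]", call. = FALSE)
  roster <- match.arg(toupper(roster), c("ZF", "PT", "DT", "FT", "RFT", "LFT"), several.ok = TRUE)
  if (!length(seeds)) stop("need at least one seed", call. = FALSE)
  structure(list(scenario = scenario, rates = rates, train_sizes = train_sizes,
                 roster = roster, seeds = as.integer(seeds),
                 n_source = n_source, n_target = n_target, size = size,
                 depth = depth, base_channels = base_channels,
                 max_epochs = max_epochs, patience = patience, metrics = metrics),
            class = "scenario_config")
}

#' Run a transfer scenario grid
#'
#' For every (rate, train_size, seed) cell: generates the source/target
#' phantom collections, splits them 16:5:4, fixes one sampling mask for the
#' rate, pre-trains the source model, then evaluates every roster model on
#' the identical target test set with the identical mask. ZF and PT involve
#' no target training; DT/FT/RFT/LFT train on the target training subset.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional directory; when given, the long-format CSV and
#'   per-cell markdown tables are written there.
#' @param verbose print per-cell progress lines.
#' @return List with `results` (long data frame: one row per model x metric x
#'   cell) and `reports` (list of [aggregate_report()]s, one per cell).
#' @export
run_scenario <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  specs <- scenario_specs(config$scenario, size = config$size)
  nspec <- network_spec(depth = config$depth, base_channels = config$base_channels)
  all_rows <- list(); reports <- list()
  for (seed in config$seeds) {
    pair <- generate_domain_pair(specs$source, specs$target,
                                 config$n_source, config$n_target, seed = seed)
    src_imgs <- lapply(pair$source, `[[`, "image")
    tgt_imgs <- lapply(pair$target, `[[`, "image")
    src_split <- split_dataset(src_imgs, split_spec(), seed = derive_seed(seed, 31))
    tgt_split <- split_dataset(tgt_imgs, split_spec(), seed = derive_seed(seed, 37))
    for (rate in config$rates) {
      mask <- generate_cartesian_mask(config$size, rate,
                                      seed = derive_seed(seed, 41, round(rate * 100)))
      pre_cfg <- strategy_config("DT", max_epochs = config$max_epochs,
                                 patience = config$patience, seed = derive_seed(seed, 43))
      pre <- pretrain(build_generator(nspec, seed = derive_seed(seed, 47)),
                      src_split, pre_cfg, mask)
      ckpt <- net_checkpoint(pre$net)
      train_sizes <- config$train_sizes %||% list(NULL)
      for (ts in train_sizes) {
        tgt_data <- tgt_split
        if (!is.null(ts)) {
          if (ts > length(tgt_data$train)) stop("train_size exceeds the target train split", call. = FALSE)
          tgt_data$train <- tgt_data$train[seq_len(ts)]
        }
        cell_rows <- list()
        for (model in config$roster) {
          net_m <- switch(model,
            ZF = NULL,
            PT = transfer(build_generator(nspec, seed = derive_seed(seed, 47)), ckpt,
                          tgt_data, strategy_config("PT", seed = seed), mask)$net,
            DT = ,
            FT = transfer(build_generator(nspec, seed = derive_seed(seed, 47)), ckpt,
                          tgt_data,
                          strategy_config(model, max_epochs = config$max_epochs,
                                          patience = config$patience,
                                          seed = derive_seed(seed, 53, match(model, config$roster))),
                          mask)$net,
            RFT = ,
            LFT = transfer(insert_ss(build_generator(nspec, seed = derive_seed(seed, 47)),
                                     if (model == "LFT") "kernel" else "row"),
                           ckpt, tgt_data,
                           strategy_config(model, max_epochs = config$max_epochs,
                                           patience = config$patience,
                                           seed = derive_seed(seed, 53, match(model, config$roster))),
                           mask)$net)
          cell_rows[[model]] <- evaluate_model(net_m, tgt_data$test, mask,
                                               model = model, metrics = config$metrics)
          if (verbose)
            message(sprintf("seed %d rate %.2f size %s: %s mean PSNR %.2f dB",
                            seed, rate, ts %||% "full", model,
                            mean(cell_rows[[model]]$psnr[is.finite(cell_rows[[model]]$psnr)])))
        }
        per_image <- do.call(rbind, cell_rows)
        meta <- list(scenario = config$scenario, rate = rate,
                     train_size = ts %||% length(tgt_split$train), seed = seed)
        rep <- aggregate_report(per_image, roster = config$roster, metadata = meta)
        reports[[length(reports) + 1L]] <- rep
        long <- as.data.frame(rep)
        long$rate <- rate; long$train_size <- meta$train_size; long$seed <- seed
        all_rows[[length(all_rows) + 1L]] <- long
      }
    }
  }
  results <- do.call(rbind, all_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "results_long.csv"), row.names = FALSE)
    md <- vapply(reports, function(r) {
      m <- attr(r, "metadata")
      paste0(sprintf("## %s, rate %.2f, %d train images, seed %d\n\n",
                     m$scenario, m$rate, m$train_size, m$seed),
             format_report_markdown(r))
    }, character(1))
    writeLines(paste(md, collapse = "\n"), file.path(out_dir, "reports.md"))
  }
  list(results = results, reports = reports)
}

#' Extract an advanced-feature map from a network
#'
#' Returns the post-linear-combination, pre-activation output of one filter
#' of one convolution layer for a given input — the feature map whose type
#' the transfer hypothesis says is restored by adjusting the linear
#' combination coefficients. For a network with SS factors the factors are
#' applied (folded into the effective weights).
#'
#' @param net a `recon_network`.
#' @param image network input (`(in_channels, H, W)` array) or a 2D magnitude
#'   image together with `mask`.
#' @param layer_index which convolution layer (1-based, in construction order).
#' @param channel_index which filter of that layer.
#' @param mask optional sampling mask used to build the network input from a
#'   2D image.
#' @return 2D matrix, the feature map at that layer's spatial resolution.
#' @export
extract_feature_maps <- function(net, image, layer_index, channel_index, mask = NULL) {
  if (is.matrix(image)) {
    if (is.null(mask)) stop("supply a mask to build the network input from a 2D image", call. = FALSE)
    image <- zf_complex(image, mask)
  }
  conv_steps <- Filter(function(s) s$op == "conv", net$steps)
  if (layer_index < 1 || layer_index > length(conv_steps))
    stop("layer_index out of range (index error)", call. = FALSE)
  step <- conv_steps[[which(vapply(conv_steps, function(s) s$layer, integer(1)) == layer_index)]]
  fw <- net_forward(net, image, keep_buffers = TRUE)
  buf <- fw$buffers[[step$out]]
  if (channel_index < 1 || channel_index > dim(buf)[1])
    stop("channel_index out of range (index error)", call. = FALSE)
  buf[channel_index, , ]
}

#' Source-domain retention of a transferred model
#'
#' Evaluates the pre-trained model and a transferred model on held-out
#' source-domain images; the PSNR drop `psnr_pt_on_source -
#' psnr_transferred_on_source` quantifies how much source-domain competence
#' the transfer forgot. A diagnostic added around the training protocol: a
#' frozen-backbone model with identity factors forgets exactly nothing.
#'
#' @param pretrained,transferred `recon_network`s of the same architecture.
#' @param source_val_set list of source-domain reference images.
#' @param mask the sampling mask.
#' @return Named numeric vector `c(psnr_pt_on_source, psnr_transferred_on_source)`.
#' @export
compare_forgetting <- function(pretrained, transferred, source_val_set, mask) {
  if (!identical(net_layer_shapes(pretrained), net_layer_shapes(transferred)))
    stop("networks have incompatible layer shapes (compatibility error)", call. = FALSE)
  ex <- prepare_examples(source_val_set, mask)
  c(psnr_pt_on_source = validation_psnr(pretrained, ex),
    psnr_transferred_on_source = validation_psnr(transferred, ex))
}
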