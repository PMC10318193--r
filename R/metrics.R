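#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)` in dB. Identical images have zero MSE and
#' return `Inf`, which reporting code treats as a flagged sentinel (excluded
#' from mean/sd aggregation with a count).
#'
#' @param reference,test 2D numeric matrices of identical shape.
#' @param data_range dynamic range of the images (default 1 for magnitude
#'   images normalized to `[0, 1]`).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test, data_range = 1) {
  if (!identical(dim(reference), dim(test)))
    stop("reference and test must have the same shape (shape error)", call. = FALSE)
  if (data_range <= 0) stop("data_range must be positive", call. = FALSE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_kernel_1d <- function(sigma = 1.5, radius = 5L) {
  g <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable valid-mode filtering with a 1D kernel applied along both axes.
filter2_valid <- function(x, g) {
  r <- length(g)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h - r + 1L, w)
  for (k in seq_len(r)) out <- out + g[k] * x[k:(h - r + k), , drop = FALSE]
  out2 <- matrix(0, nrow(out), w - r + 1L)
  for (k in seq_len(r)) out2 <- out2 + g[k] * out[, k:(w - r + k), drop = FALSE]
  out2
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the standard 11x11 Gaussian window (sigma = 1.5) and
#' stabilization constants `k1 = 0.01`, `k2 = 0.03`. Local statistics are
#' Gaussian-weighted moments (not sample covariances) and the map is averaged
#' over the valid (fully-overlapping) region, following the original
#' definition of the index.
#'
#' @inheritParams psnr
#' @param k1,k2 stabilization constants.
#' @param sigma Gaussian window standard deviation (window size is
#'   `2 * ceiling(3.3 * sigma) + 1 = 11` at the default).
#' @return SSIM in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim <- function(reference, test, data_range = 1, k1 = 0.01, k2 = 0.03, sigma = 1.5) {
  if (!identical(dim(reference), dim(test)))
    stop("reference and test must have the same shape (shape error)", call. = FALSE)
  radius <- 5L
  win <- 2L * radius + 1L
  if (nrow(reference) < win || ncol(reference) < win)
    stop(sprintf("images must be at least %dx%d for the SSIM window (size error)", win, win),
         call. = FALSE)
  g <- gaussian_kernel_1d(sigma, radius)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  mu1 <- filter2_valid(reference, g)
  mu2 <- filter2_valid(test, g)
  s11 <- filter2_valid(reference * reference, g) - mu1 * mu1
  s22 <- filter2_valid(test * test, g) - mu2 * mu2
  s12 <- filter2_valid(reference * test, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Weighted PSNR
#'
#' PSNR with a spatial weight map on the squared error:
#' `10 log10(data_range^2 / (sum(w e^2) / sum(w)))`. When no map is supplied,
#' a contrast-sensitivity-inspired map is derived from the reference image:
#' high-frequency (fine-detail) regions are down-weighted, emulating reduced
#' visual sensitivity to errors in busy texture. This default map is a
#' documented approximation, not a standardized formula; supply `weight_map`
#' to use a specific weighting. A uniform map reproduces [psnr()] exactly.
#'
#' @inheritParams psnr
#' @param weight_map optional nonnegative matrix, same shape as the images;
#'   normalized internally to mean 1.
#' @return Weighted PSNR in dB (possibly `Inf`).
#' @export
wpsnr <- function(reference, test, data_range = 1, weight_map = NULL) {
  if (!identical(dim(reference), dim(test)))
    stop("reference and test must have the same shape (shape error)", call. = FALSE)
  if (is.null(weight_map)) weight_map <- csf_weight_map(reference)
  if (!identical(dim(weight_map), dim(reference)))
    stop("weight_map shape must match the images (shape error)", call. = FALSE)
  if (any(weight_map < 0)) stop("weight_map must be nonnegative (validation error)", call. = FALSE)
  w <- weight_map / mean(weight_map)
  wmse <- sum(w * (reference - test)^2) / sum(w)
  if (wmse == 0) return(Inf)
  10 * log10(data_range^2 / wmse)
}

# High-frequency attenuation weight map: 1 / (1 + local detail energy),
# normalized to mean 1. Falls back to uniform weights on constant images.
csf_weight_map <- function(reference, sigma = 1.5) {
  g <- gaussian_kernel_1d(sigma, 5L)
  padded <- pad_replicate(reference, 5L)
  low <- filter2_valid(padded, g)
  hf <- abs(reference - low)
  m <- mean(hf)
  if (m == 0) return(matrix(1, nrow(reference), ncol(reference)))
  w <- 1 / (1 + hf / m)
  w / mean(w)
}

pad_replicate <- function(x, r) {
  x <- x[c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r)), , drop = FALSE]
  x[, c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r)), drop = FALSE]
}

#' Aggregate per-image metrics into a mean +/- sd report
#'
#' Builds the standard comparison table: one row per model, one `mean +/- sd`
#' cell per metric, using the sample (n-1) standard deviation. Infinite
#' metric values (e.g. PSNR of an exact reconstruction) are excluded from the
#' aggregation and counted in `n_inf`.
#'
#' @param per_image_metrics data frame with a `model` column and one numeric
#'   column per metric (e.g. `psnr`, `ssim`, `wpsnr`).
#' @param roster character vector of models to report, in display order;
#'   defaults to the models present.
#' @param metadata named list stored alongside the table (rate, train size,
#'   seed, ...).
#' @return A `metrics_report`: data frame of `model`, `metric`, `mean`, `sd`,
#'   `n`, `n_inf` with the metadata attached as an attribute.
#' @export
aggregate_report <- function(per_image_metrics, roster = NULL, metadata = list()) {
  df <- as.data.frame(per_image_metrics)
  if (!"model" %in% names(df)) stop("per_image_metrics needs a 'model' column", call. = FALSE)
  metric_cols <- setdiff(names(df), c("model", "image"))
  roster <- roster %||% unique(df$model)
  rows <- list()
  for (mod in roster) {
    sub <- df[df$model == mod, , drop = FALSE]
    for (met in metric_cols) {
      v <- sub[[met]]
      n_inf <- sum(is.infinite(v))
      v <- v[is.finite(v)]
      if (length(v) < 2)
        stop(sprintf("need >= 2 finite values for model '%s', metric '%s' (reporting error)",
                     mod, met), call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod, metric = met, mean = mean(v), sd = sd(v),
        n = length(v), n_inf = n_inf, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- metadata
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat(format_report_markdown(x, digits))
  invisible(x)
}

#' Render a metrics report as a markdown table
#'
#' One row per model, one `mean +/- sd` column per metric; the best mean in
#' each column is bolded. Models with excluded infinite values get a footnote
#' count.
#'
#' @param report a [aggregate_report()] result.
#' @param digits decimals for means and sds.
#' @return A single character string of markdown.
#' @export
format_report_markdown <- function(report, digits = 2) {
  metrics <- unique(report$metric)
  models <- unique(report$model)
  best <- vapply(metrics, function(m) max(report$mean[report$metric == m]), numeric(1))
  header <- paste0("| model | ", paste(metrics, collapse = " | "), " |\n",
                   "|", paste(rep("---|", length(metrics) + 1L), collapse = ""), "\n")
  body <- vapply(models, function(mod) {
    cells <- vapply(metrics, function(m) {
      r <- report[report$model == mod & report$metric == m, ]
      cell <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"), r$mean, r$sd)
      if (r$mean == best[[m]]) cell <- paste0("**", cell, "**")
      if (r$n_inf > 0) cell <- paste0(cell, sprintf(" (%d inf excluded)", r$n_inf))
      cell
    }, character(1))
    paste0("| ", mod, " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  paste0(header, paste(body, collapse = "\n"), "\n")
}
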