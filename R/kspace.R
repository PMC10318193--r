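#' Cartesian variable-density sampling masks
#'
#' Retrospective 1D undersampling keeps a subset of phase-encode rows of
#' k-space. Rows are drawn without replacement with probability proportional
#' to a Gaussian density centered on the DC row, so sampling is denser in the
#' center of k-space, and a contiguous center band is always acquired to
#' preserve low-frequency content.
#'
#' @param height number of phase-encode rows (image height).
#' @param rate fraction of rows to acquire, in (0, 1]; exactly
#'   `round(rate * height)` rows are selected.
#' @param center_fraction fraction of rows in the always-acquired center
#'   band (`round(center_fraction * height)` rows); default 0.08.
#' @param sigma_fraction Gaussian standard deviation as a fraction of
#'   `height`; default 1/6.
#' @param seed integer seed; the mask is a pure function of all arguments.
#' @return An object of class `sampling_mask` with fields `rows` (0/1 vector
#'   of length `height`), `rate`, `center_fraction`, `sigma_fraction`, `seed`.
#' @examples
#' m <- generate_cartesian_mask(256, 0.3, seed = 7)
#' sum(m$rows)  # 77 == round(0.3 * 256)
#' @export
generate_cartesian_mask <- function(height, rate, center_fraction = 0.08,
                                    sigma_fraction = 1 / 6, seed = 0) {
  if (rate <= 0 || rate > 1) stop("rate must be in (0, 1]", call. = FALSE)
  n_keep <- round(rate * height)
  n_center <- round(center_fraction * height)
  if (n_center > n_keep)
    stop("rate too small to cover the center band (configuration error)", call. = FALSE)
  dc <- floor(height / 2) + 1L  # 1-based DC row of the centered spectrum
  rows <- integer(height)
  if (n_center > 0) {
    lo <- dc - floor(n_center / 2)
    rows[lo:(lo + n_center - 1L)] <- 1L
  }
  n_rest <- n_keep - sum(rows)
  if (n_rest > 0) {
    candidates <- which(rows == 0L)
    wts <- dnorm(candidates - dc, sd = sigma_fraction * height)
    if (sum(wts) <= 0) wts <- rep(1, length(candidates))  # numeric underflow fallback
    picked <- with_seed(seed, sample(candidates, n_rest, prob = wts))
    rows[picked] <- 1L
  }
  structure(list(rows = rows, rate = rate, center_fraction = center_fraction,
                 sigma_fraction = sigma_fraction, seed = as.integer(seed)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %d/%d rows (rate %.2f, center %.2f, seed %d)\n",
              sum(x$rows), length(x$rows), x$rate, x$center_fraction, x$seed))
  invisible(x)
}

#' Write/read a sampling mask as a plain-text 0/1 vector
#' @param mask a `sampling_mask`.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  writeLines(c(sprintf("# rate=%g center_fraction=%g sigma_fraction=%g seed=%d",
                       mask$rate, mask$center_fraction, mask$sigma_fraction, mask$seed),
               paste(mask$rows, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  meta <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", lines[1]), " ")[[1]]))
  rows <- as.integer(strsplit(lines[2], " ")[[1]])
  structure(list(rows = rows, rate = meta[1], center_fraction = meta[2],
                 sigma_fraction = meta[3], seed = as.integer(meta[4])),
            class = "sampling_mask")
}

fftshift_idx <- function(n) ((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L
ifftshift_idx <- function(n) ((seq_len(n) - 1L + ceiling(n / 2)) %% n) + 1L

#' Centered orthonormal 2D Fourier transform
#'
#' Maps an image to k-space with the DC component at the center index
#' `(floor(h/2) + 1, floor(w/2) + 1)`. The transform is orthonormal
#' (scaled by `1/sqrt(h w)`), so energy is preserved (Parseval) and
#' [from_kspace()] is its exact inverse.
#'
#' @param image 2D numeric (or complex) matrix.
#' @return Complex matrix of the same size, class `kspace2d`.
#' @export
to_kspace <- function(image) {
  if (!is.matrix(image)) stop("input must be a 2D matrix (shape error)", call. = FALSE)
  stopifnot_finite(Mod(image), "image")
  k <- fft(image) / sqrt(length(image))
  k <- k[fftshift_idx(nrow(k)), fftshift_idx(ncol(k)), drop = FALSE]
  structure(k, class = c("kspace2d", class(k)))
}

#' @rdname to_kspace
#' @param k centered k-space matrix.
#' @return `from_kspace()` returns the complex-valued image.
#' @export
from_kspace <- function(k) {
  if (!is.matrix(k)) stop("input must be a 2D matrix (shape error)", call. = FALSE)
  k <- unclass(k)
  k <- k[ifftshift_idx(nrow(k)), ifftshift_idx(ncol(k)), drop = FALSE]
  fft(k, inverse = TRUE) / sqrt(length(k))
}

#' Apply a row mask to k-space
#'
#' Rows flagged 1 in the mask are copied; rows flagged 0 are set to exactly
#' zero. Row 1 of the matrix corresponds to mask entry 1 (axis 1 is the
#' phase-encode direction).
#'
#' @param k centered k-space matrix ([to_kspace()] output).
#' @param mask a [generate_cartesian_mask()] result with `length(mask$rows) == nrow(k)`.
#' @return Masked k-space matrix of the same size.
#' @export
undersample <- function(k, mask) {
  if (length(mask$rows) != nrow(k))
    stop("mask length must equal the k-space height (shape error)", call. = FALSE)
  out <- unclass(k)
  out[mask$rows == 0L, ] <- 0 + 0i
  structure(out, class = c("kspace2d", class(out)))
}

#' Zero-filled reconstruction
#'
#' Magnitude of the centered inverse FFT of (under-sampled) k-space: the
#' aliased baseline every trained model is compared against.
#'
#' @param k_under centered (possibly masked) k-space matrix.
#' @return Nonnegative real matrix of the same size.
#' @export
zero_filled_recon <- function(k_under) Mod(from_kspace(k_under))

#' Complex zero-filled image for network input
#'
#' Convenience forward model: image -> centered k-space -> row mask ->
#' inverse FFT. Returns a 2-channel real array (real, imaginary), the input
#' contract of the reconstruction generator.
#'
#' @param image 2D real matrix in `[0, 1]`.
#' @param mask a sampling mask of matching height.
#' @return 3D array, dim `(2, h, w)`.
#' @export
zf_complex <- function(image, mask) {
  z <- from_kspace(undersample(to_kspace(image), mask))
  out <- array(0, c(2, nrow(z), ncol(z)))
  out[1, , ] <- Re(z); out[2, , ] <- Im(z)
  out
}
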