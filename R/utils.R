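# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; stays below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 1000003 + (p %% 2147483647)) %% 2147483647
  as.integer(h)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

check_feature_tensor <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature tensor must be a 3D array with dim (channels, height, width)",
         call. = FALSE)
  if (any(dim(x) < 1L)) stop("feature tensor dimensions must be >= 1", call. = FALSE)
  stopifnot_finite(x, "feature tensor")
}
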