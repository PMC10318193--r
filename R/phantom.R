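#' Parametric phantom specification
#'
#' Describes a family of synthetic 2D magnitude slices built from ellipse
#' composites. A template fixes the geometry (layout of structures), a
#' contrast map assigns an intensity in `[0, 1]` to each tissue label, and a
#' per-slice geometry jitter makes consecutive slices distinct while keeping
#' them draws from the same "domain". The three templates and the two preset
#' contrast maps span the transfer scenarios studied here: same geometry with
#' remapped intensities (contrast shift), reoriented brain geometry (slice
#' direction shift), and a structurally different knee-like layout (anatomy
#' shift).
#'
#' Tissue labels are `background` (always intensity 0), `outer`, `matter_a`,
#' `matter_b`, and `lesion`.
#'
#' @param size slice side length in pixels (default 256; 64 is the desk-scale
#'   default used by the experiment runner — any multiple of 4 works with the
#'   default network depth).
#' @param template `"brain_sagittal"`, `"brain_axial"`, or `"knee"`.
#' @param contrast `"t1"`, `"t2"`, or a named numeric vector over the five
#'   labels (must be injective, `background = 0`, all values in `[0, 1]`).
#' @param jitter geometry perturbation scale (fraction of the field of view).
#' @param n_lesions integer range `c(min, max)` of lesion ellipses per slice.
#' @param bias_field_amp amplitude of the smooth multiplicative bias field
#'   (`<= 0.1` recommended, 0 disables it).
#' @param seed integer; with the slice index, fully determines each slice.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256, template = c("brain_sagittal", "brain_axial", "knee"),
                         contrast = "t1", jitter = 0.1, n_lesions = c(1, 3),
                         bias_field_amp = 0.08, seed = 0) {
  template <- match.arg(template)
  cmap <- resolve_contrast_map(contrast)
  if (bias_field_amp < 0 || bias_field_amp > 0.5)
    stop("bias_field_amp must be in [0, 0.5]", call. = FALSE)
  structure(list(size = as.integer(size), template = template,
                 contrast_map = cmap, jitter = jitter,
                 n_lesions = as.integer(n_lesions),
                 bias_field_amp = bias_field_amp, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_labels <- c("background", "outer", "matter_a", "matter_b", "lesion")

resolve_contrast_map <- function(contrast) {
  if (is.character(contrast) && length(contrast) == 1) {
    contrast <- switch(contrast,
      # T1-like: fat/outer bright, matter_a above matter_b, fluid/lesion dark
      t1 = c(background = 0, outer = 0.9, matter_a = 0.65, matter_b = 0.35, lesion = 0.2),
      # T2-like: matter_a/matter_b ordering inverted, fluid/lesion bright,
      # fat still bright — a moderate shift, as between real T1w and T2w
      t2 = c(background = 0, outer = 0.8, matter_a = 0.45, matter_b = 0.75, lesion = 0.95),
      stop("unknown contrast preset: ", contrast, call. = FALSE))
  }
  if (!all(phantom_labels %in% names(contrast)))
    stop("contrast map must name all labels: ", paste(phantom_labels, collapse = ", "),
         call. = FALSE)
  contrast <- contrast[phantom_labels]
  if (contrast[["background"]] != 0) stop("background must map to 0", call. = FALSE)
  if (any(contrast < 0 | contrast > 1)) stop("intensities must be in [0, 1]", call. = FALSE)
  if (anyDuplicated(contrast)) stop("contrast map must be injective on labels", call. = FALSE)
  contrast
}

# ellipse interior test on grids x, y (matrices), center (cx, cy), semi-axes
# (a, b), rotation theta (radians)
ellipse_mask <- function(x, y, cx, cy, a, b, theta = 0) {
  ct <- cos(theta); st <- sin(theta)
  xr <- (x - cx) * ct + (y - cy) * st
  yr <- -(x - cx) * st + (y - cy) * ct
  (xr / a)^2 + (yr / b)^2 <= 1
}

# Template geometry: list of (label, cx, cy, a, b, theta) painted in order.
# jit() draws fresh offsets per structure, so each structure's position,
# size, and orientation vary independently across slices (subject-level
# anatomical variability, not a rigid whole-slice perturbation).
template_geometry <- function(template, jit) {
  e <- function(label, cx, cy, a, b, theta) {
    j <- jit()
    list(label, cx + j$dx, cy + j$dy, a + j$da, b + j$db, theta + j$dt)
  }
  switch(template,
    brain_sagittal = list(                      # skull, cerebrum, and a set of
      e("outer",    0,     0,    0.68, 0.82, 0.15),  # internal structures
      e("matter_a", 0,     0.05, 0.55, 0.62, 0.15),
      e("matter_b", -0.05, 0.15, 0.30, 0.10, 0.25),  # corpus-callosum-like arc
      e("matter_b", 0.25, -0.45, 0.18, 0.14, -0.4),  # cerebellum
      e("matter_b", 0.05, -0.35, 0.08, 0.22, 0.1),   # brainstem
      e("matter_b", -0.3,  0.35, 0.16, 0.05, 0.7),   # gyral band
      e("matter_b", 0.2,   0.4,  0.14, 0.05, -0.6),  # gyral band
      e("matter_b", -0.35, -0.1, 0.06, 0.14, 0.3),   # occipital structure
      e("matter_b", 0.1,   0.2,  0.05, 0.05, 0)),    # deep nucleus
    brain_axial = list(
      e("outer",    0,     0,    0.80, 0.62, 0),
      e("matter_a", 0,     0,    0.68, 0.50, 0),
      e("matter_b", -0.16, 0.05, 0.26, 0.08, 1.35),  # lateral ventricles
      e("matter_b", 0.16,  0.05, 0.26, 0.08, -1.35),
      e("matter_b", -0.28, -0.12, 0.10, 0.05, 0.5),  # putamen-like pair
      e("matter_b", 0.28,  -0.12, 0.10, 0.05, -0.5),
      e("matter_b", 0,     -0.35, 0.22, 0.05, 0),    # occipital band
      e("matter_b", 0,     0.42, 0.05, 0.12, 0),     # frontal midline
      e("matter_b", 0,     0,    0.05, 0.05, 0)),    # thalamic center
    knee = list(                                # layered stripes + elongated
      e("outer",    0,     0,    0.55, 0.92, 0),     # bones, maximally distant
      e("matter_a", 0,     0,    0.45, 0.80, 0),     # geometry from the brains
      e("matter_b", 0,     0.52, 0.30, 0.30, 0.1),   # femur
      e("matter_b", 0,    -0.52, 0.32, 0.28, -0.1),  # tibia
      e("matter_b", 0,     0.02, 0.34, 0.06, 0),     # joint-space band
      e("matter_b", -0.35, 0.15, 0.08, 0.18, 0.2),   # patellar structure
      e("matter_b", 0.05,  0.24, 0.24, 0.04, 0.05),  # cartilage stripe
      e("matter_b", 0.05, -0.22, 0.24, 0.04, -0.05), # cartilage stripe
      e("matter_b", 0.3,  -0.05, 0.05, 0.10, 0)),    # ligament
    stop("unknown template"))
}

#' Generate one labeled phantom slice
#'
#' Deterministic in `(spec$seed, index)`: the same pair always yields the
#' same arrays regardless of call order or surrounding RNG use. Geometry
#' jitter, lesion placement, and the bias field all derive from that pair.
#'
#' @param spec a [phantom_spec()].
#' @param index slice index (>= 1).
#' @return A `labeled_slice`: list with `image` (matrix in `[0, 1]`),
#'   `labels` (integer matrix, 0 = background .. 4 = lesion), and
#'   `fingerprint` (the generating parameters).
#' @export
generate_slice <- function(spec, index = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  ax <- seq(-1, 1, length.out = n)
  x <- matrix(rep(ax, each = n), n, n)   # column coordinate
  y <- matrix(rep(rev(ax), n), n, n)     # row coordinate, top = +1
  slice_seed <- derive_seed(spec$seed, 7919, index)
  labels <- matrix(0L, n, n)
  with_seed(slice_seed, {
    jit <- function() list(dx = runif(1, -1, 1) * spec$jitter,
                           dy = runif(1, -1, 1) * spec$jitter,
                           da = runif(1, -1, 1) * spec$jitter,
                           db = runif(1, -1, 1) * spec$jitter,
                           dt = runif(1, -1, 1) * spec$jitter * 2)
    geom <- template_geometry(spec$template, jit)
    for (g in geom) {
      lab <- match(g[[1]], phantom_labels) - 1L
      m <- ellipse_mask(x, y, g[[2]], g[[3]], g[[4]], g[[5]], g[[6]])
      labels[m] <- lab
    }
    n_les <- if (spec$n_lesions[1] >= spec$n_lesions[2]) spec$n_lesions[1] else
      sample(spec$n_lesions[1]:spec$n_lesions[2], 1)
    inside <- which(labels == 2L, arr.ind = TRUE)
    for (l in seq_len(n_les)) {
      if (nrow(inside) == 0) break
      c_idx <- inside[sample(nrow(inside), 1), ]
      cx <- x[c_idx[1], c_idx[2]]; cy <- y[c_idx[1], c_idx[2]]
      r <- runif(1, 0.03, 0.08)
      m <- ellipse_mask(x, y, cx, cy, r, r * runif(1, 0.6, 1.4), runif(1, 0, pi))
      labels[m & labels >= 2L] <- 4L
    }
    img <- matrix(spec$contrast_map[labels + 1L], n, n)
    if (spec$bias_field_amp > 0) {
      bx <- runif(1, -0.5, 0.5); by <- runif(1, -0.5, 0.5)
      field <- exp(-((x - bx)^2 + (y - by)^2) / (2 * 0.8^2))
      field <- 2 * (field - min(field)) / (max(field) - min(field)) - 1  # [-1, 1]
      img <- img * (1 + spec$bias_field_amp * field)
    }
  })
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, labels = labels,
                 fingerprint = list(seed = spec$seed, index = index,
                                    template = spec$template,
                                    contrast_map = spec$contrast_map)),
            class = "labeled_slice")
}

#' Generate paired source/target slice collections
#'
#' Draws `n_source` slices from the source spec and `n_target` from the
#' target spec, with independent per-collection seeds derived from `seed`.
#' Use [scenario_specs()] for the three preset domain shifts.
#'
#' @param source_spec,target_spec [phantom_spec()] objects.
#' @param n_source,n_target collection sizes (>= 1).
#' @param seed integer seed.
#' @return List with `source` and `target`, each a list of `labeled_slice`s.
#' @export
generate_domain_pair <- function(source_spec, target_spec, n_source, n_target, seed = 0) {
  if (identical(source_spec[c("template", "contrast_map")],
                target_spec[c("template", "contrast_map")]))
    warning("source and target specs are identical: degenerate transfer scenario")
  src_spec <- source_spec; src_spec$seed <- derive_seed(seed, 11, source_spec$seed)
  tgt_spec <- target_spec; tgt_spec$seed <- derive_seed(seed, 13, target_spec$seed)
  list(source = lapply(seq_len(n_source), function(i) generate_slice(src_spec, i)),
       target = lapply(seq_len(n_target), function(i) generate_slice(tgt_spec, i)))
}

#' Preset source/target specs for the three transfer scenarios
#'
#' * `contrast`: same sagittal-brain geometry, T1-like vs T2-like intensity
#'   maps (the matter_a/matter_b intensity ordering is inverted).
#' * `direction`: sagittal vs axial brain templates, same contrast.
#' * `anatomy`: brain vs knee templates — the largest geometric shift.
#'
#' @param scenario `"contrast"`, `"direction"`, or `"anatomy"`.
#' @param size slice size in pixels.
#' @param ... passed to both [phantom_spec()] calls (e.g. `jitter`).
#' @return List with `source` and `target` [phantom_spec()]s.
#' @export
scenario_specs <- function(scenario = c("contrast", "direction", "anatomy"),
                           size = 64, ...) {
  scenario <- match.arg(scenario)
  src <- phantom_spec(size = size, template = "brain_sagittal", contrast = "t1", ...)
  tgt <- switch(scenario,
    contrast = phantom_spec(size = size, template = "brain_sagittal", contrast = "t2", ...),
    direction = phantom_spec(size = size, template = "brain_axial", contrast = "t1", ...),
    anatomy = phantom_spec(size = size, template = "knee", contrast = "t1", ...))
  list(source = src, target = tgt)
}

#' Mean label-map Dice overlap between two slice collections
#'
#' Dice coefficient of the non-background label maps of index-matched slices,
#' averaged over pairs and over the tissue labels present. Geometry-
#' preserving shifts (contrast remapping) score 1; geometric shifts score
#' lower, more so the larger the structural deviation.
#'
#' @param set_a,set_b lists of `labeled_slice`s of equal length.
#' @return Mean Dice in `[0, 1]`.
#' @export
label_dice <- function(set_a, set_b) {
  stopifnot(length(set_a) == length(set_b))
  dices <- mapply(function(a, b) {
    la <- a$labels; lb <- b$labels
    per_label <- vapply(1:4, function(l) {
      na <- sum(la == l); nb <- sum(lb == l)
      if (na + nb == 0) return(NA_real_)
      2 * sum(la == l & lb == l) / (na + nb)
    }, numeric(1))
    mean(per_label, na.rm = TRUE)
  }, set_a, set_b)
  mean(dices)
}

#' Write a scenario fixture to disk
#'
#' Materializes the preset toy fixture (default 25 source + 25 target slices
#' at 64x64) as per-split folders of PNGs (when the `png` package is
#' available; otherwise plain CSV matrices) plus a JSON manifest holding the
#' counts, seeds and specs needed to regenerate the fixture bit-for-bit.
#'
#' @param scenario `"contrast"`, `"direction"`, or `"anatomy"`.
#' @param out_path directory to create.
#' @param n_source,n_target collection sizes.
#' @param size slice size.
#' @param seed integer seed.
#' @return The manifest, invisibly.
#' @export
package_fixture <- function(scenario, out_path, n_source = 25, n_target = 25,
                            size = 64, seed = 0) {
  specs <- scenario_specs(scenario, size = size)
  pair <- generate_domain_pair(specs$source, specs$target, n_source, n_target, seed)
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(scenario = scenario, n_source = n_source, n_target = n_target,
                   size = size, seed = seed, split_ratio = c(16, 5, 4),
                   format = if (requireNamespace("png", quietly = TRUE)) "png" else "csv")
  for (domain in c("source", "target")) {
    imgs <- lapply(pair[[domain]], `[[`, "image")
    split <- split_dataset(imgs, split_spec(), seed = derive_seed(seed, 17, match(domain, c("source", "target"))))
    for (part in c("train", "val", "test")) {
      d <- file.path(out_path, domain, part)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(split[[part]])) {
        img <- split[[part]][[i]]
        if (manifest$format == "png") {
          png::writePNG(img, file.path(d, sprintf("slice_%03d.png", i)), dpi = NULL)
        } else {
          write.csv(img, file.path(d, sprintf("slice_%03d.csv", i)), row.names = FALSE)
        }
      }
      manifest[[paste(domain, part, "n", sep = "_")]] <- length(split[[part]])
    }
  }
  jsonlite::write_json(manifest, file.path(out_path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Regenerate a fixture's slice collections from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by [package_fixture()].
#' @return As [generate_domain_pair()].
#' @export
fixture_from_manifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  specs <- scenario_specs(m$scenario, size = m$size)
  generate_domain_pair(specs$source, specs$target, m$n_source, m$n_target, m$seed)
}
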