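#' Tissue-labeled phantom
#'
#' A `tissue_phantom` couples an integer label grid (2D matrix or 3D array)
#' with a lookup table mapping each label to a tissue/material name and the
#' physical element spacing in millimetres. Labels are the unit every other
#' stage of the pipeline keys on: spectral simulation assigns HU by label,
#' the texture prior learns one kernel per label, and lesion feature
#' extraction masks by label.
#'
#' @param labels integer matrix (2D) or array (3D) of tissue ids.
#' @param tissue_table named character vector, names are label ids as strings.
#' @param spacing physical size of one element in mm (scalar, isotropic).
#' @return object of class `tissue_phantom`.
#' @export
tissue_phantom <- function(labels, tissue_table, spacing = 1) {
  storage.mode(labels) <- "integer"
  present <- as.character(sort(unique(as.vector(labels))))
  missing <- setdiff(present, names(tissue_table))
  if (length(missing))
    stop("labels without a tissue_table entry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(labels = labels, tissue_table = tissue_table,
                 spacing = spacing),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("<tissue_phantom> ", paste(d, collapse = " x "),
      " @ ", x$spacing, " mm\n", sep = "")
  tab <- table(factor(as.vector(x$labels), levels = names(x$tissue_table)))
  for (id in names(x$tissue_table))
    cat(sprintf("  %s (%s): %d elements\n", x$tissue_table[[id]], id, tab[[id]]))
  invisible(x)
}

chest_tissue_table <- function() {
  c("1" = "lung", "2" = "bone", "3" = "fat", "4" = "muscle")
}

lesion_material_table <- function() {
  c("0" = "background", "1" = "fat", "2" = "cellular tissue", "3" = "water")
}

#' Synthetic 2D chest phantom with four tissues
#'
#' Builds a square slice containing the four tissue classes used for
#' chest reconstruction experiments: two elliptical lung fields, a ring of
#' rib-like bone inserts, a subcutaneous fat layer, and muscle elsewhere.
#' The geometry is mildly jittered from the seed so distinct seeds give
#' distinct (but anatomically similar) phantoms; a given seed is
#' bit-reproducible.
#'
#' @param side image side length in pixels (>= 32).
#' @param seed integer seed.
#' @param spacing pixel size in mm.
#' @return a [tissue_phantom()] with labels 1 = lung, 2 = bone, 3 = fat,
#'   4 = muscle (no background: the slice is fully tissue).
#' @export
make_chest_phantom <- function(side, seed = 1L, spacing = 3) {
  stopifnot_scalar_num(side, "side", positive = TRUE)
  if (side < 32) stop("`side` must be at least 32 pixels", call. = FALSE)
  side <- as.integer(side)
  local_seed(seed, {
    jit <- rnorm(6, 0, 0.01)
    cx <- seq(-1, 1, length.out = side)
    x <- matrix(cx, side, side)
    y <- matrix(cx, side, side, byrow = TRUE)

    lab <- matrix(4L, side, side)                       # muscle base
    lab[(x / 0.85)^2 + (y / 0.80)^2 > 1] <- 3L          # subcutaneous fat

    in_ell <- function(x0, y0, a, b)
      ((x - x0) / a)^2 + ((y - y0) / b)^2 <= 1
    lab[in_ell(-0.42 + jit[1], 0.04 + jit[2], 0.29, 0.44)] <- 1L  # left lung
    lab[in_ell( 0.42 + jit[3], 0.04 + jit[4], 0.29, 0.44)] <- 1L  # right lung

    # rib cross-sections; sized so each keeps interior pixels after erosion
    # by a 7x7 window radius at side >= 64 (needed for MRF weight learning)
    th <- seq(0, 2 * pi, length.out = 10L)[-10L] + jit[5]
    rx <- 0.72 * cos(th); ry <- 0.64 * sin(th)
    for (i in seq_along(th))
      lab[in_ell(rx[i], ry[i], 0.14, 0.14)] <- 2L

    tissue_phantom(lab, chest_tissue_table(), spacing = spacing)
  })
}

# Periodic Gaussian random field with correlation length `corr_len` (in
# elements), any number of dimensions; standardized to zero mean, unit sd.
gaussian_random_field <- function(dims, corr_len) {
  white <- array(rnorm(prod(dims)), dim = dims)
  axes <- lapply(dims, function(n)
    c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / n)
  # separable Gaussian transfer function exp(-2 pi^2 l^2 |f|^2)
  tf <- Reduce(function(a, b) outer(a, b, `+`),
               lapply(axes, function(f) 2 * pi^2 * corr_len^2 * f^2))
  tf <- array(exp(-tf), dim = dims)
  g <- Re(fft(fft(white) * tf, inverse = TRUE)) / prod(dims)
  (g - mean(g)) / sd(g)
}

#' Default per-class lesion texture parameters
#'
#' The class contrast is carried mainly by the spatial correlation length
#' (coarse benign vs fine malignant texture) with a milder
#' material-fraction shift; per-lesion log-normal jitter of both makes
#' lesions overlap between classes the way patient cohorts do, so
#' first-order voxel statistics alone do not trivially separate the
#' classes.
#' @export
default_texture_spec <- function() {
  list(
    benign    = list(corr_len_mm = 6,
                     frac = c(fat = 0.20, `cellular tissue` = 0.60, water = 0.20),
                     frac_jitter = 0.25, corr_jitter = 0.10),
    malignant = list(corr_len_mm = 3,
                     frac = c(fat = 0.25, `cellular tissue` = 0.50, water = 0.25),
                     frac_jitter = 0.25, corr_jitter = 0.10)
  )
}

#' Default per-class mean lesion diameters (mm)
#'
#' Benign is the count-weighted mean over the adenoma sub-types of a
#' published 63-polyp cohort; malignant is that cohort's adenocarcinoma
#' mean.
#' @export
default_size_spec <- function() {
  c(benign = 39.9, malignant = 43.9)
}

make_one_lesion <- function(size_mm, spec, spacing, sample_id, class_label) {
  r_vox <- size_mm / 2 / spacing
  n <- 2L * ceiling(r_vox) + 5L
  ax <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  mask <- d2 <= r_vox^2

  corr_len <- spec$corr_len_mm * exp(rnorm(1, 0, spec$corr_jitter %||% 0))
  g <- gaussian_random_field(c(n, n, n), corr_len / spacing)
  frac <- spec$frac * exp(rnorm(length(spec$frac), 0, spec$frac_jitter %||% 0))
  frac <- frac / sum(frac)
  cuts <- quantile(g[mask], cumsum(frac)[1:2], names = FALSE, type = 8)
  lab <- array(0L, dim = c(n, n, n))
  lab[mask] <- 1L + findInterval(g[mask], cuts)  # 1 fat, 2 cellular, 3 water
  vol <- tissue_phantom(lab, lesion_material_table(), spacing = spacing)
  structure(list(volume = vol, label = class_label, size_mm = size_mm,
                 id = sample_id),
            class = "lesion_sample")
}

#' Generate a synthetic lesion cohort for classification experiments
#'
#' Each lesion is a 3D volume of pure-material voxels (fat / cellular
#' tissue / water on a background) inside a spherical mask. Material
#' assignment thresholds a spatially correlated Gaussian random field, so
#' spatial heterogeneity is controlled by the field's correlation length
#' and the material mixing fractions. Malignant lesions default to a
#' shorter correlation length and more balanced mixing (finer, stronger
#' texture) than benign ones, which is the class contrast the downstream
#' texture features are asked to detect.
#'
#' @param n_benign,n_malignant per-class sample counts (>= 1).
#' @param size_spec named vector of per-class mean largest diameters (mm).
#' @param texture_spec per-class list with `corr_len_mm` and material
#'   fractions `frac`; see `default` in the returned attributes.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param spacing voxel size in mm.
#' @param size_cv coefficient of variation of lesion diameters about the
#'   class mean.
#' @return a list of class `lesion_cohort`: `samples` (list of
#'   `lesion_sample`) and `manifest` (tibble: id, label, size_mm).
#' @export
make_lesion_cohort <- function(n_benign = 31L, n_malignant = 32L,
                               size_spec = default_size_spec(),
                               texture_spec = default_texture_spec(),
                               seed = 1L, spacing = 2, size_cv = 0.15) {
  if (n_benign < 1 || n_malignant < 1)
    stop("need at least one sample per class", call. = FALSE)
  if (any(size_spec <= 0)) stop("lesion sizes must be positive", call. = FALSE)
  local_seed(seed, {
    labels <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
    sizes <- pmax(8 * spacing,
                  rnorm(length(labels), size_spec[labels],
                        size_cv * size_spec[labels]))
    samples <- lapply(seq_along(labels), function(i)
      make_one_lesion(sizes[i], texture_spec[[labels[i]]], spacing,
                      sample_id = sprintf("L%03d", i), class_label = labels[i]))
    manifest <- tibble::tibble(
      id = vapply(samples, `[[`, "", "id"),
      label = labels,
      size_mm = sizes
    )
    structure(list(samples = samples, manifest = manifest,
                   texture_spec = texture_spec, spacing = spacing),
              class = "lesion_cohort")
  })
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat("<lesion_cohort> ", length(x$samples), " lesions (",
      sum(x$manifest$label == "benign"), " benign / ",
      sum(x$manifest$label == "malignant"), " malignant) @ ",
      x$spacing, " mm\n", sep = "")
  invisible(x)
}
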