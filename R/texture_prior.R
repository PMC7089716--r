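#' Disjoint tissue masks
#'
#' @param masks named list of logical matrices, pairwise disjoint, jointly
#'   covering the image.
#' @param source optional identifier of the full-dose image they came from.
#' @return object of class `tissue_mask_set`.
#' @export
tissue_mask_set <- function(masks, source = NULL) {
  stack <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(stack > 1L)) stop("masks must be pairwise disjoint", call. = FALSE)
  if (any(stack < 1L)) stop("masks must jointly cover the image", call. = FALSE)
  if (is.null(names(masks)))
    names(masks) <- paste0("tissue", seq_along(masks))
  structure(list(masks = masks, source = source), class = "tissue_mask_set")
}

#' Masks from a phantom's ground-truth labels
#' @param phantom a [tissue_phantom()].
#' @export
masks_from_phantom <- function(phantom) {
  ids <- sort(unique(as.vector(phantom$labels)))
  masks <- lapply(ids, function(id) phantom$labels == id)
  names(masks) <- phantom$tissue_table[as.character(ids)]
  tissue_mask_set(masks, source = "phantom-labels")
}

#' Intensity-based tissue segmentation (stand-in)
#'
#' Clusters image intensities into `n_tissues` classes by 1D k-means with
#' deterministic quantile initialization; a stand-in for a full
#' segmentation pipeline, adequate when tissues have well-separated mean
#' HU (as CT tissues do). Masks are named `tissue1..n` in order of
#' increasing mean intensity.
#'
#' @param full_dose numeric image (HU).
#' @param n_tissues number of classes (>= 2).
#' @return a [tissue_mask_set()].
#' @export
segment_tissues <- function(full_dose, n_tissues = 4L) {
  if (n_tissues < 2L) stop("need at least 2 tissues", call. = FALSE)
  v <- as.vector(full_dose)
  if (diff(range(v)) == 0)
    stop("cannot segment a constant image", call. = FALSE)
  centers <- quantile(v, probs = seq(0.5, n_tissues - 0.5) / n_tissues,
                      names = FALSE, type = 8)
  centers <- centers + seq_len(n_tissues) * 1e-9 * max(abs(centers), 1) # distinct
  km <- kmeans(v, centers = matrix(centers, ncol = 1), iter.max = 100)
  ord <- order(km$centers)
  cls <- match(km$cluster, ord)
  masks <- lapply(seq_len(n_tissues), function(k)
    matrix(cls == k, nrow(full_dose), ncol(full_dose)))
  tissue_mask_set(masks)
}

window_offsets <- function(window) {
  rad <- (window - 1L) / 2L
  g <- expand.grid(dx = -rad:rad, dy = -rad:rad)
  g[!(g$dx == 0 & g$dy == 0), , drop = FALSE]
}

# out[i, j] = x[i + dx, j + dy], zero-padded; `valid` marks in-bounds source
shift_mat <- function(x, dx, dy) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  src_i <- max(1, 1 + dx):min(n, n + dx)
  src_j <- max(1, 1 + dy):min(m, m + dy)
  out[src_i - dx, src_j - dy] <- x[src_i, src_j]
  out
}

#' Per-tissue, per-channel MRF neighborhood weights
#'
#' @param weights list over tissues; each a list over channels of a
#'   `window` x `window` kernel matrix (center entry 0, off-center entries
#'   summing to 1).
#' @param window odd neighborhood side length.
#' @param tissues tissue names.
#' @param energies_keV channel energies.
#' @export
mrf_weight_set <- function(weights, window, tissues, energies_keV = NULL) {
  for (r in seq_along(weights)) for (k in seq_along(weights[[r]])) {
    w <- weights[[r]][[k]]
    if (!all(dim(w) == window) || !all(is.finite(w)))
      stop("kernel for tissue ", r, " channel ", k, " malformed", call. = FALSE)
  }
  structure(list(weights = weights, window = as.integer(window),
                 tissues = tissues, energies_keV = energies_keV),
            class = "mrf_weight_set")
}

uniform_kernel <- function(window) {
  w <- matrix(1 / (window^2 - 1), window, window)
  w[(window + 1) / 2, (window + 1) / 2] <- 0
  w
}

#' Learn tissue-specific MRF weights from a full-dose image
#'
#' For every (tissue, channel) pair, fits one shared neighborhood kernel by
#' least-squares autoregression: over all pixels j of the tissue region
#' whose full window lies inside the region, minimize
#' `sum_j (x_j - sum_m w_m x_m)^2` with m running over the `window^2 - 1`
#' neighbors. The kernel is then normalized to sum 1, making the texture
#' prior a consensus penalty. A constant region admits any normalized
#' kernel; the uniform kernel is returned as the tie-break.
#'
#' @param full_dose_channels a [spectral_image()] (full-dose).
#' @param masks a [tissue_mask_set()].
#' @param window odd neighborhood side (default 7, i.e. 48 neighbors).
#' @return an [mrf_weight_set()].
#' @export
learn_mrf_weights <- function(full_dose_channels, masks, window = 7L) {
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be odd and >= 3", call. = FALSE)
  offs <- window_offsets(window)
  nch <- dim(full_dose_channels$data)[1]
  weights <- vector("list", length(masks$masks))
  names(weights) <- names(masks$masks)
  for (r in seq_along(masks$masks)) {
    mask <- masks$masks[[r]]
    # interior pixels: the whole window stays inside the region
    interior <- mask
    for (o in seq_len(nrow(offs)))
      interior <- interior & shift_mat(mask, offs$dx[o], offs$dy[o]) > 0
    if (!any(interior))
      stop("tissue '", names(masks$masks)[r],
           "' is empty after eroding by the window radius", call. = FALSE)
    weights[[r]] <- vector("list", nch)
    for (k in seq_len(nch)) {
      img <- channel(full_dose_channels, k)
      y <- img[interior]
      if (diff(range(y)) == 0) {           # constant region: tie-break
        weights[[r]][[k]] <- uniform_kernel(window)
        next
      }
      X <- vapply(seq_len(nrow(offs)), function(o)
        shift_mat(img, offs$dx[o], offs$dy[o])[interior], numeric(sum(interior)))
      fit <- qr(X)
      if (fit$rank < ncol(X))
        stop("region '", names(masks$masks)[r],
             "' too small or degenerate for a full-rank kernel fit",
             call. = FALSE)
      w <- qr.coef(fit, y)
      w <- w / sum(w)
      ker <- matrix(0, window, window)
      ker[cbind(offs$dx + (window + 1) / 2, offs$dy + (window + 1) / 2)] <- w
      weights[[r]][[k]] <- ker
    }
  }
  mrf_weight_set(weights, window, names(masks$masks),
                 full_dose_channels$energies_keV)
}

# Shared core: accumulate value and gradient of the texture prior.
# The penalty is the quadruple sum exactly as the model states it: pixels
# whose window crosses the region (or image) boundary simply contribute
# the terms for the neighbors they do have, at their raw kernel weights.
texture_prior_core <- function(chi, weights, masks, want_grad) {
  offs <- window_offsets(weights$window)
  nch <- dim(chi$data)[1]
  value <- 0
  grad <- if (want_grad) array(0, dim = dim(chi$data)) else NULL
  for (k in seq_len(nch)) {
    img <- channel(chi, k)
    gk <- if (want_grad) matrix(0, nrow(img), ncol(img)) else NULL
    for (r in seq_along(masks$masks)) {
      mask <- masks$masks[[r]] * 1
      ker <- weights$weights[[r]][[k]]
      wv <- ker[cbind(offs$dx + (weights$window + 1) / 2,
                      offs$dy + (weights$window + 1) / 2)]
      for (o in seq_len(nrow(offs))) {
        nb_in <- shift_mat(mask, offs$dx[o], offs$dy[o])
        c_jo <- wv[o] * mask * nb_in           # both endpoints in the region
        diff <- img - shift_mat(img, offs$dx[o], offs$dy[o])
        value <- value + sum(c_jo * diff^2)
        if (want_grad) {
          t_o <- c_jo * diff
          gk <- gk + 2 * t_o - 2 * shift_mat(t_o, -offs$dx[o], -offs$dy[o])
        }
      }
    }
    if (want_grad) grad[slice.index(grad, 1L) == k] <- gk
  }
  list(value = value, grad = grad)
}

#' Texture prior value R(chi)
#'
#' The quadratic tissue-texture penalty: for every channel, tissue region
#' and in-region pixel, the weighted sum of squared differences between the
#' pixel and its neighbors under the tissue's learned kernel. Zero iff
#' every pixel equals its kernel-weighted neighborhood mean (for
#' sum-normalized kernels); fitted kernels may carry negative weights, in
#' which case the value may be negative.
#'
#' @param chi a [spectral_image()].
#' @param weights an [mrf_weight_set()].
#' @param masks a [tissue_mask_set()] aligned with `chi`.
#' @return scalar.
#' @export
texture_prior_value <- function(chi, weights, masks) {
  check_prior_shapes(chi, masks)
  texture_prior_core(chi, weights, masks, want_grad = FALSE)$value
}

#' Gradient of the texture prior
#' @inheritParams texture_prior_value
#' @return array shaped like `chi$data`.
#' @export
texture_prior_gradient <- function(chi, weights, masks) {
  check_prior_shapes(chi, masks)
  texture_prior_core(chi, weights, masks, want_grad = TRUE)$grad
}

check_prior_shapes <- function(chi, masks) {
  sdim <- dim(chi$data)[-1]
  for (m in masks$masks)
    if (!identical(dim(m), as.integer(sdim)))
      stop("mask and image shapes differ", call. = FALSE)
  invisible(TRUE)
}
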