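#' Symmetry-reduced co-occurrence directions
#'
#' First-neighbor sampling directions modulo central symmetry: a GLCM
#' accumulated with both pair orders is identical for a direction and its
#' negation, so only one of each +/- pair is kept. 8 raw directions in 2D
#' reduce to 4; 26 in 3D reduce to 13. The representative has its first
#' nonzero component positive; directions are returned in lexicographic
#' order.
#'
#' @param dims 2 or 3.
#' @return matrix with one offset vector per row.
#' @export
enumerate_directions <- function(dims) {
  if (!dims %in% c(2L, 3L)) stop("`dims` must be 2 or 3", call. = FALSE)
  g <- as.matrix(do.call(expand.grid, rep(list(-1:1), dims)))
  colnames(g) <- c("dx", "dy", "dz")[seq_len(dims)]
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  first_nz <- apply(g, 1, function(v) v[which(v != 0)[1]])
  g <- g[first_nz > 0, , drop = FALSE]
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

#' Uniform gray-level quantization
#'
#' Bins values uniformly into `levels` integer gray levels `0..levels-1`.
#' With `range = NULL` (ROI min-max mode) the bin edges span the observed
#' range, making downstream descriptors invariant to adding a constant HU
#' offset; a fixed `c(lo, hi)` window can be supplied instead. A constant
#' input maps wholly to level 0.
#'
#' @param values numeric vector/array.
#' @param levels number of gray levels G >= 2.
#' @param range optional fixed `c(lo, hi)` window.
#' @return integer object of the same shape, in `[0, levels)`.
#' @export
quantize <- function(values, levels = 32L, range = NULL) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (levels < 2L) stop("need at least 2 levels", call. = FALSE)
  rng <- range %||% base::range(values, finite = TRUE)
  if (diff(rng) == 0) {
    q <- values; q[] <- 0L; storage.mode(q) <- "integer"
    return(q)
  }
  q <- floor((values - rng[1]) / diff(rng) * levels)
  q[] <- pmin(pmax(q, 0), levels - 1L)
  storage.mode(q) <- "integer"
  q
}

# extract the co-located slabs q[src] and q[src + off]
pair_slabs <- function(dims, off) {
  lapply(seq_along(dims), function(d) {
    lo <- max(1L, 1L - off[d]); hi <- min(dims[d], dims[d] - off[d])
    if (lo > hi) integer(0) else lo:hi
  })
}

#' Gray-level co-occurrence matrix
#'
#' Counts, over all positions p with both p and p + d*direction inside the
#' mask, the gray-level pair (g1, g2) -- accumulated in both orders, so
#' the matrix is symmetric -- then normalizes to sum 1.
#'
#' @param quantized integer grid (2D or 3D) of gray levels in `[0, levels)`.
#' @param mask logical grid, same shape (default: everything).
#' @param direction offset vector, one row of [enumerate_directions()].
#' @param displacement pair distance d in elements (default 1).
#' @param levels number of gray levels G (default `max(quantized) + 1`).
#' @return object of class `glcm`: fields `matrix` (G x G, sums to 1),
#'   `direction`, `displacement`, `levels`.
#' @export
glcm <- function(quantized, mask = NULL, direction, displacement = 1L,
                 levels = max(quantized) + 1L) {
  dims <- dim(quantized) %||% length(quantized)
  if (is.null(dim(quantized))) dim(quantized) <- dims
  mask <- mask %||% array(TRUE, dim = dims)
  off <- as.integer(direction) * as.integer(displacement)
  if (length(off) != length(dims))
    stop("direction dimensionality does not match the grid", call. = FALSE)
  src <- pair_slabs(dims, off)
  if (any(lengths(src) == 0)) stop("no valid pairs for this offset", call. = FALSE)
  dst <- Map(`+`, src, as.list(off))
  a <- do.call(`[`, c(list(quantized), src, list(drop = FALSE)))
  b <- do.call(`[`, c(list(quantized), dst, list(drop = FALSE)))
  keep <- do.call(`[`, c(list(mask), src, list(drop = FALSE))) &
          do.call(`[`, c(list(mask), dst, list(drop = FALSE)))
  if (!any(keep)) stop("no valid in-mask pairs for this offset", call. = FALSE)
  ij <- cbind(a[keep], b[keep])
  cnt <- matrix(tabulate(ij[, 1] * levels + ij[, 2] + 1L, levels * levels),
                levels, levels, byrow = TRUE)
  cnt <- cnt + t(cnt)                       # both pair orders
  structure(list(matrix = cnt / sum(cnt), direction = as.integer(direction),
                 displacement = as.integer(displacement),
                 levels = as.integer(levels)),
            class = "glcm")
}

haralick_names <- c("asm", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy", "entropy",
                    "difference_variance", "difference_entropy",
                    "imc1", "imc2", "mcc")

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' The 14 classical Haralick measures of a GLCM
#'
#' Computed per the classical definitions with natural logarithms and
#' `0 log 0 = 0`. Degeneracies return defined values: correlation and the
#' information measures are 0 when a marginal is degenerate, and the
#' maximal correlation coefficient is 0 when the Q matrix is rank
#' deficient. Sum variance is centered on the sum average.
#'
#' @param g a [glcm()] (or a plain normalized matrix).
#' @return named numeric vector of length 14 in the fixed order: asm,
#'   contrast, correlation, variance, idm, sum_average, sum_variance,
#'   sum_entropy, entropy, difference_variance, difference_entropy,
#'   imc1, imc2, mcc.
#' @export
haralick <- function(g) {
  p <- if (inherits(g, "glcm")) g$matrix else g
  G <- nrow(p)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(seq_len(G) * px); my <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(G) - my)^2 * py))

  # sum / difference histograms
  psum <- vapply(2:(2 * G), function(k) sum(p[i + j == k]), 0)
  pdif <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), 0)
  kk_s <- 2:(2 * G); kk_d <- 0:(G - 1)

  asm <- sum(p^2)
  contrast <- sum(kk_d^2 * pdif)
  correlation <- if (sx > 0 && sy > 0) (sum(i * j * p) - mx * my) / (sx * sy) else 0
  variance <- sum((i - mx)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_average <- sum(kk_s * psum)
  sum_variance <- sum((kk_s - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(p))
  dif_mean <- sum(kk_d * pdif)
  difference_variance <- sum((kk_d - dif_mean)^2 * pdif)
  difference_entropy <- -sum(xlogx(pdif))

  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  lpxy <- outer(px, py)
  hxy1 <- -sum(p * ifelse(lpxy > 0, log(lpxy), 0))
  hxy2 <- -sum(xlogx(lpxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  nz <- px > 0
  mcc <- 0
  if (sum(nz) >= 2) {
    pn <- p[nz, nz, drop = FALSE]
    Q <- (pn / px[nz]) %*% t(pn / py[nz])   # Q[i,l] = sum_k p(i,k)p(l,k)/(px(i)py(k))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2 && ev[2] > 1e-12) mcc <- sqrt(min(max(ev[2], 0), 1))
  }

  out <- c(asm, contrast, correlation, variance, idm, sum_average,
           sum_variance, sum_entropy, entropy, difference_variance,
           difference_entropy, imc1, imc2, mcc)
  names(out) <- haralick_names
  out
}

#' 28-entry texture descriptor of a 3D volume
#'
#' Computes one GLCM per symmetry-reduced 3D direction (13 of them),
#' derives the 14 Haralick measures from each, and aggregates each measure
#' by its mean and its range (max - min) over directions: 14 means
#' followed by 14 ranges, 28 values.
#'
#' @param quantized integer 3D grid of gray levels.
#' @param mask logical 3D grid.
#' @param displacement pair distance (default 1).
#' @param levels gray levels G.
#' @return named numeric vector of length 28 (`<measure>_mean` block, then
#'   `<measure>_range` block).
#' @export
descriptor <- function(quantized, mask = NULL, displacement = 1L,
                       levels = max(quantized) + 1L) {
  if (length(dim(quantized)) != 3L)
    stop("descriptor requires a 3D volume", call. = FALSE)
  dirs <- enumerate_directions(3L)
  H <- vapply(seq_len(nrow(dirs)), function(d)
    haralick(glcm(quantized, mask, dirs[d, ], displacement, levels)),
    numeric(14L))
  means <- rowMeans(H)
  ranges <- apply(H, 1, max) - apply(H, 1, min)
  out <- c(means, ranges)
  names(out) <- c(paste0(haralick_names, "_mean"),
                  paste0(haralick_names, "_range"))
  out
}

#' Neighboring-channel difference images
#'
#' Channel i of the output is channel i minus channel i + 1 of the input
#' (the "35-45", ..., "65-75" pairing), so n channels yield n - 1
#' difference images. The output's nominal energies are the pair
#' midpoints; pair labels are attached as `attr(, "pairs")`.
#'
#' @param spectral a [spectral_image()] with >= 2 channels.
#' @return a [spectral_image()] with one fewer channel.
#' @export
difference_images <- function(spectral) {
  nch <- dim(spectral$data)[1]
  if (nch < 2L) stop("need at least two channels", call. = FALSE)
  d <- dim(spectral$data)
  out <- array(0, dim = c(nch - 1L, d[-1]))
  for (c in seq_len(nch - 1L))
    out[slice.index(out, 1L) == c] <-
      spectral$data[slice.index(spectral$data, 1L) == c] -
      spectral$data[slice.index(spectral$data, 1L) == c + 1L]
  e <- spectral$energies_keV
  res <- spectral_image(out, (e[-nch] + e[-1]) / 2)
  attr(res, "pairs") <- paste0(e[-nch], "-", e[-1])
  res
}
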