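#' @name image_quality
#' @title Image fidelity metrics between a reference and a test image
NULL

rmse_metric <- function(ref, test) sqrt(mean((ref - test)^2))

# 2D convolution with a small kernel, replicate-padded borders
conv2_same <- function(img, ker) {
  kr <- (nrow(ker) - 1L) / 2L
  kc <- (ncol(ker) - 1L) / 2L
  n <- nrow(img); m <- ncol(img)
  pad <- img[pmin(pmax(seq(1 - kr, n + kr), 1), n),
             pmin(pmax(seq(1 - kc, m + kc), 1), m)]
  out <- matrix(0, n, m)
  for (a in seq_len(nrow(ker))) for (b in seq_len(ncol(ker)))
    out <- out + ker[a, b] * pad[(a - 1) + seq_len(n), (b - 1) + seq_len(m)]
  out
}

gaussian_kernel <- function(side, sigma) {
  r <- (side - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity index (mean SSIM)
#'
#' Standard windowed formulation: local means, variances and covariance
#' under a Gaussian window (7 x 7, sigma 1.5 by default) and the usual
#' stabilizing constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with `L` the
#' reference dynamic range.
#'
#' @param ref,test numeric matrices of identical shape.
#' @param window window side (odd).
#' @param sigma Gaussian window sigma.
#' @param K stabilizing constants `c(K1, K2)`.
#' @export
ssim_metric <- function(ref, test, window = 7L, sigma = 1.5,
                        K = c(0.01, 0.03)) {
  L <- diff(range(ref))
  if (L == 0) L <- 1
  C1 <- (K[1] * L)^2; C2 <- (K[2] * L)^2
  ker <- gaussian_kernel(window, sigma)
  mu1 <- conv2_same(ref, ker); mu2 <- conv2_same(test, ker)
  s11 <- conv2_same(ref^2, ker) - mu1^2
  s22 <- conv2_same(test^2, ker) - mu2^2
  s12 <- conv2_same(ref * test, ker) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

# ---- phase congruency (log-Gabor bank) for FSIM ---------------------------

lowpass_filter <- function(n, m, cutoff = 0.45, order = 15) {
  fx <- ((seq_len(m) - 1 - floor(m / 2)) / m)
  fy <- ((seq_len(n) - 1 - floor(n / 2)) / n)
  r <- sqrt(outer(fy^2, fx^2, `+`))
  lp <- 1 / (1 + (r / cutoff)^(2 * order))
  # ifftshift
  lp[c((floor(n / 2) + 1):n, 1:floor(n / 2)),
     c((floor(m / 2) + 1):m, 1:floor(m / 2))]
}

radius_angle <- function(n, m) {
  fx <- ((seq_len(m) - 1 - floor(m / 2)) / m)
  fy <- ((seq_len(n) - 1 - floor(n / 2)) / n)
  r <- sqrt(outer(fy^2, fx^2, `+`))
  th <- atan2(outer(fy, rep(1, m)), outer(rep(1, n), fx))
  shift <- function(x) x[c((floor(n / 2) + 1):n, 1:floor(n / 2)),
                         c((floor(m / 2) + 1):m, 1:floor(m / 2))]
  r <- shift(r); th <- shift(th)
  r[1, 1] <- 1   # avoid log(0) at DC
  list(r = r, th = th)
}

#' Phase congruency map of a 2D image
#'
#' Log-Gabor implementation over `nscale` scales and `norient`
#' orientations; moment-summed over orientations. Feature-rich points
#' (edges, lines) score near 1 regardless of contrast, which is what
#' makes the measure suitable as the FSIM saliency map.
#'
#' @param img numeric matrix.
#' @param nscale,norient filter-bank size.
#' @param min_wavelength,mult smallest wavelength and scale multiplier.
#' @param sigma_onf log-Gabor bandwidth parameter.
#' @param k noise threshold in noise standard deviations.
#' @return matrix in `[0, 1]`.
#' @export
phase_congruency <- function(img, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2,
                             sigma_onf = 0.55, k = 2) {
  n <- nrow(img); m <- ncol(img)
  IM <- fft(img)
  ra <- radius_angle(n, m)
  lp <- lowpass_filter(n, m)
  eps <- 1e-4
  pc_sum <- matrix(0, n, m)
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- cos(ra$th) * sin(angl) - sin(ra$th) * cos(angl)
    dc <- cos(ra$th) * cos(angl) + sin(ra$th) * sin(angl)
    dtheta <- pmin(abs(atan2(ds, dc)) * norient / 2, pi)
    spread <- (cos(dtheta) + 1) / 2
    sumE <- matrix(0, n, m); sumO <- matrix(0, n, m); sumAn <- matrix(0, n, m)
    maxAn <- matrix(0, n, m); t_noise <- 0
    for (s in seq_len(nscale)) {
      wavelength <- min_wavelength * mult^(s - 1)
      fo <- 1 / wavelength
      logGabor <- exp(-(log(ra$r / fo))^2 / (2 * log(sigma_onf)^2)) * lp
      logGabor[1, 1] <- 0
      filt <- logGabor * spread
      eo <- fft(IM * filt, inverse = TRUE) / (n * m)
      e <- Re(eo); oo <- Im(eo)
      an <- sqrt(e^2 + oo^2)
      sumE <- sumE + e; sumO <- sumO + oo; sumAn <- sumAn + an
      maxAn <- pmax(maxAn, an)
      if (s == 1) {
        # noise energy estimate from the smallest-scale response median
        tau <- stats::median(an) / sqrt(log(4))
        totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
        noiseMean <- totalTau * sqrt(pi / 2)
        noiseSigma <- totalTau * sqrt((4 - pi) / 2)
        t_noise <- noiseMean + k * noiseSigma
      }
    }
    xe <- sumE / pmax(sqrt(sumE^2 + sumO^2), eps)
    xo <- sumO / pmax(sqrt(sumE^2 + sumO^2), eps)
    energy <- sumE * xe + sumO * xo - abs(sumE * xo - sumO * xe)
    pc_sum <- pc_sum + pmax(energy - t_noise, 0) / (sumAn + eps)
  }
  pmin(pc_sum / norient, 1)
}

scharr_gradient <- function(img) {
  gx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3) / 16, 3, 3, byrow = TRUE)
  sqrt(conv2_same(img, gx)^2 + conv2_same(img, t(gx))^2)
}

#' Feature similarity index (FSIM)
#'
#' Combines phase-congruency similarity and gradient-magnitude similarity,
#' weighted by the pointwise maximum phase congruency, per the original
#' formulation. Images are rescaled to 0-255 using the reference range so
#' the published constants `T1 = 0.85`, `T2 = 160` apply.
#'
#' @param ref,test numeric matrices of identical shape.
#' @param T1,T2 stabilizing constants.
#' @export
fsim_metric <- function(ref, test, T1 = 0.85, T2 = 160) {
  rng <- range(ref)
  sc <- if (diff(rng) > 0) 255 / diff(rng) else 1
  r8 <- (ref - rng[1]) * sc
  t8 <- (test - rng[1]) * sc
  pc1 <- phase_congruency(r8)
  pc2 <- phase_congruency(t8)
  g1 <- scharr_gradient(r8)
  g2 <- scharr_gradient(t8)
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

#' Per-channel quality report between two spectral images
#'
#' @param ref,test [spectral_image()]s of identical shape; `ref` is the
#'   ground truth / full-dose reference.
#' @return tibble: channel, energy_keV, rmse, psnr, ssim, fsim. PSNR uses
#'   `20 log10(range(ref) / rmse)` per channel.
#' @export
image_quality <- function(ref, test) {
  if (!identical(dim(ref$data), dim(test$data)))
    stop("reference and test shapes differ", call. = FALSE)
  nch <- dim(ref$data)[1]
  rows <- lapply(seq_len(nch), function(c) {
    r <- channel(ref, c); t <- channel(test, c)
    rm <- rmse_metric(r, t)
    rng <- diff(range(r)); if (rng == 0) rng <- 1
    tibble::tibble(channel = c, energy_keV = ref$energies_keV[c],
                   rmse = rm,
                   psnr = if (rm == 0) Inf else 20 * log10(rng / rm),
                   ssim = ssim_metric(r, t),
                   fsim = fsim_metric(r, t))
  })
  do.call(rbind, rows)
}
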