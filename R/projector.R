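#' Parallel-beam projection geometry
#'
#' Describes a 2D parallel-beam acquisition: `n_angles` view angles evenly
#' spaced over `[0, pi)` and a 1D detector of `n_bins` bins. The discrete
#' projector is realized as a sparse system matrix (pixel-driven with
#' linear detector interpolation), so back-projection is the exact matrix
#' transpose and the adjoint identity holds to machine precision.
#'
#' @param image_side image side in pixels.
#' @param n_angles number of angles (default 180).
#' @param n_bins detector bins; default the smallest odd count covering the
#'   image diagonal. Must be >= `image_side`.
#' @param bin_spacing detector bin width in pixel units.
#' @return object of class `projection_geometry`.
#' @export
proj_geometry <- function(image_side, n_angles = 180L, n_bins = NULL,
                          bin_spacing = 1) {
  image_side <- as.integer(image_side)
  if (is.null(n_bins)) {
    n_bins <- ceiling(image_side * sqrt(2)) + 2L
    if (n_bins %% 2L == 0L) n_bins <- n_bins + 1L
  }
  if (n_angles < 1L) stop("need at least one angle", call. = FALSE)
  if (n_bins < image_side)
    stop("n_bins must be >= image_side for full coverage", call. = FALSE)
  structure(list(n_angles = as.integer(n_angles),
                 angles = seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)],
                 n_bins = as.integer(n_bins),
                 bin_spacing = bin_spacing,
                 image_side = image_side),
            class = "projection_geometry")
}

.sysmat_cache <- new.env(parent = emptyenv())

#' Sparse system matrix of a geometry
#'
#' Rows index (angle, bin) pairs, columns pixels (column-major image
#' layout). Cached per geometry.
#' @param geom a [proj_geometry()].
#' @return a `dgCMatrix` of size `n_angles * n_bins` x `image_side^2`.
#' @export
system_matrix <- function(geom) {
  key <- paste(geom$image_side, geom$n_angles, geom$n_bins, geom$bin_spacing,
               sep = "_")
  if (!is.null(.sysmat_cache[[key]])) return(.sysmat_cache[[key]])
  s <- geom$image_side
  ctr <- (s + 1) / 2
  px <- rep(seq_len(s) - ctr, times = s)   # x (row) coordinate, column-major
  py <- rep(seq_len(s) - ctr, each = s)    # y (col) coordinate
  trips <- vector("list", geom$n_angles)
  bctr <- (geom$n_bins + 1) / 2
  for (a in seq_len(geom$n_angles)) {
    th <- geom$angles[a]
    t <- (px * cos(th) + py * sin(th)) / geom$bin_spacing + bctr
    b0 <- floor(t)
    w1 <- 1 - (t - b0)
    col <- rep(seq_len(s * s), 2L)
    bin <- c(b0, b0 + 1)
    w <- c(w1, 1 - w1)
    keep <- bin >= 1 & bin <= geom$n_bins & w > 0
    trips[[a]] <- list(i = (a - 1L) * geom$n_bins + bin[keep],
                       j = col[keep], x = w[keep])
  }
  A <- Matrix::sparseMatrix(
    i = unlist(lapply(trips, `[[`, "i")),
    j = unlist(lapply(trips, `[[`, "j")),
    x = unlist(lapply(trips, `[[`, "x")),
    dims = c(geom$n_angles * geom$n_bins, s * s))
  .sysmat_cache[[key]] <- A
  A
}

check_image_geom <- function(image, geom) {
  d <- dim(image)
  if (length(d) != 2L || d[1] != d[2] || d[1] != geom$image_side)
    stop("image must be square with side ", geom$image_side, call. = FALSE)
}

#' Forward projection (discrete Radon transform)
#'
#' @param image square numeric matrix (attenuation, or any linear quantity).
#' @param geom a [proj_geometry()].
#' @return `n_angles` x `n_bins` matrix of line integrals in pixel units.
#' @export
forward_project <- function(image, geom) {
  check_image_geom(image, geom)
  p <- as.numeric(system_matrix(geom) %*% as.vector(image))
  matrix(p, geom$n_angles, geom$n_bins, byrow = TRUE)
}

#' Back-projection (exact adjoint of [forward_project()])
#'
#' @param sino `n_angles` x `n_bins` matrix.
#' @param geom a [proj_geometry()].
#' @return square image matrix.
#' @export
back_project <- function(sino, geom) {
  if (!identical(dim(sino), c(geom$n_angles, geom$n_bins)))
    stop("sinogram shape does not match geometry", call. = FALSE)
  v <- as.numeric(Matrix::crossprod(system_matrix(geom), as.vector(t(sino))))
  matrix(v, geom$image_side, geom$image_side)
}

#' Photon-counting measurement: Poisson noise on attenuated counts
#'
#' Each bin receives `Poisson(I0 * exp(-p))` photons, independently.
#' For very large means (> 1e7) a seeded normal approximation is used,
#' since exact Poisson generation overflows; at such means the relative
#' approximation error is negligible.
#'
#' @param line_integrals numeric matrix/vector of line integrals p.
#' @param I0 incident photons per bin (> 0).
#' @param seed integer seed.
#' @return photon counts, same shape as the input.
#' @export
add_poisson <- function(line_integrals, I0, seed = 1L) {
  stopifnot_scalar_num(I0, "I0", positive = TRUE)
  lam <- I0 * exp(-line_integrals)
  local_seed(seed, {
    counts <- lam
    big <- lam > 1e7
    counts[!big] <- rpois(sum(!big), lam[!big])
    if (any(big))
      counts[big] <- pmax(0, round(rnorm(sum(big), lam[big], sqrt(lam[big]))))
    counts
  })
}

#' Log transform photon counts back to line integrals
#'
#' `p_hat = -log(max(counts, c_min) / I0)`; the floor `c_min` keeps the
#' transform finite when a bin records zero photons.
#'
#' @param counts photon counts.
#' @param I0 incident photons per bin.
#' @param c_min count floor (default 1).
#' @return line integrals, same shape.
#' @export
counts_to_lineintegrals <- function(counts, I0, c_min = 1) {
  stopifnot_scalar_num(I0, "I0", positive = TRUE)
  -log(pmax(counts, c_min) / I0)
}

# smooth water attenuation (1/mm) vs effective energy; anchored at
# ~0.019/mm at 75 keV with a power-law rise toward low keV
mu_water_keV <- function(keV) 0.0187 * (75 / keV)^0.75

#' HU to linear attenuation and back
#' @param hu CT values.
#' @param mu_water water attenuation (1/mm) at the channel energy.
#' @export
hu_to_mu <- function(hu, mu_water) mu_water * (1 + hu / 1000)

#' @rdname hu_to_mu
#' @param mu linear attenuation (1/mm).
#' @export
mu_to_hu <- function(mu, mu_water) 1000 * (mu / mu_water - 1)

#' Multi-channel spectral sinogram
#'
#' @param data array channels x n_angles x n_bins.
#' @param kind "photon-counts" or "line-integrals".
#' @param I0 incident photons per bin per channel (vector, one per channel).
#' @param energies_keV channel energies.
#' @export
spectral_sinogram <- function(data, kind = c("photon-counts", "line-integrals"),
                              I0, energies_keV) {
  kind <- match.arg(kind)
  if (kind == "photon-counts" && any(data < 0))
    stop("photon counts must be non-negative", call. = FALSE)
  if (any(!is.finite(data))) stop("sinogram entries must be finite", call. = FALSE)
  structure(list(data = data, kind = kind, I0 = I0,
                 energies_keV = energies_keV),
            class = "spectral_sinogram")
}

#' Simulate a photon-counting acquisition of a spectral image
#'
#' Converts each channel from HU to attenuation using the channel's water
#' attenuation coefficient, forward projects (scaled by the pixel spacing
#' to get line integrals in 1/mm x mm), and applies Poisson counting
#' statistics. The photon budget mirrors a photon-counting detector: the
#' total beam `I0_total` is split evenly across channels, so each channel
#' individually is photon-starved relative to a single-energy scan.
#'
#' @param img a [spectral_image()] in HU.
#' @param geom a [proj_geometry()].
#' @param I0_total total incident photons per bin across channels.
#' @param spacing_mm pixel size in mm.
#' @param seed integer seed.
#' @param noiseless if TRUE skip Poisson sampling and return expected counts.
#' @return a [spectral_sinogram()] of photon counts.
#' @export
project_spectral <- function(img, geom, I0_total = 5e4, spacing_mm = 3,
                             seed = 1L, noiseless = FALSE) {
  nch <- dim(img$data)[1]
  I0 <- rep(I0_total / nch, nch)
  out <- array(0, dim = c(nch, geom$n_angles, geom$n_bins))
  for (c in seq_len(nch)) {
    muw <- mu_water_keV(img$energies_keV[c])
    mu <- hu_to_mu(channel(img, c), muw)
    p <- forward_project(mu, geom) * spacing_mm
    out[c, , ] <- if (noiseless) I0[c] * exp(-p)
                  else add_poisson(p, I0[c], seed = derive_seed(seed, paste0("ch", c)))
  }
  spectral_sinogram(out, "photon-counts", I0, img$energies_keV)
}

#' Log-transform a photon-count spectral sinogram to line integrals
#' @param sino a [spectral_sinogram()] of kind "photon-counts".
#' @param c_min count floor.
#' @export
sinogram_to_lineintegrals <- function(sino, c_min = 1) {
  if (sino$kind != "photon-counts") return(sino)
  out <- sino$data
  for (c in seq_len(dim(out)[1]))
    out[c, , ] <- counts_to_lineintegrals(sino$data[c, , ], sino$I0[c], c_min)
  spectral_sinogram(out, "line-integrals", sino$I0, sino$energies_keV)
}
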