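# Shared fixtures, built once per test run and memoized.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Low-count 5-channel chest acquisition: the reconstruction fixture
# (64 x 64 phantom, 90 angles, 1e4 photons per channel per bin, seed 11).
chest_fixture <- function() fixture("chest", function() {
  phantom <- make_chest_phantom(64, seed = 1)
  truth <- synthesize_spectral(phantom)
  geom <- proj_geometry(64, n_angles = 90)
  sino <- project_spectral(truth, geom, I0_total = 5e4, seed = 11)
  masks <- masks_from_phantom(phantom)
  weights <- learn_mrf_weights(truth, masks)
  list(phantom = phantom, truth = truth, geom = geom, sino = sino,
       masks = masks, weights = weights)
})

sart_fixture <- function() fixture("sart", function() {
  fx <- chest_fixture()
  sart_reconstruct(fx$sino, fx$geom, n_iters = 50)
})

lrtp_fixture <- function() fixture("lrtp", function() {
  fx <- chest_fixture()
  lrtp_reconstruct(fx$sino, fx$geom, fx$weights, fx$masks,
                   lrtp_default_config())
})

# Small lesion cohort for unit tests; the full 31/32 cohort and its
# feature tables are built only by the acceptance tests.
cohort_small <- function() fixture("cohort_small", function()
  make_lesion_cohort(8, 8, seed = 7))

cohort_full <- function() fixture("cohort_full", function()
  make_lesion_cohort(31, 32, seed = 7))

# Full-dose chest image with shared anatomical texture across channels:
# phantom HU plus a smooth random field whose amplitude scales mildly
# with channel, mimicking energy-dependent contrast of one anatomy.
textured_fulldose <- function() fixture("textured_fulldose", function() {
  fx <- chest_fixture()
  set.seed(21)
  tex <- spectex:::gaussian_random_field(c(64, 64), 2) * 25
  dat <- fx$truth$data
  for (c in 1:5)
    dat[slice.index(dat, 1L) == c] <-
      dat[slice.index(dat, 1L) == c] + (1 + 0.1 * c) * as.vector(tex)
  spectral_image(dat, fx$truth$energies_keV)
})

# Exact neighborhood autoregression: interior pixels satisfy
# x_j = sum_m w_m x_(j+m) exactly (w-harmonic interpolation of a random
# boundary), so least squares recovers the kernel with zero residual.
ar_image <- function(n, kernel, seed = 1) {
  rad <- (nrow(kernel) - 1) / 2
  set.seed(seed)
  x <- matrix(rnorm(n * n), n, n)
  interior <- matrix(FALSE, n, n)
  interior[(rad + 1):(n - rad), (rad + 1):(n - rad)] <- TRUE
  idx <- matrix(seq_len(n * n), n, n)
  offs <- spectex:::window_offsets(nrow(kernel))
  wv <- kernel[cbind(offs$dx + rad + 1, offs$dy + rad + 1)]
  ii <- jj <- integer(0); xx <- numeric(0)
  bi <- numeric(sum(interior))
  int_ids <- idx[interior]
  row_of <- match(int_ids, int_ids)
  for (o in seq_len(nrow(offs))) {
    nb_r <- row(idx)[interior] + offs$dx[o]
    nb_c <- col(idx)[interior] + offs$dy[o]
    nb_id <- idx[cbind(nb_r, nb_c)]
    nb_int <- interior[cbind(nb_r, nb_c)]
    ii <- c(ii, row_of[nb_int])
    jj <- c(jj, match(nb_id[nb_int], int_ids))
    xx <- c(xx, rep(-wv[o], sum(nb_int)))
    bi[!nb_int] <- bi[!nb_int] + wv[o] * x[cbind(nb_r, nb_c)][!nb_int]
  }
  M <- Matrix::sparseMatrix(i = c(ii, seq_along(int_ids)),
                            j = c(jj, seq_along(int_ids)),
                            x = c(xx, rep(1, length(int_ids))),
                            dims = c(length(int_ids), length(int_ids)))
  x[interior] <- as.numeric(Matrix::solve(M, bi))
  x
}

rmse_by_channel <- function(a, b)
  vapply(seq_len(dim(a$data)[1]), function(c)
    sqrt(mean((channel(a, c) - channel(b, c))^2)), 0)

# Independent brute-force GLCM oracle: loop over every voxel pair.
glcm_oracle <- function(q, mask, direction, displacement, levels) {
  dims <- dim(q)
  cnt <- matrix(0, levels, levels)
  off <- direction * displacement
  it <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  for (r in seq_len(nrow(it))) {
    p <- it[r, ]
    p2 <- p + off
    if (any(p2 < 1) || any(p2 > dims)) next
    if (!mask[matrix(p, 1)] || !mask[matrix(p2, 1)]) next
    a <- q[matrix(p, 1)] + 1L
    b <- q[matrix(p2, 1)] + 1L
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  cnt / sum(cnt)
}
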