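test_that("intensity segmentation recovers phantom tissues", {
  fx <- chest_fixture()
  full_dose <- channel(fx$truth, 5)
  seg <- segment_tissues(full_dose, 4)
  # noiseless: tissues have distinct constant HU, agreement is exact
  agree <- function(seg, labels) {
    assign <- sapply(seg$masks, function(m) {
      tab <- table(labels[m]); as.integer(names(tab)[which.max(tab)]) })
    pred <- matrix(0L, nrow(labels), ncol(labels))
    for (k in seq_along(seg$masks)) pred[seg$masks[[k]]] <- assign[k]
    mean(pred == labels)
  }
  expect_equal(agree(seg, fx$phantom$labels), 1)
  # 20 HU of noise: at least 95% agreement
  set.seed(8)
  noisy <- full_dose + matrix(rnorm(length(full_dose), 0, 20), 64)
  expect_gte(agree(segment_tissues(noisy, 4), fx$phantom$labels), 0.95)
  expect_error(segment_tissues(matrix(5, 10, 10), 4), "constant")
  expect_error(segment_tissues(matrix(rnorm(100), 10), 1), "at least 2")
})

test_that("mask sets must be disjoint and covering", {
  m <- matrix(TRUE, 4, 4)
  expect_error(tissue_mask_set(list(m, m)), "disjoint")
  expect_error(tissue_mask_set(list(m & FALSE)), "cover")
  ms <- masks_from_phantom(chest_fixture()$phantom)
  expect_named(ms$masks, c("lung", "bone", "fat", "muscle"))
})

test_that("least-squares autoregression recovers a planted kernel", {
  ker <- matrix(c(0.05, 0.2, 0.05,
                  0.2, 0, 0.2,
                  0.05, 0.2, 0.05), 3, 3, byrow = TRUE)
  x <- ar_image(24, ker, seed = 1)
  fit_kernel <- function(noise_sd, seed = 2) {
    set.seed(seed)
    xn <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x))
    chi <- spectral_image(array(xn, c(1, 24, 24)), 55)
    masks <- tissue_mask_set(list(all = matrix(TRUE, 24, 24)))
    learn_mrf_weights(chi, masks, window = 3L)$weights[[1]][[1]]
  }
  expect_lt(max(abs(fit_kernel(0) - ker)), 1e-6)
  # recovery degrades monotonically with observation noise
  errs <- vapply(c(1e-4, 1e-2, 1e-1),
                 function(s) max(abs(fit_kernel(s) - ker)), 0)
  expect_true(all(diff(errs) > 0))
})

test_that("constant regions fall back to the uniform kernel", {
  chi <- spectral_image(array(7, c(1, 20, 20)), 55)
  masks <- tissue_mask_set(list(all = matrix(TRUE, 20, 20)))
  w <- learn_mrf_weights(chi, masks, window = 5L)
  expect_equal(w$weights[[1]][[1]], spectex:::uniform_kernel(5L))
  expect_error(learn_mrf_weights(chi, masks, window = 4L), "odd")
  # tiny region: erosion leaves nothing
  small <- tissue_mask_set(list(a = rbind(TRUE, matrix(FALSE, 19, 20)),
                                b = rbind(FALSE, matrix(TRUE, 19, 20))))
  expect_error(learn_mrf_weights(chi, small, window = 7L), "eroding")
})

test_that("per-tissue kernels are similar across energy channels", {
  fx <- chest_fixture()
  # window 5: the rib cross-sections keep enough interior pixels for a
  # full-rank 24-neighbor fit at side 64 (48 neighbors would need more bone)
  w <- learn_mrf_weights(textured_fulldose(), fx$masks, window = 5L)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (r in seq_along(w$weights)) {
    ks <- lapply(w$weights[[r]], as.vector)
    for (k in 2:length(ks))
      expect_gt(cosine(ks[[1]], ks[[k]]), 0.9)
  }
})

test_that("texture prior value matches brute-force enumeration", {
  # 3x3 single-tissue image, center 1, uniform 1/8 kernel: R = 2
  img <- matrix(0, 3, 3); img[2, 2] <- 1
  chi <- spectral_image(array(img, c(1, 3, 3)), 55)
  masks <- tissue_mask_set(list(all = matrix(TRUE, 3, 3)))
  ker <- matrix(1 / 8, 3, 3); ker[2, 2] <- 0
  w <- mrf_weight_set(list(list(ker)), 3L, "all")
  expect_equal(texture_prior_value(chi, w, masks), 2)
  # constant image: zero value, zero gradient
  cchi <- spectral_image(array(4, c(1, 3, 3)), 55)
  expect_equal(texture_prior_value(cchi, w, masks), 0)
  expect_true(all(texture_prior_gradient(cchi, w, masks) == 0))
  # quadratic form: doubling the image quadruples the value
  chi2 <- spectral_image(2 * chi$data, 55)
  expect_equal(texture_prior_value(chi2, w, masks),
               4 * texture_prior_value(chi, w, masks))
  expect_equal(texture_prior_gradient(chi2, w, masks),
               2 * texture_prior_gradient(chi, w, masks))
})

test_that("prior gradient matches central finite differences", {
  set.seed(5)
  n <- 8
  img <- matrix(rnorm(n * n), n)
  chi <- spectral_image(array(img, c(1, n, n)), 55)
  half <- matrix(rep(c(TRUE, FALSE), each = n * n / 2), n)
  masks <- tissue_mask_set(list(a = half, b = !half))
  mk <- function() {
    k <- matrix(rnorm(9), 3); k[2, 2] <- 0; k / sum(k)
  }
  w <- mrf_weight_set(list(list(mk()), list(mk())), 3L, c("a", "b"))
  g <- texture_prior_gradient(chi, w, masks)
  h <- 1e-5
  fd <- array(0, dim(g))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    e <- array(0, c(1, n, n)); e[1, i, j] <- h
    fd[1, i, j] <- (texture_prior_value(spectral_image(chi$data + e, 55), w, masks) -
                    texture_prior_value(spectral_image(chi$data - e, 55), w, masks)) / (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
})
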