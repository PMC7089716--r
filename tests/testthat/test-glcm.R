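test_that("symmetry-reduced directions: 4 in 2D, 13 in 3D, no +/- pairs", {
  d2 <- enumerate_directions(2)
  d3 <- enumerate_directions(3)
  expect_equal(nrow(d2), 4)
  expect_equal(nrow(d3), 13)
  for (d in list(d2, d3)) {
    keys <- apply(d, 1, paste, collapse = ",")
    neg <- apply(-d, 1, paste, collapse = ",")
    expect_length(intersect(keys, neg), 0)
    expect_false(any(duplicated(keys)))
    expect_true(all(apply(d, 1, function(v) v[which(v != 0)[1]] > 0)))
  }
  expect_error(enumerate_directions(4), "2 or 3")
})

test_that("quantization bins uniformly and handles constants", {
  expect_true(all(quantize(matrix(5, 3, 3), 8) == 0L))
  ramp <- seq(0, 1, length.out = 8)
  expect_equal(as.vector(quantize(ramp, 4)), rep(0:3, each = 2))
  # bin centers re-quantize to their own levels
  centers <- (0:3 + 0.5) / 4
  expect_equal(as.vector(quantize(centers, 4, range = c(0, 1))), 0:3)
  expect_error(quantize(numeric(0), 4), "empty")
  expect_error(quantize(1:3, 1), "2 levels")
})

test_that("glcm matches hand-computed small cases", {
  g <- glcm(matrix(0L, 2, 2), direction = c(1L, 0L), levels = 1L)
  expect_equal(g$matrix, matrix(1, 1, 1))
  g2 <- glcm(matrix(c(0L, 1L, 0L, 1L), 1, 4), direction = c(0L, 1L),
             levels = 2L)
  expect_equal(g2$matrix, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_error(glcm(matrix(0L, 2, 2), direction = c(5L, 0L), levels = 1L),
               "no valid")
})

test_that("glcm equals the brute-force pair-enumeration oracle in 3D", {
  set.seed(13)
  dirs <- enumerate_directions(3)
  for (rep in 1:4) {
    q <- array(sample(0:3, 4^3, TRUE), c(4, 4, 4))
    mask <- array(stats::runif(4^3) > 0.2, c(4, 4, 4))
    for (d in seq_len(nrow(dirs))) for (disp in 1:2) {
      skip <- FALSE
      oracle <- tryCatch(glcm_oracle(q, mask, dirs[d, ], disp, 4L),
                         error = function(e) { skip <<- TRUE; NULL })
      got <- tryCatch(glcm(q, mask, dirs[d, ], disp, 4L)$matrix,
                      error = function(e) NULL)
      if (is.null(got)) next
      expect_equal(got, oracle, tolerance = 1e-12,
                   label = paste("dir", d, "disp", disp))
    }
  }
})

test_that("rotating an image permutes the per-direction 2D GLCM set", {
  set.seed(14)
  q <- matrix(sample(0:3, 36, TRUE), 6, 6)
  q_rot <- t(q[nrow(q):1, ])   # 90 degree rotation
  dirs <- enumerate_directions(2)
  mats <- lapply(seq_len(nrow(dirs)), function(d)
    glcm(q, direction = dirs[d, ], levels = 4L)$matrix)
  mats_rot <- lapply(seq_len(nrow(dirs)), function(d)
    glcm(q_rot, direction = dirs[d, ], levels = 4L)$matrix)
  # every rotated-image GLCM appears among the original's direction set
  for (m in mats_rot) {
    found <- any(vapply(mats, function(o) isTRUE(all.equal(o, m, tolerance = 1e-12)),
                        TRUE))
    expect_true(found)
  }
})

test_that("haralick measures match direct formula evaluation", {
  h0 <- haralick(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(unname(h0["asm"]), 1)
  expect_equal(unname(h0["entropy"]), 0)
  expect_equal(unname(h0["contrast"]), 0)
  hc <- haralick(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(unname(hc["contrast"]), 1)
  expect_equal(unname(hc["asm"]), 0.5)
  expect_length(h0, 14)
  expect_named(h0, spectex:::haralick_names)
})

test_that("descriptor aggregates 13 directions into 28 ordered values", {
  vol <- array(0L, c(4, 4, 4))
  d0 <- descriptor(vol, levels = 2L)
  expect_length(d0, 28)
  expect_true(all(d0[15:28] == 0))        # isotropic constant: zero ranges
  # anisotropic stripes force inter-direction spread of contrast
  stripes <- array(rep(c(0L, 1L), 32), c(4, 4, 4))
  ds <- descriptor(stripes, levels = 2L)
  expect_gt(ds[["contrast_range"]], 0)
  expect_error(descriptor(matrix(0L, 3, 3)), "3D")
  # invariance to constant HU shift under roi-minmax quantization
  set.seed(15)
  v <- array(stats::rnorm(5^3), c(5, 5, 5))
  expect_equal(descriptor(quantize(v, 8), levels = 8L),
               descriptor(quantize(v + 100, 8), levels = 8L))
})

test_that("descriptor entries stay finite on random lesions", {
  set.seed(16)
  for (i in 1:30) {
    v <- array(sample(0:2, 6^3, TRUE), c(6, 6, 6))
    mask <- array(stats::runif(6^3) > 0.3, c(6, 6, 6))
    d <- descriptor(v, mask, levels = 3L)
    expect_true(all(is.finite(d)))
    expect_true(all(d[15:28] >= 0))
  }
})

test_that("difference images subtract neighboring channels", {
  fx <- chest_fixture()
  di <- difference_images(fx$truth)
  expect_equal(dim(di$data)[1], 4)
  expect_equal(attr(di, "pairs"), c("35-45", "45-55", "55-65", "65-75"))
  expect_equal(channel(di, 1), channel(fx$truth, 1) - channel(fx$truth, 2))
  # identical channels difference to zero
  dup <- spectral_image(array(1, c(3, 4, 4)), c(40, 50, 60))
  expect_true(all(difference_images(dup)$data == 0))
  # channels linear in energy give equal difference channels
  lin <- spectral_image(array(rep(c(10, 20, 30), each = 1),
                              c(3, 1, 1)), c(40, 50, 60))
  dl <- difference_images(lin)
  expect_equal(channel(dl, 1), channel(dl, 2))
  expect_error(difference_images(spectral_image(array(0, c(1, 2, 2)), 55)),
               "two channels")
})
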