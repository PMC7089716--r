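test_that("chest phantom has four connected tissues and is seed-deterministic", {
  ph <- make_chest_phantom(64, seed = 1)
  expect_setequal(unique(as.vector(ph$labels)), 1:4)
  expect_identical(ph$labels, make_chest_phantom(64, seed = 1)$labels)
  expect_false(identical(ph$labels, make_chest_phantom(64, seed = 2)$labels))
  expect_error(make_chest_phantom(16), "at least 32")

  # lung fields occupy a plausible fraction of the slice
  ph2 <- make_chest_phantom(128, seed = 2)
  lung_frac <- mean(ph2$labels == 1L)
  expect_gt(lung_frac, 0.1)
  expect_lt(lung_frac, 0.6)
})

test_that("tissue_phantom enforces label closure", {
  expect_error(tissue_phantom(matrix(1:4, 2), c("1" = "a", "2" = "b")),
               "tissue_table")
  ph <- tissue_phantom(matrix(1L, 2, 2), c("1" = "a"))
  expect_s3_class(ph, "tissue_phantom")
})

test_that("lesion cohort mirrors the requested class counts and sizes", {
  coh <- cohort_full()
  expect_length(coh$samples, 63)
  expect_equal(sum(coh$manifest$label == "benign"), 31)
  expect_equal(sum(coh$manifest$label == "malignant"), 32)
  expect_true(all(coh$manifest$size_mm > 0))
  # material labels: background + the three pure materials
  labs <- unique(unlist(lapply(coh$samples, function(s)
    unique(as.vector(s$volume$labels)))))
  expect_setequal(labs, 0:3)
  # deterministic
  coh2 <- make_lesion_cohort(31, 32, seed = 7)
  expect_identical(coh$samples[[5]]$volume$labels,
                   coh2$samples[[5]]$volume$labels)
  expect_error(make_lesion_cohort(0, 3), "at least one")
  expect_error(make_lesion_cohort(2, 2, size_spec = c(benign = -1, malignant = 40)),
               "positive")
})

test_that("malignant lesions are more heterogeneous than benign ones", {
  coh <- cohort_full()
  v <- vapply(coh$samples, function(s) {
    img <- synthesize_spectral(s$volume, 75)
    stats::var(channel(img, 1)[s$volume$labels > 0L])
  }, 0)
  lab <- coh$manifest$label
  expect_gt(mean(v[lab == "malignant"]), mean(v[lab == "benign"]))
})

test_that("identical texture specs give indistinguishable voxel distributions", {
  spec <- default_texture_spec()
  spec$malignant <- spec$benign
  coh <- make_lesion_cohort(10, 10, texture_spec = spec, seed = 3)
  # lesions are the independent sampling units (voxels within a lesion are
  # strongly clustered), so the two-sample test compares per-lesion means
  mean_hu <- vapply(coh$samples, function(s)
    mean(channel(synthesize_spectral(s$volume, 75), 1)[s$volume$labels > 0L]),
    0)
  lab <- coh$manifest$label
  tt <- stats::t.test(mean_hu[lab == "benign"], mean_hu[lab == "malignant"])
  expect_gt(tt$p.value, 0.01)
})

test_that("widening the heterogeneity gap never hurts single-channel separation", {
  # three gap levels: benign fixed, malignant correlation length shrinking
  aucs <- vapply(c(6, 4.5, 3), function(cl_mal) {
    spec <- default_texture_spec()
    spec$malignant$corr_len_mm <- cl_mal
    coh <- make_lesion_cohort(10, 10, texture_spec = spec, seed = 11)
    v <- vapply(coh$samples, function(s) {
      img <- synthesize_spectral(s$volume, 75)
      stats::var(channel(img, 1)[s$volume$labels > 0L])
    }, 0)
    auc(v, coh$manifest$label)
  }, 0)
  expect_true(all(diff(aucs) >= -0.1))   # monotone up to stochastic slack
})
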