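make_rn_mask <- function(dims, slice_counts_by_index) {
  m <- array(FALSE, dims)
  for (s in names(slice_counts_by_index)) {
    k <- slice_counts_by_index[[s]]
    if (k > 0) m[seq_len(k), 1, as.integer(s)] <- TRUE
  }
  m
}

test_that("analysis slices start where the red nucleus fades", {
  g <- voxel_grid(c(32, 32, 20), c(0.5, 0.5, 1))
  rn <- make_rn_mask(g$dims, list(`10` = 5, `11` = 20, `12` = 20, `13` = 20,
                                  `14` = 5))
  # threshold ceil(0.1 * 20) = 2; first caudal slice with count < 2 is 15
  expect_equal(select_analysis_slices(rn, g, fraction = 0.1), c(15L, 16L, 17L))

  expect_error(select_analysis_slices(array(FALSE, g$dims), g), "empty")
  # RN still visible on the final slice: no inferior slices available
  rn_last <- make_rn_mask(g$dims, list(`19` = 10, `20` = 10))
  expect_error(select_analysis_slices(rn_last, g), "geometry error")
  rn_tail <- make_rn_mask(g$dims, list(`17` = 10, `18` = 10))
  expect_error(select_analysis_slices(rn_tail, g), "fewer than 3")
})

test_that("slice selection is invariant to flipping the in-plane axes", {
  g <- voxel_grid(c(32, 32, 20), c(0.5, 0.5, 1))
  rn <- array(FALSE, g$dims)
  rn[10:14, 12:15, 8:12] <- TRUE
  s0 <- select_analysis_slices(rn, g)
  flipped <- rn[rev(seq_len(32)), rev(seq_len(32)), ]
  expect_equal(select_analysis_slices(flipped, g), s0)
})

test_that("thresholded volume counts qualifying voxels times voxel volume", {
  g <- voxel_grid(c(10, 10, 5), c(0.5, 0.5, 1))   # 0.25 mm^3 voxels
  img <- array(100, g$dims)
  region <- array(FALSE, g$dims)
  region[1:10, 1:4, 2] <- TRUE                    # 40 voxels on slice 2
  expect_equal(thresholded_volume(img, region, 2, 150, "below", g), 10)
  expect_equal(thresholded_volume(img, region, 2, 50, "below", g), 0)
  expect_equal(thresholded_volume(img, region, 2, 50, "above", g), 10)
  expect_error(thresholded_volume(img, region, 9, 150, "below", g), "index error")
})

test_that("threshold search maximizes the group AUC over the grid", {
  set.seed(31)
  # PD subjects carry few low values, HC many: separable at threshold 0
  vals <- c(lapply(1:8, function(i) rnorm(40, 2, 0.2)),
            lapply(1:8, function(i) c(rnorm(25, -1, 0.2), rnorm(15, 2, 0.2))))
  labels <- rep(c("PD", "HC"), each = 8)
  res <- optimize_threshold(vals, labels, seq(-2, 3, by = 0.25), "below")
  expect_equal(res$objective, 1.0)
  expect_true(res$threshold %in% res$grid$threshold)
  expect_true(all(res$objective >= res$grid$objective))
  # brute-force scan agreement
  brute <- vapply(res$grid$threshold, function(t) {
    v <- vapply(vals, function(x) sum(x < t), 0)
    auc_bruteforce(v, labels)
  }, 0)
  expect_equal(res$grid$objective, brute, tolerance = 1e-12)

  # permuted labels give chance-level objective
  set.seed(7)
  aucs <- replicate(20, {
    optimize_threshold(vals, sample(labels), 0, "below")$objective
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
  expect_error(optimize_threshold(vals, rep("PD", 16), 0, "below"), "both groups")
})

test_that("NMS contrast range uses linear-interpolation percentiles", {
  g <- voxel_grid(c(10, 10, 3), c(0.5, 0.5, 1))
  region <- array(FALSE, g$dims)
  region[1:10, 1, 2] <- TRUE
  nms <- array(0, g$dims)
  nms[1:10, 1, 2] <- 1:10
  expect_equal(nms_contrast_range(nms, region, 2, g), 9.1 / 1.9,
               tolerance = 1e-12)
  nms[1:10, 1, 2] <- 7
  expect_equal(nms_contrast_range(nms, region, 2, g), 1.0)
  nms[1:10, 1, 2] <- c(-1, -1, -1, 1:7)
  expect_error(nms_contrast_range(nms, region, 2, g), "undefined-ratio")
  region[3:10, 1, 2] <- FALSE
  expect_error(nms_contrast_range(nms, region, 2, g), "10 region voxels")
})

test_that("composite score reproduces the printed group medians' ordering", {
  pd_product <- composite_score(27.50, 16.00, 1.139)
  expect_equal(pd_product, 501.16, tolerance = 1e-10)
  hc_product <- composite_score(98.00, 51.00, 1.173)
  # PD-median product below the reported optimal cutoff, HC-median above
  expect_lt(pd_product, 2178.62)
  expect_gt(hc_product, 2178.62)
  expect_equal(composite_score(0, 16, 1.1), 0)
  expect_error(composite_score(-1, 2, 3), "domain error")
})

test_that("SMWI N1 volume detects residual hyperintensity only", {
  g <- voxel_grid(c(20, 20, 6), c(0.5, 0.5, 1))
  sn <- array(FALSE, g$dims); sn[6:15, 6:15, 2:4] <- TRUE
  smwi <- array(1, g$dims)      # background level 1
  smwi[sn] <- 0                 # fully iron-saturated SN
  expect_equal(n1_volume_smwi(smwi, sn, 2:4, g, rel_threshold = 0.2), 0)
  smwi[8:10, 8:10, 3] <- 0.9    # bright N1 islet: 9 voxels
  expect_equal(n1_volume_smwi(smwi, sn, 2:4, g, rel_threshold = 0.2),
               9 * 0.25)
  expect_error(n1_volume_smwi(smwi, array(FALSE, g$dims), 2:4, g), "empty SN")
})

test_that("hemisphere aggregation averages values and AND-combines ratings", {
  expect_equal(aggregate_hemispheres(10, 20, "mean"), 15)
  expect_equal(aggregate_hemispheres("Normal", "Abnormal", "both_normal"),
               "Abnormal")
  expect_equal(aggregate_hemispheres("Abnormal", "Normal", "both_normal"),
               "Abnormal")
  expect_equal(aggregate_hemispheres("Normal", "Normal", "both_normal"),
               "Normal")
  expect_error(aggregate_hemispheres(NA, 3, "mean"), "left")
  expect_error(aggregate_hemispheres(3, NULL, "mean"), "right")
})
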