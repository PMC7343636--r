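test_that("Gaussian smoothing conserves constants and impulse mass", {
  const <- array(7.5, dim = c(12, 12, 12))
  expect_equal(gaussian_smooth(const), const, tolerance = 1e-12)

  imp <- array(0, dim = c(16, 16, 16))
  imp[8, 8, 8] <- 100
  sm <- gaussian_smooth(imp)
  expect_equal(sum(sm), 100, tolerance = 1e-9)
  expect_gte(min(sm), 0)
  expect_equal(which.max(sm), which.max(imp))
})

test_that("smoothing twice matches a single pass at sigma * sqrt(2)", {
  set.seed(6)
  vox <- gaussian_smooth(array(runif(20^3, 0, 100), dim = c(20, 20, 20)),
                         segmentation_params(9, 1.5))
  twice <- gaussian_smooth(gaussian_smooth(vox, segmentation_params(13, 1.5)),
                           segmentation_params(13, 1.5))
  once <- gaussian_smooth(vox, segmentation_params(19, 1.5 * sqrt(2)))
  i <- 8:13
  expect_equal(twice[i, i, i], once[i, i, i], tolerance = 1e-3)
})

test_that("oversized kernels are rejected", {
  expect_error(gaussian_smooth(array(1, dim = c(4, 32, 32)),
                               segmentation_params(16, 2)),
               "larger than the volume axis")
})

test_that("Otsu separates a bimodal volume", {
  vox <- array(rep(c(10, 200), each = 500), dim = c(10, 10, 10))
  thr <- otsu_threshold(vox)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_identical(sum(vox > thr), 500L)
  expect_error(otsu_threshold(array(5, dim = c(4, 4, 4))), "degenerate")
})

test_that("Otsu matches the exhaustive intra-class variance oracle", {
  # the worked example: the best cut separates {1,1,2,2} from {8,9,9}
  v <- array(c(1, 1, 2, 2, 8, 9, 9, 1), dim = c(2, 2, 2))
  thr <- otsu_threshold(v)
  masks <- otsu_oracle_masks(v)
  expect_true(any(vapply(masks, function(m) identical(m, v > thr),
                         logical(1))))
  expect_identical(v > thr, array(v >= 8, dim(v)))

  set.seed(7)
  for (i in 1:30) {
    d <- sample(3:6, 3, replace = TRUE)
    vals <- sample(seq(0, 1, length.out = 65), sample(4:20, 1))
    v <- array(sample(vals, prod(d), replace = TRUE), dim = d)
    if (length(unique(as.numeric(v))) < 2) next
    thr <- otsu_threshold(v)
    masks <- otsu_oracle_masks(v)
    expect_true(any(vapply(masks, function(m) identical(m, v > thr),
                           logical(1))),
                info = paste("volume", i))
  }
})

test_that("corner-touching voxels connect under 26- but not 6-connectivity", {
  vox <- array(0, dim = c(4, 4, 4))
  vox[2, 2, 2] <- 1
  vox[3, 3, 3] <- 1  # shares only a corner
  expect_identical(nrow(label_components(vox, 26)$objects), 1L)
  expect_identical(nrow(label_components(vox, 6)$objects), 2L)

  edge <- array(0, dim = c(4, 4, 4))
  edge[2, 2, 2] <- 1
  edge[2, 3, 3] <- 1  # shares an edge
  expect_identical(nrow(label_components(edge, 18)$objects), 1L)
  expect_identical(nrow(label_components(edge, 6)$objects), 2L)
})

test_that("component labeling matches the flood-fill oracle", {
  set.seed(8)
  for (i in 1:10) {
    d <- sample(3:8, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.4, dim = d)
    for (conn in c(6, 26)) {
      got <- label_components(mask, conn)$label_volume
      want <- flood_fill_labels(mask, conn)
      expect_identical(canonical_labels(got), canonical_labels(want))
    }
  }
})

test_that("labels are consecutive and voxel counts add up", {
  set.seed(9)
  mask <- array(runif(6 * 10 * 10) < 0.3, dim = c(6, 10, 10))
  res <- label_components(mask, 26)
  expect_identical(res$objects$label, seq_len(nrow(res$objects)))
  expect_identical(sum(res$objects$voxel_count),
                   sum(res$label_volume != 0))
  expect_identical(sum(res$objects$voxel_count), sum(mask))
})

test_that("small-object removal keeps only objects at the size threshold", {
  # disjoint straight segments of sizes 3, 4, 5, 6
  vox <- array(0, dim = c(4, 8, 30))
  sizes <- c(3, 4, 5, 6)
  for (i in seq_along(sizes)) vox[2, 4, (i * 7 - 5):(i * 7 - 6 + sizes[i])] <- 1
  res <- label_components(vox, 26)
  expect_identical(sort(res$objects$voxel_count), c(3L, 4L, 5L, 6L))
  kept <- remove_small_objects(res, 5)
  expect_identical(sort(kept$objects$voxel_count), c(5L, 6L))
  expect_identical(kept$objects$label, 1:2)
  expect_identical(sum(kept$label_volume != 0), 11L)

  expect_identical(nrow(remove_small_objects(label_components(
    array(0, dim = c(4, 4, 4)), 26), 5)$objects), 0L)
  expect_identical(remove_small_objects(res, 1)$objects$voxel_count,
                   res$objects$voxel_count)
})

test_that("size filter and connectivity behave monotonically", {
  set.seed(10)
  vox <- gaussian_smooth(array(runif(12^3, 0, 100), dim = c(12, 12, 12)),
                         segmentation_params(5, 1))
  mask <- vox > otsu_threshold(vox)
  res <- label_components(mask, 26)
  counts <- vapply(1:8, function(m)
    nrow(remove_small_objects(res, m)$objects), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_lte(nrow(label_components(mask, 26)$objects),
             nrow(label_components(mask, 6)$objects))
  expect_lte(nrow(label_components(mask, 18)$objects),
             nrow(label_components(mask, 6)$objects))
})

test_that("segmenting a featureless stack yields no objects", {
  expect_identical(nrow(segment(array(0, dim = c(8, 16, 16)))$objects), 0L)
  expect_identical(nrow(segment(array(42, dim = c(8, 16, 16)))$objects), 0L)
})

test_that("well-separated phantom cells are counted exactly, with signal from raw intensities", {
  cfg <- small_phantom_config(noise = noise_off(),
                              misregistration = rigid_transform(0, 0, 0),
                              rng_seed = 34)
  ph <- generate_phantom(cfg)
  stack <- ph$pre$RFP_532$fluorescence
  res <- segment(stack)
  expect_identical(nrow(res$objects), nrow(ph$truth$tumor_cell_centers_pre))
  expect_true(all(res$objects$voxel_count >= 5))
  # total_fluorescence sums the pre-smoothing intensities over each object
  lv <- res$label_volume
  manual <- vapply(res$objects$label, function(l)
    sum(stack$voxels[lv == l]), numeric(1))
  expect_equal(res$objects$total_fluorescence, manual)
})

test_that("segmentations round-trip through label TIFF and object CSV", {
  set.seed(16)
  mask <- array(runif(6 * 12 * 12) < 0.2, dim = c(6, 12, 12))
  res <- label_components(mask, 26)
  lp <- withr::local_tempfile(fileext = ".tif")
  tp <- withr::local_tempfile(fileext = ".csv")
  write_segmentation(res, lp, tp)
  back <- read_stack(lp, acquisition_metadata())
  expect_equal(array(as.integer(back$voxels), dim(mask)), res$label_volume)
  tab <- read.csv(tp)
  expect_identical(tab$voxel_count, res$objects$voxel_count)
  expect_equal(tab$total_fluorescence, res$objects$total_fluorescence)
})

test_that("object counts at default noise stay within 5% of truth", {
  cfg <- small_phantom_config(rng_seed = 35)
  ph <- generate_phantom(cfg)
  res <- segment(normalize_stack(ph$pre$RFP_532$fluorescence, ref_norm()))
  truth <- nrow(ph$truth$tumor_cell_centers_pre)
  expect_lte(abs(nrow(res$objects) - truth) / truth, 0.05)
})
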