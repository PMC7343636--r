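test_that("identical seed and config give bit-identical phantoms", {
  cfg <- small_phantom_config(rng_seed = 21, kill_fraction_tumor = 0.3)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$pre$RFP_532$fluorescence$voxels,
                   b$pre$RFP_532$fluorescence$voxels)
  expect_identical(a$post$GFP_488$reflectance$voxels,
                   b$post$GFP_488$reflectance$voxels)
  expect_identical(a$truth$tumor_cell_centers_pre,
                   b$truth$tumor_cell_centers_pre)
})

test_that("ground-truth counts follow the configured kill fractions", {
  cfg <- phantom_config(volume_shape = c(20, 160, 160),
                        n_spheroids = 5, spheroid_radius_um = 20,
                        n_cells_per_spheroid = 40, cell_spacing_um = 6,
                        n_keratinocytes = 500,
                        kill_fraction_tumor = 0.5,
                        kill_fraction_keratinocyte = 0.25,
                        rng_seed = 22)
  ph <- generate_phantom(cfg)
  expect_identical(nrow(ph$truth$tumor_cell_centers_pre), 200L)
  expect_identical(nrow(ph$truth$tumor_cell_centers_post), 100L)
  expect_identical(nrow(ph$truth$keratinocyte_centers_pre), 500L)
  expect_identical(nrow(ph$truth$keratinocyte_centers_post), 375L)
  expect_identical(unname(ph$truth$true_kill_fractions["tumor"]), 0.5)
})

test_that("a no-op treatment leaves post stacks voxel-identical to pre", {
  cfg <- small_phantom_config(kill_fraction_tumor = 0,
                              kill_fraction_keratinocyte = 0,
                              noise = noise_off(),
                              misregistration = rigid_transform(0, 0, 0),
                              rng_seed = 23)
  ph <- generate_phantom(cfg)
  expect_identical(ph$pre$RFP_532$fluorescence$voxels,
                   ph$post$RFP_532$fluorescence$voxels)
  expect_identical(ph$pre$GFP_488$fluorescence$voxels,
                   ph$post$GFP_488$fluorescence$voxels)
})

test_that("every ground-truth center lies inside the volume", {
  cfg <- small_phantom_config(kill_fraction_tumor = 0.4, rng_seed = 24)
  ph <- generate_phantom(cfg)
  d <- cfg$volume_shape
  for (tab in list(ph$truth$tumor_cell_centers_pre,
                   ph$truth$keratinocyte_centers_pre)) {
    expect_true(all(tab$z >= 1 & tab$z <= d[1]))
    expect_true(all(tab$y >= 1 & tab$y <= d[2]))
    expect_true(all(tab$x >= 1 & tab$x <= d[3]))
  }
})

test_that("noise-free truth centers are local intensity maxima", {
  cfg <- small_phantom_config(noise = noise_off(),
                              misregistration = rigid_transform(0, 0, 0),
                              rng_seed = 25)
  ph <- generate_phantom(cfg)
  vox <- ph$pre$RFP_532$fluorescence$voxels
  d <- dim(vox)
  pitch <- c(cfg$z_spacing_um, cfg$lateral_pixel_um, cfg$lateral_pixel_um)
  r_vox <- cfg$cell_radius_um / pitch
  tr <- ph$truth$tumor_cell_centers_pre
  for (i in seq_len(nrow(tr))) {
    c0 <- round(c(tr$z[i], tr$y[i], tr$x[i]))
    zi <- max(1, c0[1] - floor(r_vox[1])):min(d[1], c0[1] + floor(r_vox[1]))
    yi <- max(1, c0[2] - floor(r_vox[2])):min(d[2], c0[2] + floor(r_vox[2]))
    xi <- max(1, c0[3] - floor(r_vox[3])):min(d[3], c0[3] + floor(r_vox[3]))
    expect_gte(vox[c0[1], c0[2], c0[3]], max(vox[zi, yi, xi]) - 1)
  }
})

test_that("rendered objects match ground truth in a noise-free phantom", {
  cfg <- small_phantom_config(noise = noise_off(),
                              misregistration = rigid_transform(0, 0, 0),
                              rng_seed = 26)
  ph <- generate_phantom(cfg)
  seg_r <- segment(ph$pre$RFP_532$fluorescence)
  seg_g <- segment(ph$pre$GFP_488$fluorescence)
  expect_identical(nrow(seg_r$objects), nrow(ph$truth$tumor_cell_centers_pre))
  expect_identical(nrow(seg_g$objects),
                   sum(ph$truth$keratinocyte_centers_pre$labeled))
})

test_that("a volume too small for the requested spheroids errors clearly", {
  expect_error(generate_phantom(phantom_config(volume_shape = c(16, 16, 16),
                                               rng_seed = 1)),
               "volume too small|field of view is too small")
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(kill_fraction_tumor = 1.2), "\\[0, 1\\]")
  expect_error(phantom_config(volume_shape = c(8, 64, 64)), "at least 16")
  expect_error(phantom_config(z_spacing_um = 0.9), "1.5")
  expect_error(phantom_config(laser_power_factor = c(bogus = 2)),
               "scale factors")
})

test_that("bleed-through copies the tumor scene into the GFP channel", {
  cfg <- small_phantom_config(n_keratinocytes = 0,
                              bleed_through_coefficient = 0.5,
                              misregistration = rigid_transform(0, 0, 0),
                              rng_seed = 27)
  ph <- generate_phantom(cfg)
  seg_g <- segment(normalize_stack(ph$pre$GFP_488$fluorescence, ref_norm()))
  seg_r <- segment(normalize_stack(ph$pre$RFP_532$fluorescence, ref_norm()))
  expect_identical(nrow(seg_g$objects), nrow(seg_r$objects))
})

test_that("simulated datasets are written complete and loadable", {
  outdir <- withr::local_tempdir()
  man <- simulate_dataset(outdir, groups = c(control = 1, treated_1x = 1),
                          base_config = small_phantom_config(),
                          seed = 28)
  tifs <- list.files(outdir, pattern = "\\.tif$")
  expect_length(tifs, 2 * 2 * 2 * 2)  # samples x timepoints x channels x modes
  expect_length(list.files(outdir, pattern = "_rois\\.json$"), 2)
  expect_length(list.files(outdir, pattern = "_truth\\.json$"), 2)
  recs <- load_manifest(man)
  expect_length(recs, 2)
  expect_length(recs[[1]]$tumor_rois, 2)
  st <- read_stack(recs[[1]]$acquisitions$fluorescence_path[1],
                   acquisition_metadata())
  expect_identical(dim(st$voxels), c(18L, 112L, 112L))
})
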