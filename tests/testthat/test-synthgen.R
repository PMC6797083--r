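# Synthetic micrograph generator: determinism, geometry fidelity, expansion
# algebra, halo phenotypes, noise calibration.

test_that("same spec and seed give bit-identical scenes", {
  spec <- noisy_scene_spec(n = 8L)
  a <- render_scene(spec, 11)
  b <- render_scene(spec, 11)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- render_scene(spec, 12)
  expect_false(identical(a$image, c$image))
})

test_that("empty scene is pure background noise with empty truth", {
  spec <- scene_spec(c(64L, 64L), 0.1, list(species_spec("sp", 1, 0, 2, 0)),
                     counts = 0L, background_level = 0.3,
                     psf_sigma_um = 0, noise = list(shot_scale = 0,
                                                    read_sd = 0.05))
  sc <- render_scene(spec, 5)
  expect_equal(nrow(sc$truth), 0L)
  expect_equal(mean(sc$image), 0.3, tolerance = 0.01)
  expect_gt(stats::sd(as.vector(sc$image)), 0.04)
})

test_that("noiseless rendering matches the analytic spherocylinder mask", {
  spec <- clean_scene_spec(n = 10L, width = 1.0, width_sd = 0.1, len = 3,
                           len_sd = 0.3)
  sc <- render_scene(spec, 3)
  mask <- sc$image > 0.5
  oracle <- matrix(FALSE, 512, 512)
  for (i in seq_len(nrow(sc$truth))) {
    tr <- sc$truth[i, ]
    oracle <- oracle | sphero_mask(512, 512, tr$x_um, tr$y_um,
                                   tr$orientation_rad, tr$length_um,
                                   tr$width_um, 0.1)
  }
  expect_identical(mask, oracle)
  # component count equals truth count when cells are well separated
  comps <- uexm:::cpp_label_components(mask)
  expect_equal(max(comps), nrow(sc$truth))
})

test_that("fixed-width cells span their width in pixels across the short axis", {
  spec <- clean_scene_spec(n = 10L, width = 1.0)
  sc <- render_scene(spec, 21)
  comps <- uexm:::cpp_label_components(sc$image > 0.5)
  expect_equal(max(comps), 10L)
  for (k in seq_len(10)) {
    idx <- which(comps == k)
    rr <- (idx - 1L) %% 512 + 1L
    cc <- (idx - 1L) %/% 512 + 1L
    # short-axis extent via projection onto the minor principal axis
    ax <- long_axis(rr, cc, 1)
    # a 10-px-diameter disk covers 10 or 11 pixel centers depending on the
    # subpixel position of the axis
    expect_gte(ax$minor_extent_um, 10)
    expect_lte(ax$minor_extent_um, 11.5)
  }
})

test_that("scene validation and crowding errors", {
  expect_error(scene_spec(c(64L, 64L), 0,
                          list(species_spec("s", 1, 0, 2, 0)), 1L),
               "pixel_size_um")
  expect_error(species_spec("s", 1, 0, 0.5, 0), "rod")
  expect_error(species_spec("s", 1, 0, 2, 0, expansion_factor = 0.5), ">= 1")
  # total area above 30% of the frame
  dense <- scene_spec(c(50L, 50L), 0.1, list(species_spec("s", 1, 0, 2, 0)),
                      counts = 10L, min_separation_um = 0,
                      psf_sigma_um = 0, noise = list(shot_scale = 0,
                                                     read_sd = 0))
  expect_error(render_scene(dense, 1), "too crowded")
  # feasible area but unsatisfiable separation
  sparse <- scene_spec(c(100L, 100L), 0.1, list(species_spec("s", 1, 0, 2, 0)),
                       counts = 5L, min_separation_um = 8,
                       psf_sigma_um = 0, noise = list(shot_scale = 0,
                                                      read_sd = 0))
  expect_error(render_scene(sparse, 1), "too crowded")
})

test_that("expansion pair: rigid wall keeps widths, gel scales positions", {
  spec <- clean_scene_spec(n = 6L, width = 1.0, width_sd = 0.1,
                           expansion = 1)
  pair <- render_expansion_pair(spec, 9)
  expect_equal(pair$post_truth$width_um, pair$pre_truth$width_um)
  expect_equal(pair$post_truth$length_um, pair$pre_truth$length_um)
  d_pre <- dist(cbind(pair$pre_truth$x_um, pair$pre_truth$y_um))
  d_post <- dist(cbind(pair$post_truth$x_um, pair$post_truth$y_um))
  expect_equal(as.vector(d_post), 4 * as.vector(d_pre), tolerance = 1e-12)
  expect_equal(dim(pair$post_image), 4L * dim(pair$pre_image))
})

test_that("expansion pair: width scaling is exact multiplication", {
  spec22 <- clean_scene_spec(n = 5L, width = 0.8, expansion = 2.2)
  pair <- render_expansion_pair(spec22, 2)
  expect_equal(pair$post_truth$width_um, rep(0.8 * 2.2, 5), tolerance = 1e-12)
  # full digestion: everything expands with the gel
  spec4 <- clean_scene_spec(n = 5L, width = 0.8, width_sd = 0.05,
                            expansion = 4)
  pair4 <- render_expansion_pair(spec4, 2)
  expect_equal(pair4$post_truth$width_um, 4 * pair4$pre_truth$width_um,
               tolerance = 1e-12)
  # gel must keep up with the most expandable species
  bad <- clean_scene_spec(n = 2L, expansion = 1)
  bad$gel_factor <- 1
  bad$species[[1]]$expansion_factor <- 2
  expect_error(render_expansion_pair(bad, 1), "gel_factor")
})

test_that("halo scene: phenotype channels and binomial assignment", {
  spec <- clean_scene_spec(n = 12L, width = 0.8, shape = c(400L, 400L),
                           sep = 8)
  none <- render_halo_scene(spec, halo_fraction = 0, seed = 4)
  expect_true(all(none$truth$phenotype == "normal"))
  # DNA colocalizes with cytoplasm: same support at half their amplitudes
  expect_identical(none$dna_image > 0.4, none$cyto_image > 0.5)
  all_h <- render_halo_scene(spec, halo_fraction = 1, halo_factor = 4,
                             seed = 4)
  expect_true(all(all_h$truth$phenotype == "halo"))
  expect_equal(all_h$truth$halo_width_um, 4 * all_h$truth$width_um)
  # the same cells are drawn regardless of halo_fraction (coupled draws)
  expect_equal(none$truth$width_um, all_h$truth$width_um)
  expect_error(render_halo_scene(spec, 0.5, halo_factor = 1, seed = 1),
               "halo_factor")
  expect_error(render_halo_scene(spec, 1.5, seed = 1), "halo_fraction")
})

test_that("halo count over many cells follows the binomial draw", {
  spec <- scene_spec(c(600L, 600L), 0.1,
                     list(species_spec("sp", 0.5, 0.03, 1.5, 0.1)),
                     counts = 1000L, min_separation_um = 0,
                     background_level = 0, psf_sigma_um = 0,
                     noise = list(shot_scale = 0, read_sd = 0))
  sc <- render_halo_scene(spec, halo_fraction = 0.3, seed = 17)
  n_halo <- sum(sc$truth$phenotype == "halo")
  expect_lt(abs(n_halo - 300), 3 * sqrt(1000 * 0.3 * 0.7))
})

test_that("shot-noise variance tracks the configured scale", {
  for (shot in c(100, 400)) {
    spec <- scene_spec(c(200L, 200L), 0.1,
                       list(species_spec("sp", 1, 0, 2, 0)), counts = 0L,
                       background_level = 0.5, psf_sigma_um = 0,
                       noise = list(shot_scale = shot, read_sd = 0))
    sc <- render_scene(spec, 23)
    # every pixel is an independent replicate of Poisson(0.5 * shot) / shot
    expect_equal(stats::var(as.vector(sc$image)), 0.5 / shot,
                 tolerance = 0.1)
  }
})
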