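test_that("bubble phantom matches the per-voxel digitization oracle", {
  # zero bubbles: all solid
  sp0 <- phantom_spec("bubbles", dims = c(16, 16, 16), voxel_size_um = 16,
                      seed = 1, radius_params = list(radius_um = 32,
                                                     count = 0))
  t0 <- gen_bubbles(sp0)
  expect_identical(t0$true_void_fraction, 0)

  # one radius-8-voxel sphere in 64^3
  sp1 <- phantom_spec("bubbles", dims = c(64, 64, 64), voxel_size_um = 10,
                      seed = 5, radius_params = list(radius_um = 80,
                                                     count = 1))
  t1 <- gen_bubbles(sp1)
  expect_identical(nrow(t1$feature_log), 1L)
  ctr <- unlist(t1$feature_log[1, c("cz_vox", "cy_vox", "cx_vox")])
  # independent oracle: per-voxel centre-distance test over the lattice
  oracle <- make_sphere_mask(c(64, 64, 64), ctr, 8)
  expect_identical(t1$binary$mask, oracle)
  expect_identical(t1$true_void_fraction, mean(oracle))
  # near the continuum value, within digitization error
  expect_lt(abs(t1$true_void_fraction - 4 / 3 * pi * 8^3 / 64^3) /
              (4 / 3 * pi * 8^3 / 64^3), 0.03)
})

test_that("bubble generation is a pure function of the spec", {
  sp <- phantom_spec("bubbles", dims = c(48, 48, 48), voxel_size_um = 16,
                     seed = 77,
                     radius_params = list(meanlog = log(60), sdlog = 0.2,
                                          count = 12))
  a <- gen_bubbles(sp); b <- gen_bubbles(sp)
  expect_identical(a$binary$mask, b$binary$mask)
  expect_identical(a$feature_log, b$feature_log)
})

test_that("non-overlap policy keeps bubbles disconnected", {
  sp <- phantom_spec("bubbles", dims = c(60, 60, 60), voxel_size_um = 16,
                     seed = 3, radius_params = list(radius_um = 64,
                                                    count = 20))
  tr <- gen_bubbles(sp)
  lab <- voidnet:::cpp_label_components(as.logical(tr$binary$mask),
                                        dim(tr$binary$mask), 26L)
  expect_identical(max(lab), 20L)
})

test_that("infeasible bubble packing fails with the achieved fraction", {
  sp <- phantom_spec("bubbles", dims = c(20, 20, 20), voxel_size_um = 16,
                     seed = 1,
                     radius_params = list(radius_um = 7 * 16, count = 50))
  expect_error(gen_bubbles(sp), "infeasible")
})

test_that("axis-aligned uniform slab has exactly thickness/extent fraction", {
  pl <- list(list(point = c(24, 24.5, 24.5), normal = c(1, 0, 0),
                  thickness_vox = 3, extent_vox = Inf))
  sp <- phantom_spec("cracks", dims = c(50, 50, 50), voxel_size_um = 16,
                     seed = 1, crack_params = list(planes = pl))
  tr <- gen_cracks(sp)
  expect_identical(tr$true_void_fraction, 3 / 50)
  # void exactly on layers z = 23, 24, 25 (0-based)
  expect_true(all(tr$binary$mask[24:26, , ]))
  expect_identical(sum(tr$binary$mask), 3L * 50L * 50L)
})

test_that("intersecting slabs obey inclusion-exclusion", {
  mk <- function(planes) {
    sp <- phantom_spec("cracks", dims = c(40, 40, 40), voxel_size_um = 16,
                       seed = 1, crack_params = list(planes = planes))
    gen_cracks(sp)
  }
  p1 <- list(point = c(19, 19.5, 19.5), normal = c(1, 0, 0),
             thickness_vox = 3, extent_vox = Inf)
  p2 <- list(point = c(19.5, 19, 19.5), normal = c(0, 1, 0),
             thickness_vox = 3, extent_vox = Inf)
  va <- mk(list(p1))$true_void_fraction
  vb <- mk(list(p2))$true_void_fraction
  vab <- mk(list(p1, p2))$true_void_fraction
  expect_lt(vab, va + vb)
  # exact inclusion-exclusion on the voxel counts
  n <- 40^3
  expect_equal(vab * n, va * n + vb * n - (3 * 3 * 40), tolerance = 1e-12)
})

test_that("crack generation is seed-deterministic", {
  sp <- phantom_spec("cracks", dims = c(40, 40, 40), voxel_size_um = 16,
                     seed = 9, crack_params = list(n_planes = 4,
                                                   thickness_vox = 2))
  expect_identical(gen_cracks(sp)$binary$mask, gen_cracks(sp)$binary$mask)
})

test_that("sintered quantile thresholding hits the target fraction", {
  sp <- phantom_spec("sintered", dims = c(48, 48, 48), voxel_size_um = 16,
                     seed = 2,
                     blob_params = list(corr_length_vox = 2,
                                        field = "excursion",
                                        largest_component_only = FALSE),
                     target_void_fraction = 0.12)
  tr <- gen_sintered(sp)
  expect_lt(abs(tr$true_void_fraction - 0.12), 0.005)
  expect_identical(tr$true_void_fraction, mean(tr$binary$mask))
})

test_that("target void fractions outside (0,1) are rejected", {
  expect_error(phantom_spec("sintered", dims = c(8, 8, 8),
                            blob_params = list(corr_length_vox = 2),
                            target_void_fraction = 0), "\\(0, 1\\)")
  expect_error(phantom_spec("sintered", dims = c(8, 8, 8),
                            blob_params = list(corr_length_vox = 2),
                            target_void_fraction = 1.2), "\\(0, 1\\)")
})

test_that("vanishing smoothing length gives salt-and-pepper voids", {
  share <- sapply(c(0, 3), function(cl) {
    sp <- phantom_spec("sintered", dims = c(40, 40, 40), voxel_size_um = 16,
                       seed = 4,
                       blob_params = list(corr_length_vox = cl,
                                          field = "excursion",
                                          largest_component_only = FALSE),
                       target_void_fraction = 0.15)
    m <- gen_sintered(sp)$binary$mask
    lab <- voidnet:::cpp_label_components(as.logical(m), dim(m), 6L)
    max(tabulate(lab[lab > 0])) / sum(m)
  })
  expect_lt(share[1], 0.05)  # unsmoothed: speckle, no large-scale structure
  expect_gt(share[2], 10 * share[1])
})

test_that("phantom spec demands exactly its morphology's parameter block", {
  expect_error(phantom_spec("bubbles", dims = c(8, 8, 8)), "radius_params")
  expect_error(phantom_spec("bubbles", dims = c(8, 8, 8),
                            radius_params = list(radius_um = 16, count = 1),
                            crack_params = list(n_planes = 1)),
               "not used")
})

test_that("noise-free rendering is exactly two-valued with phase counts", {
  sp <- phantom_spec("bubbles", dims = c(24, 24, 24), voxel_size_um = 16,
                     seed = 6, radius_params = list(radius_um = 64,
                                                    count = 3))
  tr <- gen_bubbles(sp)
  g <- render_grayscale(tr, solid_mode = 180, void_mode = 60, noise_sd = 0,
                        blur_sigma_vox = 0, seed = 1)
  expect_setequal(unique(as.vector(g$data)), c(60L, 180L))
  expect_identical(sum(g$data == 60), sum(tr$binary$mask))
})

test_that("rendered contrast supports near-perfect thresholding", {
  sp <- phantom_spec("bubbles", dims = c(48, 48, 48), voxel_size_um = 16,
                     seed = 8, radius_params = list(radius_um = 80,
                                                    count = 10))
  tr <- gen_bubbles(sp)
  g <- render_grayscale(tr, solid_mode = 180, void_mode = 60, noise_sd = 10,
                        blur_sigma_vox = 1, seed = 2)
  # sweep every threshold; the best must misclassify < 1% of voxels
  miscl <- sapply(0:255, function(t)
    mean((g$data <= t) != tr$binary$mask))
  expect_lt(min(miscl), 0.01)
})

test_that("rendering is seed-deterministic and validates arguments", {
  sp <- phantom_spec("bubbles", dims = c(16, 16, 16), voxel_size_um = 16,
                     seed = 2, radius_params = list(radius_um = 48,
                                                    count = 2))
  tr <- gen_bubbles(sp)
  expect_identical(render_grayscale(tr, seed = 42)$data,
                   render_grayscale(tr, seed = 42)$data)
  expect_error(render_grayscale(tr, solid_mode = 90, void_mode = 90),
               "differ")
  expect_error(render_grayscale(tr, noise_sd = -1), "noise_sd")
})
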