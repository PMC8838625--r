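test_that("distance map is exact on analytic fixtures", {
  # single void voxel surrounded by solid
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  d <- distance_map(binary_volume(m, 16))
  expect_identical(d$values[2, 2, 2], 1)
  expect_true(all(d$values[!m] == 0))

  # 5-layer void slab: centre layer at distance 3
  m2 <- array(FALSE, c(11, 9, 9)); m2[4:8, , ] <- TRUE
  d2 <- distance_map(binary_volume(m2, 16))
  # centre of the volume is away from the lateral border shell
  expect_identical(d2$values[6, 5, 5], 3)
  expect_identical(d2$values[4, 5, 5], 1)
})

test_that("distance map equals exhaustive nearest-solid search", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- array(runif(16^3) < 0.4, c(16, 16, 16))
    d <- distance_map(binary_volume(m, 16))
    expect_equal(d$values, brute_force_edt(m), tolerance = 1e-12)
  }
})

test_that("border counts as solid for the distance map", {
  m <- array(TRUE, c(5, 5, 5)) # all-void: border shell bounds the distances
  d <- distance_map(binary_volume(m, 16))
  expect_identical(d$values[1, 1, 1], 1)
  expect_identical(d$values[3, 3, 3], 3)
})

test_that("maximal-ball pruning leaves no contained pair", {
  # digitized radius-8 cavity
  m <- make_sphere_mask(c(24, 24, 24), c(11, 11, 11), 8)
  dm <- distance_map(binary_volume(m, 16))
  balls <- extract_maximal_balls(dm)
  expect_false(any_contained_pair(balls))
  at_ctr <- balls[balls$z == 11 & balls$y == 11 & balls$x == 11, ]
  expect_identical(nrow(at_ctr), 1L)
  expect_gte(at_ctr$radius_vox, 7.5)

  # random small masks: oracle over the full retained set
  for (seed in 5:7) {
    set.seed(seed)
    mr <- array(runif(12^3) < 0.5, c(12, 12, 12))
    br <- extract_maximal_balls(distance_map(binary_volume(mr, 16)))
    expect_false(any_contained_pair(br))
  }
})

test_that("degenerate voids give the expected ball sets", {
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  b1 <- extract_maximal_balls(distance_map(binary_volume(m, 16)))
  expect_identical(nrow(b1), 1L)
  expect_identical(b1$radius_vox, 1)

  m[2, 2, 2] <- FALSE
  b0 <- extract_maximal_balls(distance_map(binary_volume(m, 16)))
  expect_identical(nrow(b0), 0L)

  m2 <- array(FALSE, c(8, 8, 8)); m2[2, 2, 2] <- TRUE; m2[6, 6, 6] <- TRUE
  b2 <- extract_maximal_balls(distance_map(binary_volume(m2, 16)))
  expect_identical(nrow(b2), 2L)
})

test_that("a single cavity yields one pore and no throats", {
  m <- make_sphere_mask(c(24, 24, 24), c(11, 11, 11), 8)
  net <- extract_network(binary_volume(m, 16))
  expect_identical(nrow(net$pores), 1L)
  expect_identical(nrow(net$throats), 0L)
  expect_identical(net$pores$coordination, 0L)
  expect_identical(net$pores$voxel_count, sum(m))
})

test_that("dumbbell recovery: two pores, one saddle throat", {
  m <- make_dumbbell_mask()
  net <- extract_network(binary_volume(m, 16))
  expect_identical(nrow(net$pores), 2L)
  expect_identical(nrow(net$throats), 1L)
  expect_identical(net$pores$coordination, c(1L, 1L))
  # neck radius 3 voxels, within 1 voxel
  expect_lt(abs(net$throats$radius_um / 16 - 3), 1)
  # saddle below both peaks
  expect_lte(net$throats$radius_um,
             min(net$pores$radius_um) + 1e-9)
  # cylinder throat volume model
  expect_equal(net$throats$volume_um3,
               pi * net$throats$radius_um^2 * net$throats$length_um)
})

test_that("partition and degree identities hold on varied phantoms", {
  specs <- list(
    gen_bubbles(phantom_spec("bubbles", dims = c(40, 40, 40),
                             voxel_size_um = 16, seed = 2,
                             radius_params = list(radius_um = 56,
                                                  count = 8))),
    gen_cracks(phantom_spec("cracks", dims = c(40, 40, 40),
                            voxel_size_um = 16, seed = 3,
                            crack_params = list(n_planes = 2,
                                                thickness_vox = 2.2))),
    gen_sintered(phantom_spec("sintered", dims = c(40, 40, 40),
                              voxel_size_um = 16, seed = 4,
                              blob_params = list(corr_length_vox = 3),
                              target_void_fraction = 0.12)))
  for (tr in specs) {
    net <- extract_network(tr$binary)
    expect_identical(sum(net$pores$voxel_count), sum(tr$binary$mask))
    expect_identical(net$void_voxel_count, sum(tr$binary$mask))
    expect_identical(sum(net$pores$coordination), 2L * nrow(net$throats))
    if (nrow(net$throats) > 0) {
      rmin <- pmin(net$pores$radius_um[match(net$throats$pore_a,
                                             net$pores$id)],
                   net$pores$radius_um[match(net$throats$pore_b,
                                             net$pores$id)])
      expect_true(all(net$throats$radius_um <= rmin + 1e-9))
    }
  }
})

test_that("extraction is deterministic", {
  tr <- gen_sintered(phantom_spec("sintered", dims = c(32, 32, 32),
                                  voxel_size_um = 16, seed = 11,
                                  blob_params = list(corr_length_vox = 2.5),
                                  target_void_fraction = 0.15))
  n1 <- extract_network(tr$binary)
  n2 <- extract_network(tr$binary)
  expect_identical(n1$pores, n2$pores)
  expect_identical(n1$throats, n2$throats)
})

test_that("region assignment matches an independent R watershed", {
  tr <- gen_sintered(phantom_spec("sintered", dims = c(12, 12, 12),
                                  voxel_size_um = 16, seed = 13,
                                  blob_params = list(corr_length_vox = 1.2,
                                                     field = "excursion",
                                                     largest_component_only
                                                     = FALSE),
                                  target_void_fraction = 0.25))
  dm <- distance_map(tr$binary)
  seeds <- voidnet:::cpp_find_seeds(as.vector(dm$values), dm$dims)
  sd_d <- dm$values[seeds + 1L]
  o <- order(-sd_d, seeds[, 1], seeds[, 2], seeds[, 3])
  seeds <- seeds[o, , drop = FALSE]
  lab_cpp <- array(voidnet:::cpp_grow_regions(as.vector(dm$values), dm$dims,
                                              seeds), dm$dims)
  lab_r <- r_watershed_regions(dm$values, seeds)
  expect_identical(lab_cpp, lab_r)
})

test_that("build_network validates ball/dmap consistency", {
  m <- make_sphere_mask(c(12, 12, 12), c(5, 5, 5), 4)
  dm <- distance_map(binary_volume(m, 16))
  balls <- extract_maximal_balls(dm)
  balls$radius_vox[1] <- balls$radius_vox[1] + 0.5
  expect_error(build_network(balls, dm), "mismatch")
})

test_that("empty mask produces an empty network", {
  dm <- distance_map(binary_volume(array(FALSE, c(6, 6, 6)), 16))
  net <- build_network(extract_maximal_balls(dm), dm)
  expect_identical(nrow(net$pores), 0L)
  expect_identical(nrow(net$throats), 0L)
  expect_identical(net$void_voxel_count, 0)
})

test_that("small-feature filter drops pores below the radius floor", {
  m <- make_sphere_mask(c(30, 30, 30), c(7, 7, 7), 5) |
    make_sphere_mask(c(30, 30, 30), c(21, 21, 21), 2)
  net_all <- extract_network(binary_volume(m, 16))
  expect_identical(nrow(net_all$pores), 2L)
  net_f <- extract_network(binary_volume(m, 16),
                           min_pore_radius_um = 4 * 16)
  expect_identical(nrow(net_f$pores), 1L)
  expect_gte(min(net_f$pores$radius_um), 4 * 16)
  expect_identical(sum(net_f$pores$voxel_count), net_f$void_voxel_count)
})
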