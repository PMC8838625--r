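toy_network <- function(coords) {
  # coords: list(pores = n, throats = matrix of (a, b))
  n <- coords$n
  pores <- data.frame(id = seq_len(n), cx_um = seq_len(n) * 10,
                      cy_um = 0, cz_um = 0,
                      radius_um = rep(20, n), volume_um3 = rep(1000, n))
  tm <- coords$throats
  throats <- if (is.null(tm)) {
    data.frame(id = integer(0), pore_a = integer(0), pore_b = integer(0),
               radius_um = numeric(0), length_um = numeric(0),
               volume_um3 = numeric(0))
  } else {
    data.frame(id = seq_len(nrow(tm)), pore_a = tm[, 1], pore_b = tm[, 2],
               radius_um = 5, length_um = 10, volume_um3 = pi * 25 * 10)
  }
  pore_network(pores, throats, voxel_size_um = 16, void_voxel_count = n)
}

test_that("void fraction is the voxel ratio", {
  expect_identical(void_fraction(binary_volume(array(FALSE, c(5, 5, 5)),
                                               16)), 0)
  expect_identical(void_fraction(binary_volume(array(TRUE, c(5, 5, 5)),
                                               16)), 1)
  m <- array(FALSE, c(10, 10, 10)); m[1:4, 1:4, 1:4] <- TRUE
  expect_identical(void_fraction(binary_volume(m, 16)), 0.064)
})

test_that("connectivity equals 2T/P", {
  expect_identical(connectivity(toy_network(list(n = 1, throats = NULL))), 0)
  expect_identical(connectivity(toy_network(list(n = 2,
                                                 throats = rbind(c(1, 2))))),
                   1)
  tri <- toy_network(list(n = 3, throats = rbind(c(1, 2), c(2, 3),
                                                 c(1, 3))))
  expect_identical(connectivity(tri), 2)
  empty <- toy_network(list(n = 1, throats = NULL))
  empty$pores <- empty$pores[0, ]
  expect_error(connectivity(empty), "empty")
})

test_that("coordination distributions count throat incidences", {
  iso2 <- toy_network(list(n = 2, throats = NULL))
  expect_identical(coordination_distribution(iso2), c("0" = 1))
  dumb <- toy_network(list(n = 2, throats = rbind(c(1, 2))))
  expect_identical(coordination_distribution(dumb), c("1" = 1))
  mix <- toy_network(list(n = 4, throats = rbind(c(1, 2), c(2, 3),
                                                 c(1, 3))))
  expect_identical(coordination_distribution(mix), c("0" = 0.25,
                                                     "2" = 0.75))
})

test_that("r43 matches closed forms and the brute-force oracle", {
  one <- data.frame(radius_um = 25, volume_um3 = 123)
  expect_identical(r43(one), 25)
  two <- data.frame(radius_um = c(1, 2),
                    volume_um3 = 4 / 3 * pi * c(1, 8))
  expect_equal(r43(two), 17 / 9, tolerance = 1e-15)

  set.seed(21)
  r <- rlnorm(1000, log(40), 0.4)
  f <- data.frame(radius_um = r, volume_um3 = 4 / 3 * pi * r^3)
  expect_equal(r43(f), sum(r^4) / sum(r^3), tolerance = 1e-9)
  # volume weighting pulls the mean above the unweighted mean
  expect_gt(r43(f), mean(r))
  # order invariance
  p <- sample.int(1000)
  expect_identical(r43(f[p, ]), r43(f[p, ]))
  expect_equal(r43(f[p, ]), r43(f), tolerance = 1e-12)

  expect_error(r43(data.frame(radius_um = numeric(0),
                              volume_um3 = numeric(0))), "empty")
  expect_error(r43(data.frame(radius_um = 1, volume_um3 = 0)), "positive")
})

test_that("radius binning snaps to the nearest 5-um tick, ties up", {
  f1 <- data.frame(radius_um = 12.4, volume_um3 = 1)
  expect_identical(names(weighted_radius_distribution(f1)), "10")
  f2 <- data.frame(radius_um = 12.5, volume_um3 = 1)
  expect_identical(names(weighted_radius_distribution(f2)), "15")

  set.seed(8)
  r <- runif(200, 1, 90); v <- runif(200, 1, 10)
  f <- data.frame(radius_um = r, volume_um3 = v)
  got <- weighted_radius_distribution(f)
  # brute-force per-feature assignment
  want <- tapply(v, floor(r / 5 + 0.5) * 5, sum)
  want <- want / sum(want)
  expect_equal(as.numeric(got), as.numeric(want[names(got)]),
               tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)
  # order invariance
  p <- sample.int(200)
  expect_equal(weighted_radius_distribution(f[p, ]), got,
               tolerance = 1e-12)
})

test_that("micropore boundary is inclusive at 10 um", {
  expect_identical(classify_micropores(data.frame(radius_um = 10)), 1)
  expect_identical(classify_micropores(data.frame(radius_um = 9.9)), 0)
  expect_equal(classify_micropores(data.frame(radius_um = c(5, 10, 15))),
               2 / 3, tolerance = 1e-15)
  f <- data.frame(radius_um = c(5, 15), volume_um3 = c(1, 3))
  expect_equal(classify_micropores(f, by = "volume"), 0.75)
})

test_that("replicate distribution averaging re-sums to one", {
  d1 <- c("10" = 1)
  expect_identical(average_replicate_distributions(list(d1)), c("10" = 1))
  d2 <- c("20" = 1)
  expect_identical(average_replicate_distributions(list(d1, d2)),
                   c("10" = 0.5, "20" = 0.5))
  set.seed(14)
  mk <- function() {
    bins <- sort(sample(seq(0, 50, 5), 4))
    w <- runif(4); stats::setNames(w / sum(w), bins)
  }
  ds <- list(mk(), mk(), mk())
  got <- average_replicate_distributions(ds)
  bins <- sort(unique(as.numeric(unlist(lapply(ds, names)))))
  want <- sapply(as.character(bins), function(b)
    mean(sapply(ds, function(d) if (b %in% names(d)) d[[b]] else 0)))
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)
})

test_that("replicate summaries use the n-1 standard deviation", {
  s1 <- summarize_replicates(2)
  expect_identical(s1$mean, 2)
  expect_false(s1$sd_defined)
  s2 <- summarize_replicates(c(1, 3))
  expect_identical(s2$mean, 2)
  expect_equal(s2$sd, sqrt(2), tolerance = 1e-12)
  v <- c(0.39, 0.42, 0.10)
  s3 <- summarize_replicates(v)
  expect_equal(s3$mean, mean(v), tolerance = 1e-15)
  expect_equal(s3$sd, sqrt(sum((v - mean(v))^2) / 2), tolerance = 1e-12)
  expect_error(summarize_replicates(numeric(0)), "no replicate")
})

test_that("void_metrics bundles consistent per-replicate descriptors", {
  tr <- gen_bubbles(phantom_spec("bubbles", dims = c(40, 40, 40),
                                 voxel_size_um = 16, seed = 30,
                                 radius_params = list(radius_um = 64,
                                                      count = 6)))
  net <- extract_network(tr$binary)
  vm <- void_metrics(net, tr$binary)
  expect_identical(vm$v, mean(tr$binary$mask))
  expect_identical(vm$z, 0)
  expect_identical(vm$pore_count, 6L)
  expect_equal(sum(vm$pore_radius_distribution), 1, tolerance = 1e-9)
  expect_equal(sum(vm$coord_distribution), 1, tolerance = 1e-9)
  expect_identical(vm$micropore_fraction, 1) # 64-um bubbles are micropores
})
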