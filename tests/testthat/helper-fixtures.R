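# Geometric fixtures built in code, plus slow independent oracles used to
# cross-check the compiled extraction path.

# digitized sphere: voxel void iff its 0-based centre lies inside the sphere
make_sphere_mask <- function(dims, center, radius) {
  z <- 0:(dims[1] - 1); y <- 0:(dims[2] - 1); x <- 0:(dims[3] - 1)
  arr <- outer(outer((z - center[1])^2, (y - center[2])^2, `+`),
               (x - center[3])^2, `+`) <= radius^2
  array(arr, dims)
}

# two spherical cavities bridged by an x-aligned cylindrical neck
make_dumbbell_mask <- function(dims = c(24, 24, 56), r_sphere = 8,
                               r_neck = 3) {
  cz <- (dims[1] - 1) / 2; cy <- (dims[2] - 1) / 2
  x1 <- 13; x2 <- dims[3] - 14
  m <- make_sphere_mask(dims, c(cz, cy, x1), r_sphere) |
    make_sphere_mask(dims, c(cz, cy, x2), r_sphere)
  z <- 0:(dims[1] - 1); y <- 0:(dims[2] - 1)
  disk <- outer((z - cz)^2, (y - cy)^2, `+`) <= r_neck^2
  for (xi in x1:x2) m[, , xi + 1] <- m[, , xi + 1] | disk
  m
}

# exhaustive nearest-solid-centre search (border counts as solid at
# distance 1 beyond the lattice), vectorised over the full distance matrix
brute_force_edt <- function(mask) {
  dims <- dim(mask)
  out <- array(0, dims)
  S <- which(!mask, arr.ind = TRUE)
  V <- which(mask, arr.ind = TRUE)
  if (nrow(V) == 0) return(out)
  d2 <- if (nrow(S) > 0) {
    g <- V %*% t(S)
    sw <- sweep(-2 * g, 1, rowSums(V^2), `+`)
    apply(sweep(sw, 2, rowSums(S^2), `+`), 1, min)
  } else rep(Inf, nrow(V))
  # virtual solid shell one step outside each face
  border <- pmin(V[, 1], V[, 2], V[, 3],
                 dims[1] + 1 - V[, 1], dims[2] + 1 - V[, 2],
                 dims[3] + 1 - V[, 3])^2
  out[V] <- sqrt(pmin(d2, border))
  out
}

# O(n^2) containment oracle over a ball set: TRUE if some pair violates the
# "no retained ball inside another" rule
any_contained_pair <- function(balls, eps = 1e-9) {
  n <- nrow(balls)
  if (n < 2) return(FALSE)
  co <- as.matrix(balls[, c("z", "y", "x")])
  r <- balls$radius_vox
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(co) - co[i, ])^2))
    inside <- d + r <= r[i] + eps
    inside[i] <- FALSE
    if (any(inside)) return(TRUE)
  }
  FALSE
}

# independent (plain R) watershed of -d seeded at the same maxima: one
# frontier voxel is assigned per iteration — the highest-d unassigned void
# voxel touching an assigned region (ties lexicographic on 0-based
# (z, y, x)) joins its highest-d assigned neighbour (ties: lower label)
r_watershed_regions <- function(d, seeds) {
  dims <- dim(d)
  lab <- array(0L, dims)
  for (k in seq_len(nrow(seeds)))
    lab[seeds[k, 1] + 1, seeds[k, 2] + 1, seeds[k, 3] + 1] <- k
  shift3 <- function(a, o, fill) {
    out <- array(fill, dims)
    src_z <- max(1, 1 - o[1]):min(dims[1], dims[1] - o[1])
    src_y <- max(1, 1 - o[2]):min(dims[2], dims[2] - o[2])
    src_x <- max(1, 1 - o[3]):min(dims[3], dims[3] - o[3])
    out[src_z + o[1], src_y + o[2], src_x + o[3]] <-
      a[src_z, src_y, src_x]
    out
  }
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  # 0-based coordinates for lexicographic tie-breaks
  coord <- arrayInd(seq_len(prod(dims)), dims) - 1L
  repeat {
    bestd <- array(-Inf, dims)
    bestlab <- array(0L, dims)
    for (k in seq_len(nrow(nb))) {
      ls <- shift3(lab, nb[k, ], 0L)
      ds <- shift3(d, nb[k, ], 0)
      upd <- ls > 0 & (ds > bestd | (ds == bestd & ls < bestlab))
      bestd[upd] <- ds[upd]
      bestlab[upd] <- ls[upd]
    }
    frontier <- which(d > 0 & lab == 0 & bestlab > 0)
    if (length(frontier) == 0) break
    o <- order(-d[frontier], coord[frontier, 1], coord[frontier, 2],
               coord[frontier, 3])
    v <- frontier[o[1]]
    lab[v] <- bestlab[v]
  }
  lab
}

# small random pore network for round-trip tests
random_network <- function(n_pores, n_throats, seed = 1) {
  set.seed(seed)
  pores <- data.frame(id = seq_len(n_pores),
                      cx_um = runif(n_pores, 0, 1000),
                      cy_um = runif(n_pores, 0, 1000),
                      cz_um = runif(n_pores, 0, 1000),
                      radius_um = runif(n_pores, 5, 80),
                      volume_um3 = runif(n_pores, 1e3, 1e6))
  throats <- if (n_throats > 0) {
    ab <- t(replicate(n_throats, sample.int(n_pores, 2)))
    data.frame(id = seq_len(n_throats), pore_a = ab[, 1], pore_b = ab[, 2],
               radius_um = runif(n_throats, 1, 40),
               length_um = runif(n_throats, 10, 300),
               volume_um3 = runif(n_throats, 1e2, 1e5))
  } else {
    data.frame(id = integer(0), pore_a = integer(0), pore_b = integer(0),
               radius_um = numeric(0), length_um = numeric(0),
               volume_um3 = numeric(0))
  }
  pore_network(pores, throats, voxel_size_um = 16, void_voxel_count = 0)
}
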