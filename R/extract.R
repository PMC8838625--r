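#' Euclidean distance map of a void mask
#'
#' For every void voxel, the Euclidean distance (in voxel units) from its
#' centre to the nearest solid voxel centre; zero on solid. The volume
#' border is treated as a virtual solid shell, so no inscribed ball extends
#' past the field of view. The distance doubles as the maximally inscribed
#' sphere radius at that voxel (centre-to-centre convention, no -0.5 surface
#' correction; the constant offset cancels in comparisons).
#'
#' @param binary a [binary_volume()].
#' @return A `distance_map`: `values` (3D array, voxel units),
#'   `voxel_size_um`, `dims`.
#' @export
distance_map <- function(binary) {
  stopifnot(inherits(binary, "binary_volume"))
  d <- cpp_edt(as.logical(binary$mask), binary$dims)
  structure(list(values = array(d, dim = binary$dims),
                 voxel_size_um = binary$voxel_size_um, dims = binary$dims),
            class = "distance_map")
}

#' Extract the retained maximal-ball set
#'
#' Every void voxel seeds a candidate ball of radius `d(x)`. A ball
#' `B(c2, r2)` is redundant if some other candidate `B(c1, r1)` satisfies
#' `|c1 - c2| + r2 <= r1 + 1e-9`; redundant balls are removed and the
#' retained set traces the medial axis of the void. Mutual containment
#' (equal balls within tolerance) keeps the lexicographically smallest
#' centre on `(z, y, x)`.
#'
#' @param dmap a [distance_map()].
#' @return Data frame with 0-based voxel coordinates `z`, `y`, `x` and
#'   `radius_vox`, sorted by decreasing radius then lexicographic centre.
#' @export
extract_maximal_balls <- function(dmap) {
  stopifnot(inherits(dmap, "distance_map"))
  idx <- which(dmap$values > 0)
  if (length(idx) == 0)
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      radius_vox = numeric(0)))
  co <- arrayInd(idx, dmap$dims) - 1L # 0-based (z, y, x)
  r <- dmap$values[idx]
  keep <- cpp_prune_balls(co, r, 1e-9)
  co <- co[keep, , drop = FALSE]; r <- r[keep]
  o <- order(-r, co[, 1], co[, 2], co[, 3])
  data.frame(z = co[o, 1], y = co[o, 2], x = co[o, 3], radius_vox = r[o])
}

#' Construct (or validate) a pore network
#'
#' Coordination numbers are always recomputed from the throat table, so the
#' degree identity `sum(coordination) == 2 * nrow(throats)` holds by
#' construction.
#'
#' @param pores data frame: `id`, `cx_um`, `cy_um`, `cz_um`, `radius_um`,
#'   `volume_um3` (assigned-voxel volume), plus optional bookkeeping columns.
#' @param throats data frame: `id`, `pore_a`, `pore_b`, `radius_um`,
#'   `length_um`, `volume_um3`.
#' @param voxel_size_um micrometres per voxel edge.
#' @param void_voxel_count total void voxels the pores partition.
#' @param extraction_params named list recording every extraction decision.
#' @return A `pore_network`.
#' @export
pore_network <- function(pores, throats, voxel_size_um,
                         void_voxel_count = NA_real_,
                         extraction_params = list()) {
  if (nrow(throats) > 0) {
    if (any(throats$pore_a == throats$pore_b))
      stop("self-loop throat (pore_a == pore_b)")
    bad <- setdiff(c(throats$pore_a, throats$pore_b), pores$id)
    if (length(bad))
      stop("throat references unknown pore id(s): ",
           paste(bad, collapse = ", "))
  }
  inc <- c(throats$pore_a, throats$pore_b)
  pores$coordination <- as.integer(table(factor(inc, levels = pores$id)))
  structure(list(pores = pores, throats = throats,
                 voxel_size_um = voxel_size_um,
                 void_voxel_count = void_voxel_count,
                 extraction_params = extraction_params),
            class = "pore_network")
}

#' @export
print.pore_network <- function(x, ...) {
  cat(sprintf("<pore_network> %d pores, %d throats, z = %.3f\n",
              nrow(x$pores), nrow(x$throats),
              if (nrow(x$pores)) 2 * nrow(x$throats) / nrow(x$pores)
              else NA_real_))
  invisible(x)
}

# union-find with path compression
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build the pore-throat network from a distance map
#'
#' The maximal-ball discretization of the void:
#' \enumerate{
#'   \item pore seeds are the plateau-collapsed local maxima of the distance
#'     field over the 26-neighbourhood (one seed per connected equal-d
#'     plateau, its lexicographically smallest voxel);
#'   \item every void voxel is assigned to exactly one pore by descending-d
#'     priority flooding from the seeds (equivalently, a watershed of `-d`):
#'     the highest-d frontier voxel joins the region of its highest-d
#'     already-assigned 26-neighbour, ties to the lower region id, so pore
#'     regions partition the void;
#'   \item each 26-adjacent region pair defines a throat whose radius is the
#'     saddle height of the interface (the minimal inscribed ball along the
#'     connecting path);
#'   \item pore pairs whose throat radius exceeds `merge_ratio` times the
#'     smaller pore radius are merged (iterated to a fixed point), since such
#'     a "throat" is as wide as the pore it feeds;
#'   \item throat length is the centre-to-centre distance minus both pore
#'     radii, clamped to at least one voxel; throat volume uses the cylinder
#'     model `pi * r^2 * length`; pore volume is the assigned-voxel volume.
#' }
#'
#' @param balls retained maximal balls from [extract_maximal_balls()] on the
#'   same distance map (consistency-checked; the ball field underlies the
#'   seed/saddle construction).
#' @param dmap the [distance_map()].
#' @param merge_ratio throat-to-pore radius ratio above which two pores are
#'   merged (default 0.7).
#' @return A `pore_network`; `extraction_params` records all conventions.
#' @export
build_network <- function(balls, dmap, merge_ratio = 0.7) {
  stopifnot(inherits(dmap, "distance_map"))
  h <- dmap$voxel_size_um
  d <- dmap$values
  dims <- dmap$dims
  nvoid <- sum(d > 0)
  if (nrow(balls) > 0) {
    rr <- d[cbind(balls$z + 1L, balls$y + 1L, balls$x + 1L)]
    if (max(abs(rr - balls$radius_vox)) > 1e-9)
      stop("`balls` do not match `dmap` (radius mismatch)")
  }
  params <- list(radius_convention = "center_to_center",
                 border = "solid", connectivity = 26L,
                 saddle = "max over interface pairs of min(d_i, d_j)",
                 merge_ratio = merge_ratio,
                 throat_multiplicity = "one per adjacent pore pair",
                 containment_eps = 1e-9)

  if (nvoid == 0) {
    return(pore_network(
      data.frame(id = integer(0), cx_um = numeric(0), cy_um = numeric(0),
                 cz_um = numeric(0), radius_um = numeric(0),
                 volume_um3 = numeric(0)),
      data.frame(id = integer(0), pore_a = integer(0), pore_b = integer(0),
                 radius_um = numeric(0), length_um = numeric(0),
                 volume_um3 = numeric(0)),
      voxel_size_um = h, void_voxel_count = 0, extraction_params = params))
  }

  seeds <- cpp_find_seeds(as.vector(d), dims)
  sd_d <- d[seeds + 1L]
  o <- order(-sd_d, seeds[, 1], seeds[, 2], seeds[, 3])
  seeds <- seeds[o, , drop = FALSE]
  sd_d <- sd_d[o]
  lab <- cpp_grow_regions(as.vector(d), dims, seeds)
  nreg <- nrow(seeds)
  if (sum(lab > 0) != nvoid)
    stop("region growth did not cover the void phase") # cannot happen: every
  # connected void component contains at least one maximum plateau
  vox_count <- tabulate(lab[lab > 0], nbins = nreg)
  sad <- cpp_find_throats(as.vector(d), lab, dims)

  # region state (voxel units); seed rows align with region ids 1..nreg
  reg <- list(radius = sd_d, z = seeds[, 1], y = seeds[, 2], x = seeds[, 3],
              vox = vox_count)
  edges <- if (nrow(sad)) data.frame(a = as.integer(sad[, 1]),
                                     b = as.integer(sad[, 2]),
                                     r = sad[, 3])
           else data.frame(a = integer(0), b = integer(0), r = numeric(0))

  # iterative merge to fixed point
  repeat {
    if (nrow(edges) == 0) break
    ratio <- edges$r / pmin(reg$radius[edges$a], reg$radius[edges$b])
    mg <- which(ratio > merge_ratio)
    if (length(mg) == 0) break
    n <- length(reg$radius)
    parent <- seq_len(n)
    for (k in mg) {
      ra <- .uf_find(parent, edges$a[k]); rb <- .uf_find(parent, edges$b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), function(i) .uf_find(parent, i), 1L)
    new_id <- match(root, sort(unique(root)))
    # aggregate: representative = member with largest radius (ties: lowest id)
    ordm <- order(new_id, -reg$radius, seq_len(n))
    first <- ordm[!duplicated(new_id[ordm])]
    reg <- list(radius = reg$radius[first], z = reg$z[first],
                y = reg$y[first], x = reg$x[first],
                vox = as.vector(tapply(reg$vox, new_id, sum)))
    ea <- new_id[edges$a]; eb <- new_id[edges$b]
    keep <- ea != eb
    a2 <- pmin(ea[keep], eb[keep]); b2 <- pmax(ea[keep], eb[keep])
    if (length(a2)) {
      key <- paste(a2, b2)
      agg <- tapply(edges$r[keep], key, max)
      parts <- strsplit(names(agg), " ")
      edges <- data.frame(a = as.integer(vapply(parts, `[`, "", 1)),
                          b = as.integer(vapply(parts, `[`, "", 2)),
                          r = as.vector(agg))
    } else {
      edges <- data.frame(a = integer(0), b = integer(0), r = numeric(0))
    }
  }

  np <- length(reg$radius)
  pores <- data.frame(
    id = seq_len(np),
    cx_um = (reg$x + 0.5) * h, cy_um = (reg$y + 0.5) * h,
    cz_um = (reg$z + 0.5) * h,
    radius_um = reg$radius * h,
    volume_um3 = reg$vox * h^3,
    voxel_count = reg$vox)
  if (nrow(edges)) {
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    cc <- sqrt((reg$z[edges$a] - reg$z[edges$b])^2 +
               (reg$y[edges$a] - reg$y[edges$b])^2 +
               (reg$x[edges$a] - reg$x[edges$b])^2)
    len <- pmax(cc - reg$radius[edges$a] - reg$radius[edges$b], 1) * h
    r_um <- edges$r * h
    throats <- data.frame(id = seq_len(nrow(edges)), pore_a = edges$a,
                          pore_b = edges$b, radius_um = r_um,
                          length_um = len,
                          volume_um3 = pi * r_um^2 * len)
  } else {
    throats <- data.frame(id = integer(0), pore_a = integer(0),
                          pore_b = integer(0), radius_um = numeric(0),
                          length_um = numeric(0), volume_um3 = numeric(0))
  }
  pore_network(pores, throats, voxel_size_um = h, void_voxel_count = nvoid,
               extraction_params = params)
}

#' Segmented mask to pore network, in one call
#'
#' Convenience wrapper: [distance_map()], [extract_maximal_balls()],
#' [build_network()], plus an optional small-feature filter that drops pores
#' below a radius floor together with their incident throats (their voxels
#' leave the accounted void; default off).
#'
#' @param binary a [binary_volume()].
#' @param merge_ratio see [build_network()].
#' @param min_pore_radius_um drop pores smaller than this radius
#'   (default `NULL` = keep all).
#' @return A `pore_network`.
#' @export
extract_network <- function(binary, merge_ratio = 0.7,
                            min_pore_radius_um = NULL) {
  dmap <- distance_map(binary)
  balls <- extract_maximal_balls(dmap)
  net <- build_network(balls, dmap, merge_ratio = merge_ratio)
  if (!is.null(min_pore_radius_um)) {
    small <- net$pores$id[net$pores$radius_um < min_pore_radius_um]
    if (length(small)) {
      dropped_vox <- sum(net$pores$voxel_count[net$pores$id %in% small])
      keep_t <- !(net$throats$pore_a %in% small |
                    net$throats$pore_b %in% small)
      net <- pore_network(net$pores[!net$pores$id %in% small, , drop = FALSE],
                          net$throats[keep_t, , drop = FALSE],
                          voxel_size_um = net$voxel_size_um,
                          void_voxel_count = net$void_voxel_count -
                            dropped_vox,
                          extraction_params = c(net$extraction_params,
                                                list(min_pore_radius_um =
                                                       min_pore_radius_um)))
    }
  }
  net
}
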