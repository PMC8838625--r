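#' Phantom specification
#'
#' Describes a seeded synthetic void geometry of one of the three morphology
#' classes observed in sheared crystallized lipids: disconnected spherical
#' bubbles (air whipped into the melt), planar crack networks (brittle
#' post-process fracture), and percolating irregular "sintered" voids
#' (oil-displacement during crystal bridging). The seed fully determines the
#' output.
#'
#' @param morphology `"bubbles"`, `"cracks"` or `"sintered"`.
#' @param dims integer triple `(nz, ny, nx)`.
#' @param voxel_size_um micrometres per voxel edge.
#' @param seed integer seed; the generator is a pure function of the spec.
#' @param radius_params bubbles only: list with either `radius_um` (fixed) or
#'   `meanlog`/`sdlog` of a lognormal radius distribution in micrometres,
#'   plus optional `count` and/or `target_void_fraction`, `overlap`
#'   (`"forbidden"`/`"allowed"`), `clip` (allow bubbles to be cut by the
#'   border; default `FALSE` so each bubble is one whole pore).
#' @param crack_params cracks only: list with `n_planes`, `thickness_vox`
#'   (mean aperture, voxels), `extent_frac` (slab half-extent as a fraction
#'   of the lattice diagonal; `Inf` = full extent), `aperture_amp` and
#'   `aperture_wavelength_vox` (sinusoidal in-plane aperture modulation:
#'   cracks bulge into pores and pinch into throats; `aperture_amp = 0`
#'   gives uniform slabs), or an explicit `planes` list of
#'   `list(point, normal, thickness_vox, extent_vox)` records (uniform
#'   aperture).
#' @param blob_params sintered only: list with `corr_length_vox` (Gaussian
#'   smoothing length of the underlying random fields, voxels), `field`
#'   (`"channel"`, the default: the void follows the intersection of the
#'   nodal bands of two independent smoothed fields, a percolating network
#'   of irregular tubes; or `"excursion"`: low excursions of one smoothed
#'   field, disconnected blobs at low void fractions), and
#'   `largest_component_only` (drop satellite components, default `TRUE`
#'   for `"channel"`, `FALSE` for `"excursion"`).
#' @param target_void_fraction target void fraction in (0, 1) where the
#'   morphology uses one (bubbles stop criterion; sintered threshold
#'   quantile).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(morphology = c("bubbles", "cracks", "sintered"),
                         dims, voxel_size_um = 16, seed = 1L,
                         radius_params = NULL, crack_params = NULL,
                         blob_params = NULL, target_void_fraction = NULL) {
  morphology <- match.arg(morphology)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims > 0), voxel_size_um > 0)
  need <- switch(morphology, bubbles = "radius_params",
                 cracks = "crack_params", sintered = "blob_params")
  params <- list(radius_params = radius_params, crack_params = crack_params,
                 blob_params = blob_params)
  if (is.null(params[[need]]))
    stop("morphology '", morphology, "' requires `", need, "`")
  extra <- setdiff(names(Filter(Negate(is.null), params)), need)
  if (length(extra))
    stop("parameter block(s) not used by morphology '", morphology, "': ",
         paste(extra, collapse = ", "))
  if (!is.null(target_void_fraction) &&
      (target_void_fraction <= 0 || target_void_fraction >= 1))
    stop("`target_void_fraction` must lie in (0, 1)")
  structure(list(morphology = morphology, dims = dims,
                 voxel_size_um = voxel_size_um, seed = as.integer(seed),
                 radius_params = radius_params, crack_params = crack_params,
                 blob_params = blob_params,
                 target_void_fraction = target_void_fraction),
            class = "phantom_spec")
}

.phantom_truth <- function(spec, mask, feature_log) {
  list(binary = binary_volume(mask, spec$voxel_size_um,
                              provenance = paste0("phantom:", spec$morphology,
                                                  ":seed", spec$seed)),
       feature_log = feature_log,
       true_void_fraction = mean(mask),
       spec = spec)
}

# run expr under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# voxel-centre coordinates (0-based indices); a voxel is inside a sphere iff
# its centre is, which is also the brute-force oracle used in the tests
.voxelize_spheres <- function(dims, centers, radii) {
  mask <- array(FALSE, dim = dims)
  if (nrow(centers) == 0) return(mask)
  for (k in seq_len(nrow(radii))) {
    c0 <- centers[k, ]; r <- radii[k, 1]
    zr <- max(0, floor(c0[1] - r)):min(dims[1] - 1, ceiling(c0[1] + r))
    yr <- max(0, floor(c0[2] - r)):min(dims[2] - 1, ceiling(c0[2] + r))
    xr <- max(0, floor(c0[3] - r)):min(dims[3] - 1, ceiling(c0[3] + r))
    dz2 <- (zr - c0[1])^2; dy2 <- (yr - c0[2])^2; dx2 <- (xr - c0[3])^2
    sub <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2
    mask[zr + 1, yr + 1, xr + 1] <- mask[zr + 1, yr + 1, xr + 1] | sub
  }
  mask
}

#' Generate a spherical-bubble phantom
#'
#' Places voxelized spheres at uniformly proposed centres. Under the default
#' `overlap = "forbidden"` policy, proposals touching an accepted bubble are
#' rejected, so the ground-truth pore count equals the bubble count. Stops at
#' `radius_params$count` bubbles or at `target_void_fraction`, whichever is
#' requested.
#'
#' @param spec a [phantom_spec()] with `morphology = "bubbles"`.
#' @return A phantom-truth list: `binary` ([binary_volume()]), `feature_log`
#'   (data frame of accepted centres and radii, voxel units),
#'   `true_void_fraction` (recounted from the mask), `spec`.
#' @export
gen_bubbles <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$morphology == "bubbles")
  rp <- spec$radius_params
  count <- rp$count
  target <- spec$target_void_fraction
  if (is.null(count) && is.null(target))
    stop("radius_params$count or target_void_fraction required")
  overlap_ok <- identical(rp$overlap, "allowed")
  clip <- isTRUE(rp$clip)
  # 2-voxel solid clearance so digitized bubbles are never 26-adjacent
  gap <- if (is.null(rp$gap_vox)) 2 else rp$gap_vox
  dims <- spec$dims
  ntot <- prod(dims)

  .with_seed(spec$seed, {
    draw_r <- function() {
      if (!is.null(rp$radius_um)) rp$radius_um / spec$voxel_size_um
      else stats::rlnorm(1, rp$meanlog, rp$sdlog) / spec$voxel_size_um
    }
    acc <- matrix(numeric(0), ncol = 4) # z, y, x, r (voxel units)
    vox_acc <- 0
    tries <- 0
    budget <- 20000 + 400 * (if (is.null(count)) 10000 else count)
    repeat {
      if (!is.null(count) && nrow(acc) >= count) break
      if (!is.null(target) && vox_acc / ntot >= target) break
      if (tries > budget)
        stop(sprintf(paste0("bubble packing infeasible: achieved void ",
                            "fraction %.4f after %d proposals"),
                     vox_acc / ntot, tries))
      tries <- tries + 1
      r <- draw_r()
      if (2 * r > min(dims) && !clip)
        stop("bubble radius ", signif(r, 4), " voxels cannot fit inside dims")
      lo <- if (clip) c(0, 0, 0) else rep(r, 3)
      hi <- if (clip) dims - 1 else dims - 1 - r
      if (any(hi < lo)) next
      ctr <- lo + stats::runif(3) * (hi - lo)
      if (!overlap_ok && nrow(acc) > 0) {
        dd <- sqrt(colSums((t(acc[, 1:3, drop = FALSE]) - ctr)^2))
        if (any(dd < acc[, 4] + r + gap)) next
      }
      acc <- rbind(acc, c(ctr, r))
      vox_acc <- vox_acc + 4 / 3 * pi * r^3 # running estimate for the stop rule
    }
    mask <- .voxelize_spheres(dims, acc[, 1:3, drop = FALSE],
                              acc[, 4, drop = FALSE])
    log_df <- data.frame(cz_vox = acc[, 1], cy_vox = acc[, 2],
                         cx_vox = acc[, 3], radius_vox = acc[, 4])
    .phantom_truth(spec, mask, log_df)
  })
}

#' Generate a planar crack-network phantom
#'
#' The void is a union of finite-extent planar slabs with random
#' orientation, emulating the crack-like projections that propagate through
#' brittle crystallized networks. A voxel (0-based index `p`) is void for a
#' slab `(point, normal, thickness, extent)` iff
#' `|(p - point) . normal| <= aperture(p)/2` and the in-plane distance from
#' `point` is at most `extent`. By default the aperture is modulated
#' sinusoidally in the crack plane
#' (`aperture = thickness * (1 + amp * cos(u) * cos(v))`), so each sheet
#' bulges into pore bodies and pinches into throats the way physical cracks
#' do; explicit `planes` and `aperture_amp = 0` give uniform slabs.
#'
#' @param spec a [phantom_spec()] with `morphology = "cracks"`.
#' @return A phantom-truth list (see [gen_bubbles()]); `feature_log` records
#'   each plane's point, unit normal, thickness, extent and modulation
#'   phases (voxel units).
#' @export
gen_cracks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$morphology == "cracks")
  cp <- spec$crack_params
  dims <- spec$dims
  diag_len <- sqrt(sum((dims - 1)^2))

  planes <- cp$planes
  if (is.null(planes)) {
    if (is.null(cp$n_planes) || cp$n_planes < 1) {
      if (!is.null(spec$target_void_fraction))
        stop("zero crack planes requested with a nonzero target fraction")
      stop("crack_params$n_planes must be >= 1")
    }
    amp <- if (is.null(cp$aperture_amp)) 0.6 else cp$aperture_amp
    wl <- if (is.null(cp$aperture_wavelength_vox)) 18
          else cp$aperture_wavelength_vox
    planes <- .with_seed(spec$seed, {
      lapply(seq_len(cp$n_planes), function(i) {
        n <- stats::rnorm(3); n <- n / sqrt(sum(n^2))
        pt <- stats::runif(3, 0.15, 0.85) * (dims - 1)
        ext <- if (is.null(cp$extent_frac) || !is.finite(cp$extent_frac)) Inf
               else cp$extent_frac * diag_len
        list(point = pt, normal = n, thickness_vox = cp$thickness_vox,
             extent_vox = ext, aperture_amp = amp,
             aperture_wavelength_vox = wl,
             phase = stats::runif(2, 0, 2 * pi))
      })
    })
  }

  z <- 0:(dims[1] - 1); y <- 0:(dims[2] - 1); x <- 0:(dims[3] - 1)
  axis_outer <- function(az, ay, ax)
    outer(outer(az, ay, `+`), ax, `+`)
  mask <- array(FALSE, dim = dims)
  for (pl in planes) {
    nrm <- pl$normal / sqrt(sum(pl$normal^2))
    s <- axis_outer((z - pl$point[1]) * nrm[1], (y - pl$point[2]) * nrm[2],
                    (x - pl$point[3]) * nrm[3]) # signed distance to plane
    aperture <- pl$thickness_vox
    amp <- pl$aperture_amp
    if (!is.null(amp) && amp > 0) {
      # orthonormal in-plane basis (u, v)
      ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * nrm) * nrm; u <- u / sqrt(sum(u^2))
      v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
             nrm[1] * u[2] - nrm[2] * u[1])
      su <- axis_outer((z - pl$point[1]) * u[1], (y - pl$point[2]) * u[2],
                       (x - pl$point[3]) * u[3])
      sv <- axis_outer((z - pl$point[1]) * v[1], (y - pl$point[2]) * v[2],
                       (x - pl$point[3]) * v[3])
      k <- 2 * pi / pl$aperture_wavelength_vox
      aperture <- pl$thickness_vox *
        (1 + amp * cos(k * su + pl$phase[1]) * cos(k * sv + pl$phase[2]))
    }
    inslab <- abs(s) <= aperture / 2
    if (is.finite(pl$extent_vox)) {
      r2 <- axis_outer((z - pl$point[1])^2, (y - pl$point[2])^2,
                       (x - pl$point[3])^2)
      inslab <- inslab & (r2 - s^2 <= pl$extent_vox^2)
    }
    mask <- mask | inslab
  }
  log_df <- do.call(rbind, lapply(seq_along(planes), function(i) {
    pl <- planes[[i]]
    data.frame(plane = i, pz = pl$point[1], py = pl$point[2],
               px = pl$point[3], nz = pl$normal[1], ny = pl$normal[2],
               nx = pl$normal[3], thickness_vox = pl$thickness_vox,
               extent_vox = pl$extent_vox,
               aperture_amp = if (is.null(pl$aperture_amp)) 0
                              else pl$aperture_amp,
               aperture_wavelength_vox =
                 if (is.null(pl$aperture_wavelength_vox)) NA_real_
                 else pl$aperture_wavelength_vox,
               phase_u = if (is.null(pl$phase)) NA_real_ else pl$phase[1],
               phase_v = if (is.null(pl$phase)) NA_real_ else pl$phase[2])
  }))
  .phantom_truth(spec, mask, log_df)
}

#' Generate a sintered (percolating irregular void) phantom
#'
#' Thresholds a smoothed seeded random field at the quantile that yields the
#' target void fraction. Two field constructions are available. The default
#' `"channel"` field is the pointwise maximum of the normalised absolute
#' values of two independent Gaussian-smoothed white-noise fields; its low
#' values trace the intersection curves of the two nodal surfaces, so the
#' void is a volume-spanning network of irregular tubes that bulge and
#' pinch — the long continuous voids formed by oil displacement in
#' sintering crystal networks. The `"excursion"` field is a single smoothed
#' field (low excursions = blobs), which at low void fractions yields
#' mostly disconnected blobs. Quantile thresholding hits the target
#' fraction up to ties; for `"channel"` the satellite components are
#' dropped by default (`largest_component_only`), which removes about 1-2%
#' of the void volume.
#'
#' @param spec a [phantom_spec()] with `morphology = "sintered"` and a
#'   `target_void_fraction`.
#' @return A phantom-truth list (see [gen_bubbles()]); `feature_log` records
#'   the field type, smoothing length and realized threshold.
#' @export
gen_sintered <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$morphology == "sintered")
  v <- spec$target_void_fraction
  if (is.null(v)) stop("sintered morphology requires target_void_fraction")
  bp <- spec$blob_params
  cl <- bp$corr_length_vox
  if (is.null(cl) || cl < 0) stop("blob_params$corr_length_vox required")
  field_kind <- if (is.null(bp$field)) "channel" else
    match.arg(bp$field, c("channel", "excursion"))
  keep_largest <- if (is.null(bp$largest_component_only))
    field_kind == "channel" else isTRUE(bp$largest_component_only)
  dims <- spec$dims
  field <- .with_seed(spec$seed, {
    if (field_kind == "channel") {
      g1 <- cpp_gaussian_blur(stats::rnorm(prod(dims)), dims, cl)
      g2 <- cpp_gaussian_blur(stats::rnorm(prod(dims)), dims, cl)
      pmax(abs(g1) / stats::sd(g1), abs(g2) / stats::sd(g2))
    } else {
      cpp_gaussian_blur(stats::rnorm(prod(dims)), dims, cl)
    }
  })
  thr <- stats::quantile(field, v, names = FALSE)
  mask <- array(field <= thr, dim = dims)
  if (keep_largest) {
    lab <- array(cpp_label_components(mask, dims, 26L), dim = dims)
    if (max(lab) > 0) {
      counts <- tabulate(lab[lab > 0])
      mask <- lab == which.max(counts)
    }
  }
  .phantom_truth(spec, mask,
                 data.frame(field = field_kind, corr_length_vox = cl,
                            threshold = thr,
                            largest_component_only = keep_largest))
}

#' Generate a phantom from a spec (dispatch on morphology)
#'
#' @param spec a [phantom_spec()].
#' @return A phantom-truth list.
#' @export
gen_phantom <- function(spec) {
  switch(spec$morphology,
         bubbles = gen_bubbles(spec),
         cracks = gen_cracks(spec),
         sintered = gen_sintered(spec))
}

#' Render a phantom to a noisy grayscale volume
#'
#' Assigns one mode intensity per phase, applies an isotropic Gaussian blur
#' (partial-volume mixing at the interface), adds seeded Gaussian noise, and
#' clips to the 8-bit range. The histogram is bimodal when
#' `|solid_mode - void_mode| >= 4 * noise_sd`.
#'
#' @param truth output of one of the generators.
#' @param solid_mode,void_mode mode intensities in `[0, 255]`; must differ.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param blur_sigma_vox Gaussian blur sigma in voxels (>= 0).
#' @param seed noise seed.
#' @return A [grayscale_volume()] with integer 8-bit intensities.
#' @export
render_grayscale <- function(truth, solid_mode = 180, void_mode = 60,
                             noise_sd = 10, blur_sigma_vox = 1, seed = 1L) {
  if (solid_mode == void_mode) stop("solid_mode and void_mode must differ")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (blur_sigma_vox < 0) stop("blur_sigma_vox must be >= 0")
  mask <- truth$binary$mask
  dims <- dim(mask)
  img <- ifelse(mask, void_mode, solid_mode)
  img <- cpp_gaussian_blur(as.double(img), dims, blur_sigma_vox)
  if (noise_sd > 0)
    img <- img + .with_seed(seed, stats::rnorm(length(img), 0, noise_sd))
  img <- pmin(pmax(round(img), 0), 255)
  arr <- array(as.integer(img), dim = dims)
  grayscale_volume(arr, truth$binary$voxel_size_um,
                   provenance = paste0("render:", truth$binary$provenance))
}
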