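#' Void fraction of a binary mask
#'
#' Void voxels divided by total voxels of the sample volume.
#'
#' @param binary a [binary_volume()].
#' @return Scalar in `[0, 1]`.
#' @export
void_fraction <- function(binary) {
  stopifnot(inherits(binary, "binary_volume"))
  mean(binary$mask)
}

#' Connectivity (mean pore coordination number)
#'
#' The coordination number of a pore is the number of throats stemming from
#' it; connectivity `z` is its mean over all pores, which by the degree
#' identity equals `2 * #throats / #pores`.
#'
#' @param network a `pore_network`.
#' @return Scalar `z >= 0`.
#' @export
connectivity <- function(network) {
  stopifnot(inherits(network, "pore_network"))
  if (nrow(network$pores) == 0)
    stop("connectivity is undefined for an empty network")
  mean(network$pores$coordination)
}

#' Coordination-number distribution
#'
#' Relative frequency of each observed coordination value.
#'
#' @param network a `pore_network`.
#' @return Named numeric vector (names = coordination values) summing to 1.
#' @export
coordination_distribution <- function(network) {
  stopifnot(inherits(network, "pore_network"))
  if (nrow(network$pores) == 0)
    stop("coordination distribution is undefined for an empty network")
  tab <- table(network$pores$coordination)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Volume-weighted mean radius (R43)
#'
#' `sum(volume * radius) / sum(volume)`; with spherical features whose
#' volume scales as `r^3` this is `sum(r^4) / sum(r^3)`, the De
#' Brouckere-type D[4,3] mean that the R43 notation denotes.
#'
#' @param features data frame (or list) with `radius_um` and `volume_um3`.
#' @return Scalar, micrometres.
#' @export
r43 <- function(features) {
  r <- features$radius_um; v <- features$volume_um3
  if (length(r) == 0) stop("r43 is undefined for an empty feature set")
  if (any(v <= 0)) stop("feature volumes must be positive")
  sum(v * r) / sum(v)
}

#' Volume-weighted binned radius distribution
#'
#' Each feature contributes its volume to the bin whose centre (a multiple
#' of `bin_width_um`, tick-centred at 0) is nearest its radius; half-way
#' ties go to the higher bin. Masses are normalised to sum to 1.
#'
#' @param features data frame with `radius_um` and `volume_um3`.
#' @param bin_width_um bin width and tick spacing (default 5).
#' @return Named numeric vector; names are bin centres in micrometres.
#' @export
weighted_radius_distribution <- function(features, bin_width_um = 5) {
  r <- features$radius_um; v <- features$volume_um3
  if (length(r) == 0) stop("empty feature set")
  centre <- floor(r / bin_width_um + 0.5) * bin_width_um # ties round up
  mass <- tapply(v, centre, sum)
  out <- as.numeric(mass) / sum(mass)
  names(out) <- names(mass)
  out
}

#' Micropore fraction
#'
#' Fraction of features classified as micropores, radius >= 10 micrometres
#' (boundary inclusive; note this size convention for lipid voids is
#' inverted relative to IUPAC usage). By feature count by default; set
#' `by = "volume"` for the volume-weighted variant.
#'
#' @param features data frame with `radius_um` (and `volume_um3` when
#'   `by = "volume"`).
#' @param threshold_um classification boundary (default 10).
#' @param by `"count"` or `"volume"`.
#' @return Scalar fraction in `[0, 1]`.
#' @export
classify_micropores <- function(features, threshold_um = 10,
                                by = c("count", "volume")) {
  by <- match.arg(by)
  r <- features$radius_um
  if (length(r) == 0) stop("empty feature set")
  is_micro <- r >= threshold_um
  if (by == "count") mean(is_micro)
  else sum(features$volume_um3[is_micro]) / sum(features$volume_um3)
}

#' Average replicate distributions
#'
#' Per-bin arithmetic mean of relative frequencies over replicates; bins
#' absent from a replicate contribute 0 there. The result sums to 1 again.
#'
#' @param distributions list of named numeric vectors (names = bin labels,
#'   e.g. bin centres or coordination values) as produced by
#'   [weighted_radius_distribution()] or [coordination_distribution()].
#' @return Named numeric vector over the union of bins.
#' @export
average_replicate_distributions <- function(distributions) {
  if (length(distributions) == 0) stop("no distributions supplied")
  labs <- unique(unlist(lapply(distributions, names)))
  num <- suppressWarnings(as.numeric(labs))
  if (anyNA(num)) stop("distributions must share a numeric bin labelling")
  labs <- labs[order(num)]
  m <- vapply(distributions, function(d) {
    out <- stats::setNames(numeric(length(labs)), labs)
    out[names(d)] <- d
    out
  }, numeric(length(labs)))
  rowMeans(matrix(m, nrow = length(labs), dimnames = list(labs, NULL)))
}

#' Replicate mean and sample standard deviation
#'
#' The replicate-averaging convention used for reported tables: each
#' replicate contributes one scalar (e.g. its own distribution mean), and
#' the reported value is the unweighted mean of replicates with the n-1
#' sample standard deviation as the error.
#'
#' @param values numeric vector of per-replicate scalars.
#' @return List with `mean`, `sd` (`NA` with a flag when n < 2), `n`.
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0) stop("no replicate values supplied")
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values),
       sd_defined = length(values) >= 2)
}

#' All void metrics for one replicate
#'
#' Bundles the per-replicate descriptors: void fraction `v`, connectivity
#' `z`, volume-weighted mean pore and throat radii (R43), coordination and
#' 5-um-binned volume-weighted radius distributions, and the micropore
#' fraction of the pores. Pore weights are assigned-voxel volumes; throat
#' weights use the cylinder model (see [build_network()]).
#'
#' @param network a `pore_network`.
#' @param binary the [binary_volume()] the network was extracted from.
#' @param bin_width_um radius-distribution bin width (default 5).
#' @return A `void_metrics` list.
#' @export
void_metrics <- function(network, binary, bin_width_um = 5) {
  stopifnot(inherits(network, "pore_network"),
            inherits(binary, "binary_volume"))
  has_pores <- nrow(network$pores) > 0
  has_throats <- nrow(network$throats) > 0
  structure(list(
    v = void_fraction(binary),
    z = if (has_pores) connectivity(network) else NA_real_,
    r43_pore_um = if (has_pores) r43(network$pores) else NA_real_,
    r43_throat_um = if (has_throats) r43(network$throats) else NA_real_,
    coord_distribution = if (has_pores) coordination_distribution(network)
                         else NULL,
    pore_radius_distribution =
      if (has_pores) weighted_radius_distribution(network$pores,
                                                  bin_width_um) else NULL,
    throat_radius_distribution =
      if (has_throats) weighted_radius_distribution(network$throats,
                                                    bin_width_um) else NULL,
    micropore_fraction = if (has_pores) classify_micropores(network$pores)
                         else NA_real_,
    pore_count = nrow(network$pores),
    throat_count = nrow(network$throats),
    bin_width_um = bin_width_um
  ), class = "void_metrics")
}

#' @export
print.void_metrics <- function(x, ...) {
  cat(sprintf(paste0("<void_metrics> v=%.4f z=%.3f R43p=%.2f um ",
                     "R43t=%.2f um micropores=%.3f (%d pores, %d throats)\n"),
              x$v, x$z, x$r43_pore_um, x$r43_throat_um,
              x$micropore_fraction, x$pore_count, x$throat_count))
  invisible(x)
}
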