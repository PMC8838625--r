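#' Histogram-valley threshold segmentation
#'
#' Binarizes a grayscale volume into void vs. solid/liquid by locating the
#' minimum of the (smoothed) intensity histogram between the two phase
#' modes. The histogram uses 1-intensity-unit bins for integer volumes and
#' 256 equal bins otherwise, is smoothed with a symmetric triangular kernel,
#' and the two highest-prominence local maxima are taken as the phase modes.
#' The threshold is the argmin of the smoothed counts strictly between the
#' modes; a tied minimal plateau resolves to its midpoint. In CT of lipids
#' air attenuates less than fat, so the void is dark by default.
#'
#' @param volume a [grayscale_volume()].
#' @param smoothing_bandwidth triangular-kernel half-width in bins
#'   (default 5).
#' @param void_is `"dark"` (void = intensities <= threshold) or `"bright"`.
#' @return A `segmentation_result`: `binary` ([binary_volume()]),
#'   `threshold`, `method`, `histogram` (mids, counts, smoothed) and
#'   `diagnostics` (peak locations and prominences, valley depth).
#' @export
histogram_valley_threshold <- function(volume, smoothing_bandwidth = 5,
                                       void_is = c("dark", "bright")) {
  void_is <- match.arg(void_is)
  h <- .intensity_histogram(volume)
  sm <- .triangular_smooth(h$counts, smoothing_bandwidth)
  pk <- .two_modes(sm, floor_frac = 0.001 * sum(h$counts))
  if (is.null(pk))
    stop("no valley: smoothed histogram is unimodal; ",
         "consider consensus_threshold()")
  thr <- .valley_between(sm, h$mids, pk)
  .make_segmentation(volume, thr$threshold, "valley", h, sm, pk, thr$depth,
                     void_is)
}

#' Consensus threshold segmentation
#'
#' For low-contrast volumes where the inter-mode valley is shallow or
#' undefined: combines the valley threshold (when defined) with the
#' between-class-variance-maximizing (Otsu) threshold by arithmetic mean;
#' falls back to whichever exists. This is the fallback the workflow applies
#' to low-contrast laminar-shear trilaurin-like volumes; the `method` field
#' flags its use.
#'
#' @inheritParams histogram_valley_threshold
#' @return A `segmentation_result` with `method = "consensus"`.
#' @export
consensus_threshold <- function(volume, smoothing_bandwidth = 5,
                                void_is = c("dark", "bright")) {
  void_is <- match.arg(void_is)
  h <- .intensity_histogram(volume)
  sm <- .triangular_smooth(h$counts, smoothing_bandwidth)
  pk <- .two_modes(sm, floor_frac = 0.001 * sum(h$counts))
  valley <- if (!is.null(pk)) .valley_between(sm, h$mids, pk) else NULL
  otsu <- .otsu_threshold(h)
  if (is.null(valley) && is.null(otsu))
    stop("constant volume: no threshold estimator is defined")
  thr <- if (!is.null(valley) && !is.null(otsu))
    (valley$threshold + otsu) / 2
  else if (!is.null(valley)) valley$threshold else otsu
  .make_segmentation(volume, thr, "consensus", h, sm, pk,
                     if (is.null(valley)) NA_real_ else valley$depth,
                     void_is)
}

.make_segmentation <- function(volume, thr, method, h, sm, pk, depth,
                               void_is) {
  mask <- if (void_is == "dark") volume$data <= thr else volume$data >= thr
  mask <- array(mask, dim = volume$dims)
  structure(list(
    binary = binary_volume(mask, volume$voxel_size_um,
                           provenance = paste0("segment:", method)),
    threshold = thr,
    method = method,
    void_is = void_is,
    histogram = list(mids = h$mids, counts = h$counts, smoothed = sm),
    diagnostics = list(
      peaks = if (is.null(pk)) numeric(0) else h$mids[pk$idx],
      prominences = if (is.null(pk)) numeric(0) else pk$prominence,
      valley_depth = depth)
  ), class = "segmentation_result")
}

.intensity_histogram <- function(volume) {
  x <- volume$data
  if (is.integer(x) || all(x == round(x))) {
    rng <- range(x)
    mids <- rng[1]:rng[2]
    counts <- tabulate(as.integer(x) - rng[1] + 1L, nbins = length(mids))
  } else {
    br <- seq(min(x), max(x), length.out = 257)
    if (br[1] == br[257]) { # constant real volume
      mids <- br[1]; counts <- length(x)
    } else {
      hh <- graphics::hist(as.vector(x), breaks = br, plot = FALSE)
      mids <- hh$mids; counts <- hh$counts
    }
  }
  list(mids = mids, counts = counts)
}

# symmetric triangular kernel, half-width bw bins, renormalised at edges
.triangular_smooth <- function(counts, bw) {
  n <- length(counts)
  if (bw <= 0 || n == 1) return(as.double(counts))
  w <- (bw + 1) - abs(-bw:bw)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - bw):min(n, i + bw)
    wij <- w[j - i + bw + 1]
    out[i] <- sum(counts[j] * wij) / sum(wij)
  }
  out
}

# local maxima (histogram ends included) with topographic prominence;
# returns the two most prominent (NULL if fewer than two clear the floor)
.two_modes <- function(sm, floor_frac) {
  n <- length(sm)
  if (n < 2) return(NULL)
  pad <- c(-Inf, sm, -Inf)
  is_peak <- logical(n)
  i <- 2L
  while (i <= n + 1L) {
    if (pad[i] > pad[i - 1]) {
      j <- i
      while (pad[j + 1] == pad[j]) j <- j + 1L
      if (pad[j + 1] < pad[j]) is_peak[((i + j) %/% 2L) - 1L] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  idx <- which(is_peak)
  if (length(idx) < 2) return(NULL)
  prom <- vapply(idx, function(p) {
    walk <- function(step) {
      k <- p; mn <- sm[p]; higher <- FALSE
      while (k + step >= 1 && k + step <= n) {
        k <- k + step
        if (sm[k] > sm[p]) { higher <- TRUE; break }
        mn <- min(mn, sm[k])
      }
      c(mn, higher)
    }
    l <- walk(-1L); r <- walk(1L)
    bases <- c(if (l[2] == 1) l[1], if (r[2] == 1) r[1])
    if (length(bases)) sm[p] - max(bases) else sm[p] - min(l[1], r[1])
  }, numeric(1))
  ok <- prom >= floor_frac
  idx <- idx[ok]; prom <- prom[ok]
  if (length(idx) < 2) return(NULL)
  top <- order(-prom, idx)[1:2]
  sel <- sort(idx[top])
  list(idx = sel, prominence = prom[top][order(idx[top])])
}

.valley_between <- function(sm, mids, pk) {
  lo <- pk$idx[1]; hi <- pk$idx[2]
  if (hi - lo < 2) return(list(threshold = (mids[lo] + mids[hi]) / 2,
                               depth = 0))
  inner <- (lo + 1):(hi - 1)
  vmin <- min(sm[inner])
  at <- inner[sm[inner] == vmin]
  # minimal plateau: midpoint of the contiguous run containing the argmin
  runs <- split(at, cumsum(c(1, diff(at) != 1)))
  first <- runs[[1]]
  thr <- (mids[min(first)] + mids[max(first)]) / 2
  list(threshold = thr, depth = min(sm[lo], sm[hi]) - vmin)
}

# between-class-variance-maximizing threshold on the histogram
.otsu_threshold <- function(h) {
  counts <- as.double(h$counts); mids <- h$mids
  n <- sum(counts)
  if (length(mids) < 2 || sum(counts > 0) < 2) return(NULL)
  w1 <- cumsum(counts)
  mu1 <- cumsum(counts * mids)
  muT <- mu1[length(mu1)]
  k <- seq_len(length(mids) - 1) # threshold between bin k and k+1
  w1k <- w1[k]; w2k <- n - w1k
  valid <- w1k > 0 & w2k > 0
  bcv <- rep(-Inf, length(k))
  bcv[valid] <- (muT * w1k[valid] / n - mu1[k][valid])^2 /
    (w1k[valid] / n * w2k[valid] / n)
  best <- which(bcv == max(bcv))
  # tie: midpoint of the tied range, consistent with the valley rule
  kk <- c(min(best), max(best))
  mean((mids[kk] + mids[kk + 1]) / 2)
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method=%s threshold=%.3f void=%s\n",
              x$method, x$threshold, x$void_is))
  cat(sprintf("  void fraction %.4g; modes at %s\n", mean(x$binary$mask),
              paste(signif(x$diagnostics$peaks, 5), collapse = ", ")))
  invisible(x)
}
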