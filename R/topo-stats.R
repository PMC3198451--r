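#' Global field power of a scalp map
#'
#' Root-mean-square of an (average-referenced) map's values over
#' electrodes.
#'
#' @param map numeric vector of voltages over the montage.
#' @return non-negative scalar.
#' @export
gfp <- function(map) {
  sqrt(mean(map^2))
}

#' Normalize a scalp map (Lehmann convention)
#'
#' Subtracts the spatial mean (average reference) and divides by the
#' global field power, so the result has zero mean and GFP 1. A map with
#' GFP at or below `tol` after centering signals a flat or absent
#' component and is an error.
#'
#' @param map numeric vector over electrodes.
#' @param tol degenerate-map tolerance on the GFP.
#' @return normalized map (same names).
#' @export
normalizeMap <- function(map, tol = 1e-12) {
  v <- map - mean(map)
  g <- gfp(v)
  if (!is.finite(g) || g <= tol)
    stop("degenerate (flat) scalp map: GFP <= tolerance")
  v / g
}

#' Global map dissimilarity of two scalp maps
#'
#' Square root of the mean squared difference between the two normalized
#' maps: 0 for topographic homogeneity (equal maps up to positive
#' scaling), 2 for topographic inversion, and sqrt(2) for spatially
#' uncorrelated maps (GMD^2 = 2 (1 - spatial correlation)).
#'
#' @param a,b numeric maps over the same montage.
#' @return scalar in `[0, 2]`.
#' @examples
#' m <- rnorm(80)
#' gmd(m, 2 * m)   # 0
#' gmd(m, -m)      # 2
#' @export
gmd <- function(a, b) {
  if (length(a) != length(b))
    stop("maps are on different montages")
  sqrt(mean((normalizeMap(a) - normalizeMap(b))^2))
}

#' Extract a scalp map from an ERP at a latency or window
#'
#' @param erp an [ErpAverage-class].
#' @param at latency in ms (nearest sample is used), ignored when `window`
#'   is given.
#' @param window optional ms interval to average over instead of a single
#'   latency.
#' @return named numeric vector over electrodes.
#' @export
scalpMapAt <- function(erp, at = NULL, window = NULL) {
  stopifnot(is(erp, "ErpAverage"))
  if (!is.null(window)) {
    idx <- which(erp@times >= window[1] & erp@times <= window[2])
    if (length(idx) == 0L) stop("window outside the epoch")
    v <- rowMeans(erp@data[, idx, drop = FALSE])
  } else {
    stopifnot(!is.null(at))
    j <- which.min(abs(erp@times - at))
    v <- erp@data[, j]
  }
  names(v) <- erp@channels
  v
}

# Row-wise map normalization for the vectorized permutation null. A flat
# permuted grand average (possible for adversarial inputs, e.g. exact
# mirror pairs shared by all subjects) has no topography; it enters the
# null as the zero map, keeping the GMD bound at 2.
normalizeRows <- function(M, tol = 1e-12) {
  M <- M - rowMeans(M)
  g <- sqrt(rowMeans(M^2))
  flat <- g <= tol
  g[flat] <- 1
  M <- M / g
  M[flat, ] <- 0
  M
}

#' Within-subject GMD permutation (TANOVA) test
#'
#' Tests whether two paired sets of single-subject scalp maps differ in
#' topography. The observed statistic is the GMD between the two
#' grand-average maps (each normalized after averaging). Under the null
#' each subject's A/B assignment is exchangeable: every permutation flips
#' each subject's pair independently, the grand averages are recomputed
#' and their GMD enters the null distribution. When the full flip space is
#' no larger than `nPerm` (`2^n <= nPerm`) it is enumerated exactly and
#' the p value is the exact proportion of null GMDs at or above the
#' observed one (the identity permutation guarantees p > 0); otherwise
#' `nPerm` random flip patterns are sampled and the add-one estimate
#' `(1 + #(null >= obs)) / (1 + nPerm)` is reported. The test is
#' one-sided: GMD is a distance.
#'
#' @param mapsA,mapsB numeric `subjects x electrodes` matrices of paired
#'   single-subject maps.
#' @param nPerm number of permutations (full-scale profile: 100000).
#' @param seed RNG seed for the sampled case.
#' @return a [PermutationResult-class].
#' @export
gmdPermutationTest <- function(mapsA, mapsB, nPerm = 10000L, seed = 1L) {
  mapsA <- as.matrix(mapsA); mapsB <- as.matrix(mapsB)
  if (!all(dim(mapsA) == dim(mapsB)))
    stop("paired map sets must have identical dimensions")
  n <- nrow(mapsA)
  if (n < 2L) stop("need at least 2 subjects")
  stopifnot(nPerm >= 1)

  gA <- colMeans(mapsA); gB <- colMeans(mapsB)
  observed <- gmd(gA, gB)
  D <- mapsA - mapsB

  exact <- 2^n <= nPerm
  if (exact) {
    nEff <- as.integer(2^n)
    flips <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  } else {
    nEff <- as.integer(nPerm)
    set.seed(seed)
    flips <- matrix(rbinom(nEff * n, 1L, 0.5), nEff, n)
  }
  delta <- (flips %*% D) / n
  nullA <- normalizeRows(sweep(delta, 2L, gA, FUN = function(a, b) b - a))
  nullB <- normalizeRows(sweep(delta, 2L, gB, "+"))
  nullGmd <- sqrt(rowMeans((nullA - nullB)^2))

  p <- if (exact) mean(nullGmd >= observed - 1e-12)
       else (1 + sum(nullGmd >= observed - 1e-12)) / (1 + nEff)
  new("PermutationResult", observedGmd = observed, pValue = p,
      nPermutations = nEff,
      seed = if (exact) NA_real_ else as.numeric(seed),
      nullQuantiles = quantile(nullGmd, c(0.5, 0.9, 0.95, 0.99)),
      exact = exact)
}
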