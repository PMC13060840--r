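#' Pair distance distribution curve
#'
#' Binned electron-weighted distribution of interatomic distances. Bin
#' centers sit at (k + 1/2) * dr for k = 0, 1, ... The q-independent
#' self-scattering term (sum of Z_i^2) is carried separately from the
#' cross-pair histogram so the real/reciprocal-space relation stays exact.
#'
#' @param r bin centers (Angstrom), uniformly spaced.
#' @param p densities (1/Angstrom when normalized) or raw electron-pair
#'   weights per bin.
#' @param dr bin width (Angstrom).
#' @param dmax maximum pairwise distance (Angstrom).
#' @param normalized logical; TRUE when the cross-pair curve integrates to 1.
#' @param self_term sum over atoms of Z_i^2.
#' @param total_weight total raw cross-pair weight (sum over pairs of
#'   2 Z_i Z_j); recorded so a normalized curve can still be mapped back to
#'   absolute intensity.
#' @return object of class `pr_curve`.
#' @export
pr_curve <- function(r, p, dr, dmax, normalized = FALSE, self_term = 0,
                     total_weight = NA_real_) {
  stopifnot(length(r) == length(p), dr > 0)
  if (any(p < -1e-12)) stop("P(r) densities must be non-negative")
  if (length(r) > 1 && max(abs(diff(r) - dr)) > 1e-8) {
    stop("bin centers must be uniform with spacing dr")
  }
  if (normalized) {
    area <- sum(p) * dr
    if (abs(area - 1) > 1e-9) stop("normalized curve must have unit area, got ", area)
  }
  structure(list(r = r, p = pmax(p, 0), dr = dr, dmax = dmax,
                 normalized = normalized, self_term = self_term,
                 total_weight = total_weight),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve: %d bins, dr = %.3g A, Dmax = %.3g A, %s\n",
              length(x$r), x$dr, x$dmax,
              if (x$normalized) "normalized (unit area)" else "raw weights"))
  invisible(x)
}

pair_table <- function(structure) {
  xyz <- coords_matrix(structure)
  n <- nrow(xyz)
  if (n < 2) stop("degenerate input: structure must have at least 2 atoms")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((xyz[idx[, 1], , drop = FALSE] - xyz[idx[, 2], , drop = FALSE])^2))
  z <- structure$atoms$znum
  list(i = idx[, 1], j = idx[, 2], d = d, w = 2 * z[idx[, 1]] * z[idx[, 2]],
       self = sum(z^2), n = n)
}

#' Pair distance distribution from coordinates
#'
#' Histograms all unordered distinct atom pairs with electron-pair weight
#' 2 Z_i Z_j. A distance falling exactly on a bin boundary is assigned to the
#' upper bin. The self term (sum Z_i^2) is stored on the curve, never mixed
#' into the histogram.
#'
#' @param structure a `saxs_structure` with >= 2 atoms.
#' @param dr bin width in Angstrom.
#' @param normalize scale the cross-pair histogram to unit area.
#' @param n_bins optional fixed bin count (bins beyond Dmax stay zero);
#'   defaults to the smallest count covering Dmax.
#' @return a `pr_curve`.
#' @export
compute_pr <- function(structure, dr = 0.5, normalize = FALSE, n_bins = NULL) {
  stopifnot(dr > 0)
  pt <- pair_table(structure)
  dmax <- max(pt$d)
  k <- floor(pt$d / dr)  # boundary distances go to the upper bin
  nb <- if (is.null(n_bins)) max(k) + 1L else as.integer(n_bins)
  if (nb < max(k) + 1L) stop("n_bins too small to cover Dmax")
  p <- as.numeric(tapply(pt$w, factor(k, levels = 0:(nb - 1L)), sum))
  p[is.na(p)] <- 0
  total <- sum(p)
  if (normalize) p <- p / (total * dr)
  pr_curve(r = (seq_len(nb) - 0.5) * dr, p = p, dr = dr, dmax = dmax,
           normalized = normalize, self_term = pt$self, total_weight = total)
}

# Integrated Gaussian kernel per pair and bin: the mass each pair deposits
# into bin k is the Gaussian CDF difference across the bin edges, so the
# histogram reduces exactly to the hard assignment as bandwidth -> 0.
# Returns h (pairs x bins collapsed) and optionally the d-derivative matrix.
soft_kernel <- function(d, n_bins, dr, bandwidth, deriv = FALSE) {
  edges <- (0:n_bins) * dr
  zmat <- (outer(-d, edges, "+")) / bandwidth          # (e_k - d)/bw
  cdf <- pnorm(zmat)
  k <- cdf[, 2:(n_bins + 1), drop = FALSE] - cdf[, 1:n_bins, drop = FALSE]
  if (!deriv) return(list(k = k))
  pdf <- dnorm(zmat) / bandwidth
  list(k = k,
       dk = pdf[, 1:n_bins, drop = FALSE] - pdf[, 2:(n_bins + 1), drop = FALSE])
}

#' Differentiable (soft-histogram) pair distance distribution
#'
#' Each atom pair deposits a Gaussian kernel of the given bandwidth centered
#' at its distance; the mass falling into each bin is the Gaussian CDF
#' difference across the bin edges, and the histogram is renormalized to
#' unit area. The curve is smooth in the atomic coordinates and converges to
#' [compute_pr()] as the bandwidth shrinks; [pr_soft_vjp()] supplies the
#' exact analytic gradient of any downstream scalar with respect to every
#' coordinate.
#'
#' @inheritParams compute_pr
#' @param bandwidth Gaussian kernel standard deviation in Angstrom
#'   (default `dr`).
#' @return a normalized `pr_curve`.
#' @export
compute_pr_soft <- function(structure, dr = 0.5, bandwidth = dr, n_bins = NULL) {
  if (bandwidth <= 0) stop("invalid parameter: bandwidth must be > 0")
  pt <- pair_table(structure)
  dmax <- max(pt$d)
  nb <- if (is.null(n_bins)) ceiling((dmax + 4 * bandwidth) / dr) + 1L else as.integer(n_bins)
  sk <- soft_kernel(pt$d, nb, dr, bandwidth)
  h <- as.numeric(crossprod(sk$k, pt$w))
  s <- sum(h) * dr
  pr_curve(r = (seq_len(nb) - 0.5) * dr, p = h / s, dr = dr, dmax = dmax,
           normalized = TRUE, self_term = pt$self, total_weight = sum(pt$w))
}

#' Gradient of a scalar through the soft P(r)
#'
#' Given the cotangent dL/dp at every bin of the normalized soft curve,
#' returns the exact gradient dL/dx for every atomic coordinate, propagated
#' through kernel evaluation and renormalization.
#'
#' @param structure the `saxs_structure` passed to [compute_pr_soft()].
#' @param cotangent numeric vector dL/dp, one entry per bin.
#' @inheritParams compute_pr_soft
#' @return numeric matrix (n_atoms x 3) of dL/d(x, y, z).
#' @export
pr_soft_vjp <- function(structure, cotangent, dr = 0.5, bandwidth = dr,
                        n_bins = NULL) {
  if (bandwidth <= 0) stop("invalid parameter: bandwidth must be > 0")
  pt <- pair_table(structure)
  dmax <- max(pt$d)
  nb <- if (is.null(n_bins)) ceiling((dmax + 4 * bandwidth) / dr) + 1L else as.integer(n_bins)
  if (length(cotangent) != nb) stop("cotangent length must equal bin count")
  sk <- soft_kernel(pt$d, nb, dr, bandwidth, deriv = TRUE)
  h <- as.numeric(crossprod(sk$k, pt$w))
  s <- sum(h) * dr
  p <- h / s
  # for normalized p = h / (sum(h) dr):
  # sum_k a_k dp_k/dd = (1/s) sum_k (a_k - dr <a, p>) w dK_k/dd
  a_adj <- cotangent - dr * sum(cotangent * p)
  g_d <- (pt$w / s) * as.numeric(sk$dk %*% a_adj)   # dL/dd per pair
  xyz <- coords_matrix(structure)
  u <- (xyz[pt$i, , drop = FALSE] - xyz[pt$j, , drop = FALSE]) / pt$d
  grad <- matrix(0, nrow(xyz), 3)
  contrib <- u * g_d
  for (axis in 1:3) {
    grad[, axis] <- grad[, axis] +
      as.numeric(tapply(contrib[, axis], factor(pt$i, levels = seq_len(nrow(xyz))), sum,
                        default = 0)) -
      as.numeric(tapply(contrib[, axis], factor(pt$j, levels = seq_len(nrow(xyz))), sum,
                        default = 0))
  }
  grad[is.na(grad)] <- 0
  grad
}

#' Radius of gyration from a P(r) curve
#'
#' The second-moment relation Rg^2 = integral(r^2 P(r)) /
#' (2 integral(P(r))), with the q-independent self term included in the
#' normalizing mass (it sits at r = 0, adding mass but no moment). With the
#' self term the relation is exact for any atom count — two equal atoms at
#' separation d give Rg = d/2 — and reduces to the familiar continuum
#' formula, which omits the diagonal, when the self term is absent. The
#' result is invariant to scaling the whole curve (cross weights and self
#' term together).
#'
#' @param pr a `pr_curve` with positive total mass.
#' @return Rg in Angstrom.
#' @export
rg_from_pr <- function(pr) {
  p <- pr$p
  self_mass <- pr$self_term
  if (pr$normalized) {
    if (is.finite(pr$total_weight) && pr$total_weight > 0) {
      p <- p * pr$dr * pr$total_weight
    } else {
      self_mass <- 0  # unknown absolute scale: continuum approximation
    }
  }
  m0 <- sum(p)
  if (m0 <= 0) stop("degenerate input: P(r) curve has zero mass")
  sqrt(sum(p * pr$r^2) / (2 * (m0 + self_mass)))
}

#' Radius of gyration from coordinates
#'
#' Weighted RMS distance of atoms from their weighted centroid.
#'
#' @param structure a `saxs_structure`.
#' @param weighting `"electron"` (weights Z_i) or `"uniform"`.
#' @return Rg in Angstrom.
#' @export
rg_from_coords <- function(structure, weighting = c("electron", "uniform")) {
  weighting <- match.arg(weighting)
  xyz <- coords_matrix(structure)
  if (nrow(xyz) < 1) stop("empty structure")
  w <- if (weighting == "electron") structure$atoms$znum else rep(1, nrow(xyz))
  ctr <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Resample a P(r) curve onto a new uniform grid
#'
#' Linear interpolation with zero outside the source support; a normalized
#' source is renormalized after interpolation.
#'
#' @param pr a `pr_curve`.
#' @param target_r new bin centers, uniformly spaced.
#' @return a `pr_curve` on the target grid.
#' @export
resample_pr <- function(pr, target_r) {
  if (length(target_r) > 1) {
    steps <- diff(target_r)
    if (max(abs(steps - steps[1])) > 1e-8) {
      stop("invalid parameter: target grid must be uniform")
    }
    dr_new <- steps[1]
  } else {
    dr_new <- pr$dr
  }
  p_new <- approx(pr$r, pr$p, xout = target_r, yleft = 0, yright = 0, rule = 2)$y
  p_new[target_r < min(pr$r) | target_r > max(pr$r)] <- 0
  p_new <- pmax(p_new, 0)
  tw <- pr$total_weight
  if (pr$normalized) {
    area <- sum(p_new) * dr_new
    if (area <= 0) stop("resampling produced an empty curve")
    p_new <- p_new / area
  }
  pr_curve(r = target_r, p = p_new, dr = dr_new, dmax = pr$dmax,
           normalized = pr$normalized, self_term = pr$self_term,
           total_weight = tw)
}
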