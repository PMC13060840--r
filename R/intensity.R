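#' Scattering geometry
#'
#' @param wavelength X-ray wavelength lambda in Angstrom (> 0).
#' @param half_angle half scattering angle theta in radians, in [0, pi/2).
#' @return object of class `scattering_geometry`.
#' @export
scattering_geometry <- function(wavelength, half_angle) {
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop("invalid geometry: wavelength must be > 0")
  }
  if (half_angle < 0 || half_angle >= pi / 2) {
    stop("invalid geometry: half angle must lie in [0, pi/2)")
  }
  structure(list(wavelength = wavelength, half_angle = half_angle),
            class = "scattering_geometry")
}

#' Momentum transfer from scattering geometry
#'
#' q = (4 pi / lambda) sin(theta), where 2 theta is the scattering angle.
#'
#' @param geom a `scattering_geometry`.
#' @return q in 1/Angstrom.
#' @export
q_from_angle <- function(geom) {
  stopifnot(inherits(geom, "scattering_geometry"))
  (4 * pi / geom$wavelength) * sin(geom$half_angle)
}

#' Scattering profile container
#'
#' @param q momentum transfer grid (1/Angstrom), strictly increasing.
#' @param intensity intensities, arbitrary units.
#' @param sigma optional positive point uncertainties.
#' @return object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL) {
  stopifnot(length(q) == length(intensity))
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) stop("sigma length must match q")
    if (any(sigma <= 0)) stop("sigma values must be > 0")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("scattering_profile: %d points, q in [%.4g, %.4g] 1/A%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

# sin(x)/x with the x -> 0 limit taken as 1
sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)

#' Debye scattering intensity from coordinates
#'
#' The orientation-averaged point-atom Debye sum
#' I(q) = sum_i sum_j Z_i Z_j sin(q r_ij) / (q r_ij), including the self
#' terms (i = j), so I(0) = (sum Z_i)^2 exactly.
#'
#' @param structure a `saxs_structure`.
#' @param q_grid non-negative ascending q values (1/Angstrom).
#' @return a `scattering_profile`.
#' @export
debye_intensity <- function(structure, q_grid) {
  if (length(q_grid) == 0) stop("invalid parameter: empty q grid")
  if (any(q_grid < 0) || any(diff(q_grid) <= 0) && length(q_grid) > 1) {
    stop("invalid parameter: q grid must be non-negative and ascending")
  }
  pt <- pair_table(structure)
  # cross pairs carry weight 2 Z_i Z_j; self terms are q-independent
  cross <- as.numeric(sinc(outer(q_grid, pt$d)) %*% pt$w)
  scattering_profile(q = q_grid, intensity = pt$self + cross)
}

#' Scattering intensity from a P(r) curve
#'
#' Inverse of the real-space transform on the binned curve:
#' I(q) = self_term + sum_k w_k sinc(q r_k), where w_k are the raw cross-pair
#' weights. A normalized curve is rescaled through its recorded total weight.
#'
#' @param pr a `pr_curve`.
#' @param q_grid non-negative ascending q values.
#' @param include_self add the q-independent self term.
#' @return a `scattering_profile`.
#' @export
pr_to_intensity <- function(pr, q_grid, include_self = TRUE) {
  if (length(q_grid) == 0) stop("invalid parameter: empty q grid")
  if (pr$normalized) {
    if (!is.finite(pr$total_weight)) {
      stop("missing scale: normalized curve has no recorded total weight")
    }
    w <- pr$p * pr$dr * pr$total_weight
  } else {
    w <- pr$p
  }
  base <- if (include_self) pr$self_term else 0
  intensity <- base + as.numeric(sinc(outer(q_grid, pr$r)) %*% w)
  scattering_profile(q = q_grid, intensity = intensity)
}
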