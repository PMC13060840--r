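# One-letter alphabet used for generated sequences.
.aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build a CA-trace structure from a coordinate matrix
#'
#' Fixtures are CA-only traces with a placeholder electron count of 6 per
#' residue (carbon); every in-scope computation is exercised by such traces.
#'
#' @param coords numeric matrix (n_res x 3), Angstrom.
#' @param sequence one-letter sequence (generated when NULL).
#' @param chain chain identifier.
#' @param model_id model index.
#' @param seed seed for sequence generation when `sequence` is NULL.
#' @return a `saxs_structure`.
#' @export
ca_structure <- function(coords, sequence = NULL, chain = "A", model_id = 1L,
                         seed = 1) {
  n <- nrow(coords)
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- paste(sample(.aa_letters, n, replace = TRUE), collapse = "")
  }
  letters1 <- strsplit(sequence, "")[[1]]
  stopifnot(length(letters1) == n)
  atoms <- data.frame(
    element = rep("C", n), znum = rep(6L, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    chain = rep(chain, n), resno = seq_len(n),
    resid = bio3d::aa123(letters1), elety = rep("CA", n),
    stringsAsFactors = FALSE
  )
  saxs_structure(atoms, model_id = model_id,
                 sequence = setNames(sequence, chain))
}

chain_coords <- function(kind, n_res, noise, seed, globule_radius) {
  set.seed(seed)
  if (kind == "helix") {
    # ideal alpha-like CA helix: rise 1.5 A, 100 deg/turn, radius 2.3 A
    t <- (seq_len(n_res) - 1) * 100 * pi / 180
    xyz <- cbind(2.3 * cos(t), 2.3 * sin(t), (seq_len(n_res) - 1) * 1.5)
  } else if (kind == "extended") {
    # rise 3.5 A along the axis with a lateral zigzag keeping |CA-CA| = 3.8
    amp <- sqrt(3.8^2 - 3.5^2) / 2
    xyz <- cbind((seq_len(n_res) - 1) * 3.5,
                 amp * (-1)^(seq_len(n_res) - 1), rep(0, n_res))
  } else if (kind == "globule") {
    # fixed-step random walk softly confined to a sphere
    r0 <- if (is.null(globule_radius)) 1.8 * n_res^(1 / 3) else globule_radius
    r0 <- max(r0, 4)  # confinement must admit a 3.8 A step from the origin
    xyz <- matrix(0, n_res, 3)
    for (i in 2:n_res) {
      repeat {
        step <- rnorm(3)
        cand <- xyz[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
        if (sqrt(sum(cand^2)) <= r0) break
      }
      xyz[i, ] <- cand
    }
  } else {
    stop("unknown chain kind: ", kind)
  }
  if (noise > 0) xyz <- xyz + matrix(rnorm(3 * n_res, sd = noise), n_res, 3)
  xyz
}

#' Generate a deterministic toy CA chain
#'
#' Kinds: `helix` (rise 1.5 A, 100 degrees per turn, radius 2.3 A),
#' `extended` (rise 3.5 A with a lateral zigzag so consecutive CA stay at
#' 3.8 A) and `globule` (fixed-step random walk confined to a sphere).
#' Optional isotropic Gaussian coordinate noise is applied last.
#'
#' @param kind `"helix"`, `"extended"` or `"globule"`.
#' @param n_res residue count.
#' @param noise coordinate noise standard deviation (Angstrom).
#' @param seed integer seed; output is a pure function of (arguments, seed).
#' @param globule_radius confinement radius for `kind = "globule"`
#'   (default 1.8 n^(1/3)).
#' @return a `saxs_structure` CA trace.
#' @export
make_chain <- function(kind = c("helix", "extended", "globule"), n_res = 64,
                       noise = 0, seed = 1, globule_radius = NULL) {
  kind <- match.arg(kind)
  xyz <- chain_coords(kind, n_res, noise, seed, globule_radius)
  ca_structure(xyz, seed = seed)
}

rotation_about_y <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
}

#' Generate an open/closed hinge conformer pair
#'
#' A rigid two-domain chain sharing one sequence: the first domain is fixed
#' and the second is rotated about a hinge axis at the junction by the stated
#' angle, emulating apo/holo conformer pairs. Pair RMSD grows monotonically
#' with the hinge-angle difference and the open state has the larger Dmax.
#'
#' @param n_res total residue count (split evenly between domains).
#' @param angle_open,angle_closed hinge angles in degrees (0 = straight).
#' @param seed sequence seed.
#' @return list with `open` and `closed` `saxs_structure`s.
#' @export
make_hinge_pair <- function(n_res = 64, angle_open = 0, angle_closed = 90,
                            seed = 1) {
  m <- n_res %/% 2
  base <- chain_coords("extended", n_res, 0, seed, NULL)
  hinge_at <- base[m, ]
  bend <- function(angle_deg) {
    xyz <- base
    rot <- rotation_about_y(angle_deg * pi / 180)
    tailpart <- sweep(xyz[(m + 1):n_res, , drop = FALSE], 2, hinge_at)
    xyz[(m + 1):n_res, ] <- sweep(tailpart %*% t(rot), 2, hinge_at, "+")
    xyz
  }
  set.seed(seed)
  sequence <- paste(sample(.aa_letters, n_res, replace = TRUE), collapse = "")
  list(open = ca_structure(bend(angle_open), sequence = sequence, model_id = 1L),
       closed = ca_structure(bend(angle_closed), sequence = sequence, model_id = 2L))
}

#' Generate a toy multi-model conformer ensemble
#'
#' Emulates a deposited solution-NMR entry: `n_models` perturbed copies of
#' one base conformation with identical sequence and residue numbering.
#'
#' @param n_res residue count.
#' @param n_models number of models (deposited NMR entries typically carry
#'   20-30).
#' @param sigma per-coordinate Gaussian perturbation (Angstrom).
#' @param seed integer seed.
#' @param kind base chain kind.
#' @param id entry identifier.
#' @return a `conformer_ensemble`.
#' @export
make_nmr_ensemble <- function(n_res = 48, n_models = 20, sigma = 1.0, seed = 1,
                              kind = "helix", id = "synthetic_nmr") {
  base <- chain_coords(kind, n_res, 0, seed, NULL)
  set.seed(seed)
  sequence <- paste(sample(.aa_letters, n_res, replace = TRUE), collapse = "")
  models <- lapply(seq_len(n_models), function(m) {
    xyz <- base + matrix(rnorm(3 * n_res, sd = sigma), n_res, 3)
    ca_structure(xyz, sequence = sequence, model_id = m)
  })
  conformer_ensemble(models, id = id)
}

#' Simulate a noisy experimental scattering profile
#'
#' Debye intensities with multiplicative Gaussian noise; the uncertainty
#' column is set to the stated relative level so a correctly specified fit
#' yields chi-squared near 1.
#'
#' @param structure a `saxs_structure`.
#' @param q_grid q values (1/Angstrom).
#' @param relative_noise relative noise standard deviation (e.g. 0.05).
#' @param seed integer seed.
#' @return a `scattering_profile` with `sigma`.
#' @export
make_noisy_profile <- function(structure, q_grid, relative_noise = 0.05,
                               seed = 1) {
  stopifnot(relative_noise >= 0)
  ideal <- debye_intensity(structure, q_grid)
  set.seed(seed)
  noisy <- ideal$intensity * (1 + rnorm(length(q_grid), sd = relative_noise))
  sigma <- if (relative_noise > 0) {
    relative_noise * abs(ideal$intensity)
  } else {
    NULL
  }
  scattering_profile(q = q_grid, intensity = noisy, sigma = sigma)
}
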