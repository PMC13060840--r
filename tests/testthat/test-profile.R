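test_that("q_from_angle evaluates (4 pi / lambda) sin(theta)", {
  expect_equal(q_from_angle(scattering_geometry(1.0, 0)), 0)
  expect_equal(q_from_angle(scattering_geometry(1.0, 30 * pi / 180)), 2 * pi)
  # independent hand evaluation for Cu K-alpha at 5 degrees
  expect_equal(q_from_angle(scattering_geometry(1.54, 5 * pi / 180)),
               4 * pi / 1.54 * sin(5 * pi / 180), tolerance = 1e-12)
  expect_error(scattering_geometry(-1, 0.1), "wavelength")
  expect_error(scattering_geometry(1, pi), "half angle")
})

test_that("compute_pr puts a single pair's mass in the right bin", {
  s <- two_atoms(d = 10)
  pr <- compute_pr(s, dr = 0.5, normalize = TRUE)
  expect_equal(sum(pr$p) * pr$dr, 1, tolerance = 1e-12)
  expect_lte(abs(pr$dmax - 10), 0.5)
  # all mass in the bin containing r = 10 (boundary goes to the upper bin)
  hit <- which(pr$p > 0)
  expect_length(hit, 1)
  expect_lte(abs(pr$r[hit] - 10), 0.25 + 1e-12)
  expect_equal(pr$self_term, 2)
})

test_that("equilateral triangle collapses to one bin", {
  h <- 8 * sqrt(3) / 2
  atoms <- data.frame(element = "H", znum = 1L,
                      x = c(0, 8, 4), y = c(0, 0, h), z = 0,
                      chain = "A", resno = 1:3, resid = "GLY", elety = "CA")
  # dr chosen so the side length falls inside a bin, not on a boundary
  pr <- compute_pr(saxs_structure(atoms), dr = 0.6)
  expect_length(which(pr$p > 0), 1)
  expect_equal(pr$dmax, 8, tolerance = 1e-9)
})

test_that("compute_pr matches a brute-force pair enumeration on a 30-atom fixture", {
  s <- fixture30()
  pr <- compute_pr(s, dr = 0.5)
  expected <- oracle_pr(s, 0.5)
  expect_equal(length(pr$p), length(expected))
  expect_equal(pr$p, expected, tolerance = 1e-12)
  expect_equal(pr$self_term, sum(s$atoms$znum^2))
  lone <- s
  lone$atoms <- lone$atoms[1, , drop = FALSE]
  expect_error(compute_pr(lone), "degenerate")
})

test_that("compute_pr is invariant under rigid transforms and atom reordering", {
  s <- fixture30()
  pr <- compute_pr(s, dr = 0.5)
  s2 <- transform_structure(s, random_rotation(7), c(11, -4, 2.5))
  pr2 <- compute_pr(s2, dr = 0.5)
  expect_equal(pr2$p, pr$p, tolerance = 1e-9)
  # reorder atoms (reverse); histogram must be bit-identical
  s3 <- s
  s3$atoms <- s$atoms[rev(seq_len(nrow(s$atoms))), ]
  pr3 <- compute_pr(s3, dr = 0.5)
  expect_identical(pr3$p, pr$p)
})

test_that("debye_intensity matches the closed two-atom form and the brute-force sum", {
  s <- two_atoms(d = 10)
  iq <- debye_intensity(s, c(0, 0.1))
  expect_equal(iq$intensity[1], 4)
  expect_equal(iq$intensity[2], 2 * (1 + sin(1) / 1), tolerance = 1e-12)

  s30 <- fixture30()
  q <- seq(0, 0.5, length.out = 50)
  iq30 <- debye_intensity(s30, q)
  expected <- oracle_debye(s30, q)
  expect_equal(iq30$intensity, expected, tolerance = 1e-9)
  expect_equal(iq30$intensity[1], sum(s30$atoms$znum)^2)
  expect_error(debye_intensity(s30, numeric(0)), "empty q grid")
})

test_that("pr_to_intensity agrees with the Debye sum", {
  # pair distance on a bin center: agreement is exact
  s <- two_atoms(d = 10.25)
  q <- seq(0, 0.5, length.out = 21)
  direct <- debye_intensity(s, q)$intensity
  via_pr <- pr_to_intensity(compute_pr(s, dr = 0.5), q)$intensity
  expect_equal(via_pr, direct, tolerance = 1e-12)

  # binning error < 1% for q <= 0.5 at dr = 0.1, decreasing monotonically in dr
  s30 <- fixture30()
  direct30 <- debye_intensity(s30, q)$intensity
  errs <- sapply(c(1.0, 0.5, 0.1), function(dr) {
    approx_i <- pr_to_intensity(compute_pr(s30, dr = dr), q)$intensity
    max(abs(approx_i - direct30) / direct30)
  })
  expect_lt(errs[3], 0.01)
  expect_true(all(diff(errs) < 0))

  # all-zero curve with a self term gives a flat profile
  flat <- pr_curve(r = c(0.25, 0.75), p = c(0, 0), dr = 0.5, dmax = 0,
                   self_term = 7)
  expect_equal(pr_to_intensity(flat, q)$intensity, rep(7, length(q)))

  # normalized curve without recorded total weight refuses
  anon <- pr_curve(r = c(0.25, 0.75), p = c(2, 0) / (2 * 0.5), dr = 0.5,
                   dmax = 0.3, normalized = TRUE, self_term = 2)
  expect_error(pr_to_intensity(anon, q), "missing scale")
})

test_that("radius of gyration agrees between coordinates and P(r)", {
  s <- two_atoms(d = 12)
  expect_equal(rg_from_coords(s), 6)
  expect_equal(rg_from_pr(compute_pr(s, dr = 0.1)), 6, tolerance = 0.1)

  # scale invariance of the P(r) functional (cross and self scaled together)
  pr <- compute_pr(fixture30(), dr = 0.5)
  scaled <- pr
  scaled$p <- pr$p * 37.5
  scaled$self_term <- pr$self_term * 37.5
  expect_equal(rg_from_pr(scaled), rg_from_pr(pr))

  # rigid-transform invariance and the brute-force formula on 10 atoms
  s10 <- make_chain("globule", n_res = 10, seed = 2)
  xyz <- coords_matrix(s10)
  w <- s10$atoms$znum
  ctr <- colSums(xyz * w) / sum(w)
  hand <- sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
  expect_equal(rg_from_coords(s10), hand, tolerance = 1e-12)
  s10r <- transform_structure(s10, random_rotation(3), c(-2, 9, 4))
  expect_equal(rg_from_coords(s10r), rg_from_coords(s10), tolerance = 1e-9)

  # coordinate-space vs P(r)-space agreement within 2 dr
  s30 <- fixture30()
  expect_lt(abs(rg_from_pr(compute_pr(s30, dr = 0.1)) -
                  rg_from_coords(s30)), 0.2)
  empty <- pr_curve(r = c(0.25), p = c(0), dr = 0.5, dmax = 0)
  expect_error(rg_from_pr(empty), "zero mass")
})

test_that("resample_pr interpolates, conserves area and rejects bad grids", {
  pr <- compute_pr(fixture30(), dr = 0.5, normalize = TRUE)
  same <- resample_pr(pr, pr$r)
  expect_equal(same$p, pr$p, tolerance = 1e-12)
  fine <- resample_pr(pr, seq(0.25, max(pr$r), by = 0.25))
  expect_equal(sum(fine$p) * fine$dr, 1, tolerance = 1e-6)
  # down-sampling by 2 equals an independently coded linear interpolation
  coarse_r <- pr$r[seq(1, length(pr$r), by = 2)]
  coarse <- resample_pr(pr, coarse_r)
  ref <- approx(pr$r, pr$p, xout = coarse_r, yleft = 0, yright = 0)$y
  ref <- ref / (sum(ref) * (coarse_r[2] - coarse_r[1]))
  expect_equal(coarse$p, ref, tolerance = 1e-12)
  expect_error(resample_pr(pr, c(0.1, 0.3, 0.9)), "uniform")
})

test_that("united-atom mode augments heavy atoms with implicit hydrogens", {
  atoms <- data.frame(
    element = c("N", "C", "C", "O", "C"),
    x = c(0, 1.4, 2.4, 3.1, 1.9), y = 0, z = 0,
    chain = "A", resno = 1, resid = "ALA",
    elety = c("N", "CA", "C", "O", "CB")
  )
  s <- saxs_structure(atoms)
  su <- united_atom(s)
  # N +1, CA +1, C +0, O +0, CB +3
  expect_equal(su$atoms$znum - s$atoms$znum, c(1, 1, 0, 0, 3))
  # glycine CA carries two hydrogens, proline N none
  gly <- saxs_structure(data.frame(element = "C", x = 0, y = 0, z = 0,
                                   chain = "A", resno = 1, resid = "GLY",
                                   elety = "CA"))
  expect_equal(united_atom(gly)$atoms$znum, 8)
  pro <- saxs_structure(data.frame(element = "N", x = 0, y = 0, z = 0,
                                   chain = "A", resno = 1, resid = "PRO",
                                   elety = "N"))
  expect_equal(united_atom(pro)$atoms$znum, 7)
})
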