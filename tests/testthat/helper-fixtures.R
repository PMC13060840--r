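# Shared fixtures and independent oracles used across test files.

# A 30-atom compact chain whose pair distances sit away from bin edges at
# dr = 0.5 (checked when the fixture was chosen), so hard/soft histogram
# comparisons are not confounded by boundary mass splitting.
fixture30 <- function() make_chain("globule", n_res = 30, seed = 4)

# Two-atom structure with unit electron counts at a given separation.
two_atoms <- function(d = 10, z = 1L) {
  atoms <- data.frame(
    element = c("H", "H"), znum = c(z, z),
    x = c(0, d), y = c(0, 0), z = c(0, 0),
    chain = "A", resno = 1:2, resid = c("GLY", "GLY"), elety = c("CA", "CA"),
    stringsAsFactors = FALSE
  )
  saxs_structure(atoms)
}

# Brute-force O(n^2) P(r) histogram, written independently of compute_pr.
oracle_pr <- function(structure, dr) {
  xyz <- coords_matrix(structure)
  z <- structure$atoms$znum
  n <- nrow(xyz)
  counts <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      k <- floor(d / dr) + 1
      if (length(counts) < k) counts[(length(counts) + 1):k] <- 0
      counts[k] <- counts[k] + 2 * z[i] * z[j]
    }
  }
  counts
}

# Brute-force double-loop Debye sum including self terms.
oracle_debye <- function(structure, q_grid) {
  xyz <- coords_matrix(structure)
  z <- structure$atoms$znum
  n <- nrow(xyz)
  sapply(q_grid, function(q) {
    tot <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        x <- q * d
        tot <- tot + z[i] * z[j] * (if (x < 1e-12) 1 else sin(x) / x)
      }
    }
    tot
  })
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(m)
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# Minimal mmCIF atom_site writer for cross-format read tests.
write_minimal_cif <- function(structure, path) {
  a <- structure$atoms
  lines <- c(
    "data_fixture",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
            seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
  )
  writeLines(lines, path)
}
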