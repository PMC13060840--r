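#' @importFrom stats approx rnorm runif sd cor setNames dist pnorm dnorm
#' @importFrom utils head tail
NULL

# Atomic numbers for elements commonly seen in protein structure files.
.element_z <- c(
  H = 1, D = 1, C = 6, N = 7, O = 8, F = 9, "NA" = 11, MG = 12, P = 15,
  S = 16, CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28,
  CU = 29, ZN = 30, SE = 34, BR = 35, I = 53
)

#' Electron count for an element symbol
#'
#' Point-scatterer weights are atomic numbers; the table covers the elements
#' routinely present in protein and common-cofactor coordinate files.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return integer vector of electron counts.
#' @export
element_electrons <- function(element) {
  z <- .element_z[toupper(trimws(element))]
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(as.integer(z))
}

# Implicit hydrogen counts per (residue, atom) for the united-atom option.
# Backbone: N carries 1 H (0 in proline), CA carries 1 (2 in glycine).
.implicit_h <- local({
  bb <- function(res, pro = FALSE, gly = FALSE) {
    c(setNames(if (pro) 0L else 1L, paste0(res, ":N")),
      setNames(if (gly) 2L else 1L, paste0(res, ":CA")),
      setNames(0L, paste0(res, ":C")), setNames(0L, paste0(res, ":O")))
  }
  sc <- function(res, ...) {
    v <- c(...)
    setNames(as.integer(v), paste0(res, ":", names(v)))
  }
  c(
    bb("ALA"), sc("ALA", CB = 3),
    bb("ARG"), sc("ARG", CB = 2, CG = 2, CD = 2, NE = 1, CZ = 0, NH1 = 2, NH2 = 2),
    bb("ASN"), sc("ASN", CB = 2, CG = 0, OD1 = 0, ND2 = 2),
    bb("ASP"), sc("ASP", CB = 2, CG = 0, OD1 = 0, OD2 = 0),
    bb("CYS"), sc("CYS", CB = 2, SG = 1),
    bb("GLN"), sc("GLN", CB = 2, CG = 2, CD = 0, OE1 = 0, NE2 = 2),
    bb("GLU"), sc("GLU", CB = 2, CG = 2, CD = 0, OE1 = 0, OE2 = 0),
    bb("GLY", gly = TRUE),
    bb("HIS"), sc("HIS", CB = 2, CG = 0, ND1 = 0, CD2 = 1, CE1 = 1, NE2 = 1),
    bb("ILE"), sc("ILE", CB = 1, CG1 = 2, CG2 = 3, CD1 = 3),
    bb("LEU"), sc("LEU", CB = 2, CG = 1, CD1 = 3, CD2 = 3),
    bb("LYS"), sc("LYS", CB = 2, CG = 2, CD = 2, CE = 2, NZ = 3),
    bb("MET"), sc("MET", CB = 2, CG = 2, SD = 0, CE = 3),
    bb("PHE"), sc("PHE", CB = 2, CG = 0, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, CZ = 1),
    bb("PRO", pro = TRUE), sc("PRO", CB = 2, CG = 2, CD = 2),
    bb("SER"), sc("SER", CB = 2, OG = 1),
    bb("THR"), sc("THR", CB = 1, OG1 = 1, CG2 = 3),
    bb("TRP"), sc("TRP", CB = 2, CG = 0, CD1 = 1, CD2 = 0, NE1 = 1, CE2 = 0,
                  CE3 = 1, CZ2 = 1, CZ3 = 1, CH2 = 1),
    bb("TYR"), sc("TYR", CB = 2, CG = 0, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1,
                  CZ = 0, OH = 1),
    bb("VAL"), sc("VAL", CB = 1, CG1 = 3, CG2 = 3)
  )
})

#' Atomic structure container
#'
#' A light container for a single conformer: one row per atom with element,
#' electron count, Cartesian coordinates in Angstrom, chain id, residue index
#' and residue name, plus the one-letter sequence per chain.
#'
#' @param atoms data.frame with columns `element`, `znum`, `x`, `y`, `z`,
#'   `chain`, `resno`, `resid`. `znum` may be omitted, in which case electron
#'   counts are looked up from the element table. `elety` (atom name, e.g.
#'   "CA") is optional but required for united-atom hydrogen imputation.
#' @param model_id integer model index (1 for single-model files).
#' @param sequence named character vector, one one-letter string per chain;
#'   derived from `atoms` when missing.
#' @return an object of class `saxs_structure`.
#' @export
saxs_structure <- function(atoms, model_id = 1L, sequence = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "x", "y", "z", "chain", "resno", "resid")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$znum)) atoms$znum <- element_electrons(atoms$element)
  if (is.null(atoms$elety)) atoms$elety <- atoms$element
  atoms$resno <- as.integer(atoms$resno)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$znum < 1)) stop("every atom must have electron count >= 1")
  for (ch in unique(atoms$chain)) {
    rr <- atoms$resno[atoms$chain == ch]
    if (any(diff(rr) < 0)) stop("residue indices must be non-decreasing within chain ", ch)
  }
  if (is.null(sequence)) sequence <- derive_sequence(atoms)
  structure(
    list(atoms = atoms, model_id = as.integer(model_id), sequence = sequence),
    class = "saxs_structure"
  )
}

derive_sequence <- function(atoms) {
  chains <- unique(atoms$chain)
  seqs <- vapply(chains, function(ch) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    keep <- !duplicated(a$resno)
    paste(suppressWarnings(bio3d::aa321(a$resid[keep])), collapse = "")
  }, character(1))
  setNames(seqs, chains)
}

#' @export
print.saxs_structure <- function(x, ...) {
  cat(sprintf("saxs_structure: %d atoms, %d residue(s), %d chain(s), model %d\n",
              nrow(x$atoms), sum(!duplicated(x$atoms[, c("chain", "resno")])),
              length(unique(x$atoms$chain)), x$model_id))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `saxs_structure`.
#' @return integer residue count (unique chain/residue pairs with atoms).
#' @export
n_residues <- function(structure) {
  sum(!duplicated(structure$atoms[, c("chain", "resno")]))
}

#' Coordinate matrix of a structure
#' @param structure a `saxs_structure`.
#' @param ca_only keep only CA atoms.
#' @return numeric matrix (n x 3), Angstrom.
#' @export
coords_matrix <- function(structure, ca_only = FALSE) {
  a <- structure$atoms
  if (ca_only) a <- a[a$elety == "CA", , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Add implicit-hydrogen electrons to heavy atoms (united-atom mode)
#'
#' Structure files frequently omit hydrogens; this mode folds each missing
#' hydrogen's electron into its bonded heavy atom using standard per-atom
#' counts for the twenty amino acids. Atoms without a table entry are left
#' unchanged.
#'
#' @param structure a `saxs_structure` with atom names in `elety`.
#' @return the structure with augmented `znum`.
#' @export
united_atom <- function(structure) {
  a <- structure$atoms
  key <- paste0(toupper(a$resid), ":", toupper(a$elety))
  extra <- .implicit_h[key]
  extra[is.na(extra)] <- 0L
  a$znum <- a$znum + as.integer(extra)
  structure$atoms <- a
  structure
}

#' Apply a rigid transform to a structure
#' @param structure a `saxs_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 shift in Angstrom.
#' @return transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords_matrix(structure)
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Conformer ensemble container
#'
#' Bundles the alternative models of one entry (e.g. the deposited models of a
#' solution-NMR structure). All models must share sequence and residue
#' numbering.
#'
#' @param models list of `saxs_structure` objects.
#' @param id entry identifier.
#' @return object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(models, id = "ensemble") {
  stopifnot(length(models) >= 1)
  seqs <- vapply(models, function(m) paste(m$sequence, collapse = "|"), character(1))
  if (length(unique(seqs)) != 1) {
    stop("malformed ensemble: models do not share one sequence")
  }
  structure(list(id = id, sequence = models[[1]]$sequence, models = models),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble '%s': %d model(s), %d residue(s)\n",
              x$id, length(x$models), n_residues(x$models[[1]])))
  invisible(x)
}
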