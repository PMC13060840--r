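# Residue names treated as solvent and dropped at parse time.
.water_names <- c("HOH", "WAT", "DOD", "H2O", "SOL")

# Convert one bio3d atom table (single model) into a saxs_structure,
# applying the parse policy: drop waters, alternate locations beyond 'A',
# and zero-occupancy atoms.
from_bio3d_atoms <- function(atom, model_id = 1L, quiet = TRUE) {
  n0 <- nrow(atom)
  keep <- !(toupper(atom$resid) %in% .water_names)
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  keep <- keep & (alt == "" | alt == "A")
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  keep <- keep & occ > 0
  atom <- atom[keep, , drop = FALSE]
  if (!quiet && nrow(atom) < n0) {
    message(sprintf("dropped %d atom(s) (waters/altloc/zero occupancy)",
                    n0 - nrow(atom)))
  }
  elesy <- trimws(ifelse(is.na(atom$elesy) | atom$elesy == "",
                         substr(trimws(atom$elety), 1, 1), atom$elesy))
  chain <- ifelse(is.na(atom$chain) | atom$chain == "", "A", atom$chain)
  atoms <- data.frame(
    element = elesy,
    znum = element_electrons(elesy),
    x = atom$x, y = atom$y, z = atom$z,
    chain = chain, resno = atom$resno, resid = atom$resid,
    elety = trimws(atom$elety),
    stringsAsFactors = FALSE
  )
  saxs_structure(atoms, model_id = model_id)
}

#' Read a structure file
#'
#' Reads PDB (multi-model aware) and mmCIF files through bio3d. Waters,
#' alternate locations beyond 'A' and zero-occupancy atoms are dropped. A
#' file with several MODEL blocks yields a `conformer_ensemble`; models with
#' inconsistent sequences raise a malformed-ensemble error.
#'
#' @param path file path (.pdb or .cif).
#' @param quiet suppress parse messages.
#' @return a `saxs_structure` or `conformer_ensemble`.
#' @export
read_structure <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    cif <- suppressWarnings(bio3d::read.cif(path))
    return(from_bio3d_atoms(cif$atom, model_id = 1L, quiet = quiet))
  }
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) <= 1) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    return(from_bio3d_atoms(pdb$atom, model_id = 1L, quiet = quiet))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) {
    stop("malformed multi-model file: MODEL/ENDMDL records do not pair up")
  }
  models <- vector("list", length(starts))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (m in seq_along(starts)) {
    block <- lines[(starts[m] + 1):(ends[m] - 1)]
    writeLines(c(block, "END"), tmp)
    pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
    models[[m]] <- from_bio3d_atoms(pdb$atom, model_id = m, quiet = quiet)
  }
  seqs <- vapply(models, function(s) paste(s$sequence, collapse = "|"), character(1))
  if (length(unique(seqs)) != 1) {
    stop("malformed ensemble: models do not share one sequence (model ",
         paste(which(seqs != seqs[1]), collapse = ", "), " differs)")
  }
  conformer_ensemble(models, id = sub("\\.[^.]+$", "", basename(path)))
}

write_single_pdb_lines <- function(s) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  a <- s$atoms
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, eleno = seq_len(nrow(a)),
                   elesy = a$element)
  lines <- readLines(tmp, warn = FALSE)
  lines[!grepl("^END", lines)]
}

#' Write a structure or ensemble as PDB
#'
#' Single structures become plain PDB files; ensembles become multi-model
#' files with MODEL/ENDMDL records in model order.
#'
#' @param x a `saxs_structure`, `conformer_ensemble`, or list of structures.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "saxs_structure")) {
    writeLines(c(write_single_pdb_lines(x), "END"), path)
    return(invisible(path))
  }
  models <- if (inherits(x, "conformer_ensemble")) x$models else x
  out <- character(0)
  for (m in seq_along(models)) {
    out <- c(out, sprintf("MODEL     %4d", m),
             write_single_pdb_lines(models[[m]]), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Write / read a P(r) curve as two-column text
#'
#' Whitespace-separated (r, P) columns preceded by '#' header comments
#' recording bin width, Dmax, normalization state, self term and total
#' cross-pair weight, so a written curve reads back losslessly.
#'
#' @param pr a `pr_curve`.
#' @param path file path.
#' @return `read_pr` returns a `pr_curve`.
#' @export
write_pr <- function(pr, path) {
  header <- c(
    "# pair distance distribution P(r)",
    sprintf("# dr= %.17g", pr$dr),
    sprintf("# dmax= %.17g", pr$dmax),
    sprintf("# normalized= %s", pr$normalized),
    sprintf("# self_term= %.17g", pr$self_term),
    sprintf("# total_weight= %.17g", pr$total_weight)
  )
  body <- sprintf("%.17g %.17g", pr$r, pr$p)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_pr
#' @export
read_pr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  getval <- function(key, default = NA) {
    hit <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, "="), "", hit[1]))
  }
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) != 2)
  if (length(bad)) {
    stop("malformed P(r) line ", which(!startsWith(lines, "#"))[bad[1]],
         " in ", path)
  }
  vals <- matrix(as.numeric(unlist(fields)), ncol = 2, byrow = TRUE)
  if (anyNA(vals)) stop("non-numeric value in P(r) file ", path)
  dr <- as.numeric(getval("dr", diff(vals[1:2, 1])))
  pr_curve(r = vals[, 1], p = vals[, 2], dr = dr,
           dmax = as.numeric(getval("dmax", max(vals[vals[, 2] > 0, 1]))),
           normalized = as.logical(getval("normalized", "FALSE")),
           self_term = as.numeric(getval("self_term", "0")),
           total_weight = as.numeric(getval("total_weight", "NA")))
}

#' Write / read a scattering profile as three-column text
#'
#' ATSAS-style .dat: q, I and sigma columns; the sigma column is blank when
#' uncertainties are absent. Malformed lines raise an error naming the line
#' number.
#'
#' @param profile a `scattering_profile`.
#' @param path file path.
#' @return `read_profile` returns a `scattering_profile`.
#' @export
write_profile <- function(profile, path) {
  header <- "# q intensity sigma"
  body <- if (is.null(profile$sigma)) {
    sprintf("%.17g %.17g", profile$q, profile$intensity)
  } else {
    sprintf("%.17g %.17g %.17g", profile$q, profile$intensity, profile$sigma)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[is_body]), "\\s+")
  nf <- vapply(fields, length, integer(1))
  bad <- which(!(nf %in% c(2L, 3L)))
  if (length(bad)) {
    stop("malformed profile line ", which(is_body)[bad[1]], " in ", path)
  }
  q <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 1)))
  intensity <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  bad_num <- which(is.na(q) | is.na(intensity))
  if (length(bad_num)) {
    stop("malformed profile line ", which(is_body)[bad_num[1]], " in ", path)
  }
  sigma <- if (all(nf == 3L)) {
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
    if (anyNA(s)) {
      stop("malformed profile line ", which(is_body)[which(is.na(s))[1]],
           " in ", path)
    }
    s
  } else {
    NULL
  }
  scattering_profile(q = q, intensity = intensity, sigma = sigma)
}
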