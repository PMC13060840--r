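as_coords <- function(x, ca_only = TRUE) {
  if (inherits(x, "saxs_structure")) {
    m <- coords_matrix(x, ca_only = ca_only)
    if (nrow(m) == 0) m <- coords_matrix(x, ca_only = FALSE)
    m
  } else {
    as.matrix(x)
  }
}

#' Optimal-superposition (Kabsch) RMSD
#'
#' Minimal root-mean-square deviation over all proper rotations and
#' translations, computed by SVD of the cross-covariance with the
#' determinant correction that disallows reflections. Inputs must have equal
#' point counts in matched order; `saxs_structure`s are reduced to CA atoms.
#'
#' @param a,b coordinate matrices (n x 3) or `saxs_structure`s.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as_coords(a)
  b <- as_coords(b)
  if (nrow(a) != nrow(b)) {
    stop("coordinate count mismatch: ", nrow(a), " vs ", nrow(b))
  }
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(max(0, sum((ac - bc %*% rot)^2) / n))
}

#' Accuracy tier of a prediction RMSD
#'
#' High accuracy at RMSD <= 1.0 A, mid accuracy in (1.0, 5.0] A, low
#' accuracy above 5.0 A; the three tiers partition [0, Inf) exactly.
#'
#' @param rmsd non-negative RMSD in Angstrom (vectorized).
#' @return character vector in `c("high", "mid", "low")`.
#' @export
accuracy_tier <- function(rmsd) {
  stopifnot(all(rmsd >= 0))
  ifelse(rmsd <= 1.0, "high", ifelse(rmsd <= 5.0, "mid", "low"))
}

#' Mean pairwise CA-RMSD of an ensemble
#'
#' Average of [kabsch_rmsd()] over all unordered pairs of ensemble members;
#' 0 for a single-member or all-identical ensemble.
#'
#' @param ensemble a `conformer_ensemble`, or a list of structures /
#'   coordinate matrices.
#' @return mean pairwise RMSD in Angstrom.
#' @export
intra_ensemble_rmsd <- function(ensemble) {
  models <- if (inherits(ensemble, "conformer_ensemble")) ensemble$models else ensemble
  m <- length(models)
  if (m < 2) return(0)
  vals <- c()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      vals <- c(vals, kabsch_rmsd(models[[i]], models[[j]]))
    }
  }
  mean(vals)
}

#' Correlation between input-profile divergence and output diversity
#'
#' Pearson product-moment correlation between the L1 distance of input P(r)
#' curves and the structural RMSD of the corresponding outputs.
#'
#' @param l1 numeric vector of input P(r) L1 distances (>= 3 values).
#' @param rmsd numeric vector of output structure RMSDs, same length.
#' @return Pearson r.
#' @export
divergence_diversity_correlation <- function(l1, rmsd) {
  stopifnot(length(l1) == length(rmsd), length(l1) >= 3)
  if (sd(l1) == 0 || sd(rmsd) == 0) {
    stop("correlation undefined: a coordinate has zero variance")
  }
  cor(l1, rmsd, method = "pearson")
}

#' RMSD to the conformation a prediction disfavours
#'
#' Computes CA-RMSD from a prediction to both reference conformers and
#' reports the farther one as the "unfavoured" state. An exact tie resolves
#' deterministically to the first-listed reference and is flagged.
#'
#' @param prediction,apo_ref,holo_ref structures or coordinate matrices.
#' @return list with `unfavoured` ("apo" or "holo"), `rmsd` (to the
#'   unfavoured state), `rmsd_apo`, `rmsd_holo` and `tie`.
#' @export
unfavoured_conformer_rmsd <- function(prediction, apo_ref, holo_ref) {
  r_apo <- kabsch_rmsd(prediction, apo_ref)
  r_holo <- kabsch_rmsd(prediction, holo_ref)
  tie <- isTRUE(all.equal(r_apo, r_holo))
  if (tie || r_apo >= r_holo) {
    list(unfavoured = "apo", rmsd = r_apo, rmsd_apo = r_apo,
         rmsd_holo = r_holo, tie = tie)
  } else {
    list(unfavoured = "holo", rmsd = r_holo, rmsd_apo = r_apo,
         rmsd_holo = r_holo, tie = tie)
  }
}

#' Evaluate a predicted structure or ensemble against references
#'
#' Per-reference CA-RMSD, Rg delta, accuracy tier, and for ensembles the
#' best-of-ensemble RMSD and intra-ensemble diversity.
#'
#' @param prediction a `saxs_structure`, or list of structures (ensemble).
#' @param references named list of reference `saxs_structure`s.
#' @param target_pr optional normalized target `pr_curve`; when given, the
#'   SAXS L1 of the (first) prediction's normalized P(r) is reported.
#' @param dr bin width used for P(r)-based metrics.
#' @return list of class `evaluation_report`.
#' @export
evaluate_structures <- function(prediction, references, target_pr = NULL,
                                dr = 0.5) {
  preds <- if (inherits(prediction, "saxs_structure")) list(prediction) else prediction
  ref_names <- names(references)
  if (is.null(ref_names)) ref_names <- paste0("ref", seq_along(references))
  per_ref <- lapply(seq_along(references), function(i) {
    rmsds <- vapply(preds, function(p) kabsch_rmsd(p, references[[i]]), numeric(1))
    best <- min(rmsds)
    list(reference = ref_names[i], rmsd_first = rmsds[1],
         rmsd_best = best, tier = accuracy_tier(best),
         rg_delta = rg_from_coords(preds[[1]]) - rg_from_coords(references[[i]]))
  })
  names(per_ref) <- ref_names
  saxs_l1_val <- if (!is.null(target_pr)) {
    saxs_l1(compute_pr(preds[[1]], dr = dr, normalize = TRUE), target_pr)
  } else {
    NA_real_
  }
  structure(list(
    per_reference = per_ref,
    saxs_l1 = saxs_l1_val,
    n_predictions = length(preds),
    intra_ensemble_rmsd = if (length(preds) > 1) intra_ensemble_rmsd(preds) else 0
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d prediction(s)\n", x$n_predictions))
  for (r in x$per_reference) {
    cat(sprintf("  vs %s: best RMSD %.3f A (%s tier), Rg delta %+.3f A\n",
                r$reference, r$rmsd_best, r$tier, r$rg_delta))
  }
  if (is.finite(x$saxs_l1)) cat(sprintf("  SAXS L1 vs target: %.4f\n", x$saxs_l1))
  if (x$n_predictions > 1) {
    cat(sprintf("  intra-ensemble mean pairwise RMSD: %.3f A\n",
                x$intra_ensemble_rmsd))
  }
  invisible(x)
}
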