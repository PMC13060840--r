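#' Composite training-loss weights
#'
#' Default weights for the six-term training objective: frame-aligned point
#' error (0.5), auxiliary (0.5), distogram (0.3), masked-MSA (2.0),
#' confidence (0.01) and the SAXS profile term (2.0).
#'
#' @param fape,aux,dist,msa,conf,saxs non-negative weights.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(fape = 0.5, aux = 0.5, dist = 0.3, msa = 2.0,
                         conf = 0.01, saxs = 2.0) {
  w <- c(fape = fape, aux = aux, dist = dist, msa = msa, conf = conf, saxs = saxs)
  if (any(!is.finite(w)) || any(w < 0)) stop("loss weights must be finite and >= 0")
  structure(as.list(w), class = "loss_weights")
}

#' Weighted composite loss
#'
#' Total = w_fape L_fape + w_aux L_aux + w_dist L_dist + w_msa L_msa +
#' w_conf L_conf + w_saxs L_saxs. The five non-SAXS components come from the
#' host prediction network and are consumed here as scalars.
#'
#' @param components named list or vector with entries `fape`, `aux`, `dist`,
#'   `msa`, `conf`, `saxs` — all six required and finite.
#' @param weights a `loss_weights` object.
#' @return list with the component values, the weights and `total`.
#' @export
composite_loss <- function(components, weights = loss_weights()) {
  need <- c("fape", "aux", "dist", "msa", "conf", "saxs")
  components <- as.list(components)
  miss <- setdiff(need, names(components))
  if (length(miss)) {
    stop("missing loss component(s): ", paste(miss, collapse = ", "))
  }
  vals <- vapply(components[need], function(v) as.numeric(v)[1], numeric(1))
  if (any(!is.finite(vals))) stop("loss components must be finite")
  w <- unlist(weights[need])
  total <- sum(w * vals)
  list(components = as.list(vals), weights = weights, total = total)
}

# Resample both normalized curves onto the finer common grid covering the
# union of supports; returns list(r, dr, a, b).
common_grid <- function(pred, target) {
  fine <- if (pred$dr <= target$dr) pred else target
  dr <- fine$dr
  rmax <- max(max(pred$r), max(target$r))
  nb <- ceiling(rmax / dr - 0.5) + 1L
  r <- (seq_len(nb) - 0.5) * dr
  list(r = r, dr = dr,
       a = resample_pr(pred, r)$p,
       b = resample_pr(target, r)$p)
}

#' L1 distance between two normalized P(r) curves
#'
#' sum_k |p_pred,k - p_target,k| * dr on the finer common grid. For
#' unit-area curves the value lies in [0, 2], reaching 2 exactly for curves
#' with disjoint support (total-variation bound).
#'
#' @param pred,target normalized `pr_curve` objects.
#' @return scalar loss.
#' @export
saxs_l1 <- function(pred, target) {
  if (!pred$normalized || !target$normalized) {
    stop("contract violation: saxs_l1 requires normalized curves")
  }
  g <- common_grid(pred, target)
  sum(abs(g$a - g$b)) * g$dr
}

#' Chi-squared fit of a model profile to an experimental profile
#'
#' Finds the linear scale c minimizing the per-point-averaged discrepancy
#' chi^2 = (1/N) sum_k ((I_exp,k - c I_mod,k) / sigma_k)^2 in closed form
#' (c = sum I_exp I_mod / sigma^2  /  sum I_mod^2 / sigma^2), after linear
#' interpolation of the model onto the experimental q grid.
#'
#' @param model a `scattering_profile` (computed profile).
#' @param experiment a `scattering_profile` with positive uncertainties.
#' @return list with `scale` and `chi2`.
#' @export
chi2_fit <- function(model, experiment) {
  if (is.null(experiment$sigma)) {
    stop("experimental profile carries no uncertainties; chi2 is undefined")
  }
  keep <- experiment$q >= min(model$q) & experiment$q <= max(model$q)
  if (sum(keep) < 2) stop("model and experiment q ranges do not overlap")
  qe <- experiment$q[keep]
  ie <- experiment$intensity[keep]
  se <- experiment$sigma[keep]
  im <- approx(model$q, model$intensity, xout = qe)$y
  denom <- sum(im^2 / se^2)
  if (denom <= 0) stop("degenerate fit: model profile is zero on the common grid")
  scale <- sum(ie * im / se^2) / denom
  chi2 <- mean(((ie - scale * im) / se)^2)
  list(scale = scale, chi2 = chi2, n = length(qe))
}
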