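# Soft P(r) L1 loss against a fixed target on a fixed grid, plus a smooth
# consecutive-CA bond penalty, with analytic gradient w.r.t. coordinates.
# Shares one kernel matrix between the forward and backward pass.
soft_l1_grad <- function(xyz, z, target_p, dr, bandwidth, n_bins, chain_weight,
                         bond_length = 3.8) {
  n <- nrow(xyz)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dv <- xyz[idx[, 1], , drop = FALSE] - xyz[idx[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  if (!all(is.finite(d))) {
    return(list(loss = NaN, l1 = NaN, penalty = NaN, p = NULL, grad = NULL))
  }
  w <- 2 * z[idx[, 1]] * z[idx[, 2]]
  np <- length(d)
  # windowed kernel: a pair only touches bins within 8 bandwidths of its
  # distance, so evaluate the CDF differences on a band, not the full grid
  wid <- min(n_bins, ceiling(16 * bandwidth / dr) + 2L)
  k0 <- pmax(0L, pmin(as.integer(floor((d - 8 * bandwidth) / dr)),
                      n_bins - wid))
  zmat <- (k0 * dr + matrix((0:wid) * dr, np, wid + 1L, byrow = TRUE) - d) /
    bandwidth
  cdf <- pnorm(zmat)
  kband <- cdf[, 2:(wid + 1L), drop = FALSE] - cdf[, 1:wid, drop = FALSE]
  bins <- k0 + matrix(seq_len(wid), np, wid, byrow = TRUE)   # 1-based bin ids
  h <- numeric(n_bins)
  acc <- rowsum(as.numeric(kband * w), as.numeric(bins))
  h[as.integer(rownames(acc))] <- acc[, 1]
  s <- sum(h) * dr
  p <- h / s
  l1 <- sum(abs(p - target_p)) * dr
  cot <- sign(p - target_p) * dr
  a_adj <- cot - dr * sum(cot * p)
  pdf <- dnorm(zmat) / bandwidth
  dkband <- pdf[, 1:wid, drop = FALSE] - pdf[, 2:(wid + 1L), drop = FALSE]
  amat <- matrix(a_adj[as.numeric(bins)], np, wid)
  g_d <- (w / s) * rowSums(dkband * amat)
  u <- dv / d
  contrib <- u * g_d
  grad <- matrix(0, n, 3)
  fi <- factor(idx[, 1], levels = seq_len(n))
  fj <- factor(idx[, 2], levels = seq_len(n))
  for (axis in 1:3) {
    grad[, axis] <- as.numeric(tapply(contrib[, axis], fi, sum, default = 0)) -
      as.numeric(tapply(contrib[, axis], fj, sum, default = 0))
  }
  # smooth bond-length penalty over consecutive CA
  penalty <- 0
  if (chain_weight > 0 && n > 1) {
    bd <- xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE]
    bl <- sqrt(rowSums(bd^2))
    penalty <- chain_weight * sum((bl - bond_length)^2)
    gb <- 2 * chain_weight * (bl - bond_length) / bl
    gv <- bd * gb
    grad[-1, ] <- grad[-1, ] + gv
    grad[-n, ] <- grad[-n, ] - gv
  }
  list(loss = l1 + penalty, l1 = l1, penalty = penalty, p = p, grad = grad)
}

#' Surrogate differentiable fold head
#'
#' A small deterministic, differentiable map from a feature vector to CA
#' coordinates: a fixed base conformation plus a fixed linear basis of smooth
#' collective deformation modes (each feature drives a sinusoidal
#' displacement profile along the chain with a random frequency, phase and
#' direction, in the spirit of coarse normal modes). It stands in for a
#' frozen trunk + structure module so the inference-time optimization loop
#' can be exercised at desk scale. Its parameters (base coordinates and mode
#' basis) are frozen by construction.
#'
#' @param base_coords numeric matrix (n_res x 3) of the base CA conformation.
#' @param feature_width dimension of the feature vector it consumes (number
#'   of deformation modes).
#' @param seed seed for the deformation basis.
#' @param scale amplitude of one mode in Angstrom per unit feature.
#' @return object of class `fold_head` with elements `forward(features)`,
#'   `vjp(features, d_coords)`, `feature_width`, `n_res` and `checksum`.
#' @export
surrogate_fold_head <- function(base_coords, feature_width = 32, seed = 1,
                                scale = 2) {
  stopifnot(is.matrix(base_coords), ncol(base_coords) == 3)
  n <- nrow(base_coords)
  set.seed((seed + sum(utf8ToInt("fold_modes"))) %% .Machine$integer.max)
  t_idx <- (seq_len(n) - 1) / max(1, n - 1)
  basis <- matrix(0, 3 * n, feature_width)
  for (f in seq_len(feature_width)) {
    freq <- sample(c(0.5, 1, 1.5, 2, 3, 4), 1)
    phase <- runif(1, 0, 2 * pi)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    shape <- sin(pi * freq * t_idx + phase)
    basis[, f] <- as.numeric(outer(shape, dir)) * scale
  }
  structure(list(
    forward = function(features) {
      base_coords + matrix(basis %*% features, n, 3)
    },
    vjp = function(features, d_coords) {
      as.numeric(crossprod(basis, as.numeric(d_coords)))
    },
    feature_width = feature_width,
    n_res = n,
    checksum = function() sum(basis) + sum(base_coords)
  ), class = "fold_head")
}

#' Inference-time adapter optimization against a target P(r)
#'
#' Keeps the fold head frozen and updates only the two-layer MLP adapter by
#' Adam gradient descent on the SAXS L1 loss between the soft P(r) of the
#' predicted CA trace and the target curve (plus a small smooth bond-length
#' penalty). Runs at most `max_iterations` iterations and stops early when
#' the best loss has not improved by at least `improve_tol` for `patience`
#' consecutive iterations. Every iteration's loss and CA snapshot is
#' recorded.
#'
#' @param fold_fn a `fold_head` (frozen predictor).
#' @param target a normalized `pr_curve`.
#' @param config an `adapter_config`.
#' @param features input feature vector (defaults to zeros, so with a
#'   zero-initialized adapter iteration 1 reproduces the base conformation).
#' @param dr,bandwidth soft-histogram bin width and kernel bandwidth
#'   (default: the target's bin width).
#' @return object of class `optimization_trace`.
#' @export
optimize_adapter <- function(fold_fn, target, config = adapter_config(),
                             features = NULL, dr = target$dr,
                             bandwidth = dr) {
  stopifnot(inherits(fold_fn, "fold_head"))
  if (!target$normalized) stop("contract violation: target P(r) must be normalized")
  if (is.null(features)) features <- rep(0, fold_fn$feature_width)
  adapter <- build_adapter(config, length(features))
  checksum_before <- fold_fn$checksum()

  coords0 <- fold_fn$forward(adapter_forward(adapter, features)$out)
  dmax0 <- max(dist(coords0))
  n_bins <- ceiling((1.5 * max(dmax0, target$dmax) + 4 * bandwidth) / dr)
  # smear the target with the same kernel that smooths the model histogram,
  # so the loss minimum sits at the matching structure rather than at one
  # compensating for the smoothing
  sk <- soft_kernel(target$r, n_bins, dr, bandwidth)
  th <- as.numeric(crossprod(sk$k, target$p * target$dr))
  target_p <- th / (sum(th) * dr)
  z <- rep(6, fold_fn$n_res)

  params <- adapter[c("w1", "b1", "w2", "b2")]
  state <- adam_init(params)
  losses <- numeric(0)
  snapshots <- list()
  best <- Inf
  best_iter <- 0L
  stall <- 0L
  stop_reason <- "budget"

  for (it in seq_len(config$max_iterations)) {
    adapter[c("w1", "b1", "w2", "b2")] <- params
    fwd <- adapter_forward(adapter, features)
    coords <- fold_fn$forward(fwd$out)
    res <- soft_l1_grad(coords, z, target_p, dr, bandwidth, n_bins,
                        config$chain_weight)
    if (!is.finite(res$loss)) {
      stop(errorCondition(
        sprintf("non-finite SAXS loss at iteration %d", it),
        trace = list(losses = losses, snapshots = snapshots, iteration = it),
        class = c("saxsfold_nonfinite_loss", "error", "condition")))
    }
    losses[it] <- res$loss
    snapshots[[it]] <- coords
    if (res$loss < best - config$improve_tol) {
      best <- res$loss
      best_iter <- it
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) {
        stop_reason <- "patience"
        break
      }
    }
    d_feat <- fold_fn$vjp(fwd$out, res$grad)
    back <- adapter_backward(adapter, fwd$cache, d_feat)
    upd <- adam_step(params, back[c("w1", "b1", "w2", "b2")], state,
                     config$learning_rate)
    params <- upd$params
    state <- upd$state
  }

  checksum_after <- fold_fn$checksum()
  structure(list(
    losses = losses,
    snapshots = snapshots,
    n_iterations = length(losses),
    best_iteration = best_iter,
    best_loss = best,
    stop_reason = stop_reason,
    seed = config$seed,
    config = config,
    adapter = adapter,
    frozen_checksum = c(before = checksum_before, after = checksum_after)
  ), class = "optimization_trace")
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat(sprintf(
    "optimization_trace: %d iteration(s), best loss %.6g at iteration %d, stopped on %s\n",
    x$n_iterations, x$best_loss, x$best_iteration, x$stop_reason))
  invisible(x)
}

#' Retain the lowest-loss structures of a trace
#'
#' Returns the k snapshots with the lowest recorded SAXS loss in ascending
#' loss order (ties broken by iteration index); a trace shorter than k is
#' returned whole.
#'
#' @param trace an `optimization_trace`.
#' @param k ensemble size.
#' @return list with `structures` (CA coordinate matrices), `losses` and
#'   `iterations`.
#' @export
select_top_k <- function(trace, k) {
  stopifnot(trace$n_iterations >= 1, k >= 1)
  ord <- order(trace$losses, seq_along(trace$losses))
  keep <- head(ord, k)
  list(structures = trace$snapshots[keep],
       losses = trace$losses[keep],
       iterations = keep)
}
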