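# Reference simulation of the early-stopping rule, independent of the loop.
reference_stop <- function(losses, patience, tol = 1e-6,
                           max_iterations = length(losses)) {
  best <- Inf
  stall <- 0
  for (i in seq_along(losses)) {
    if (losses[i] < best - tol) {
      best <- losses[i]
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) return(list(stop = i, reason = "patience"))
    }
  }
  list(stop = length(losses), reason = "budget")
}

# A frozen fold head with scripted coordinate output; vjp returns zeros so
# the adapter receives no signal.
scripted_fold <- function(coords_fn, n_res, feature_width = 4) {
  counter <- new.env()
  counter$t <- 0
  structure(list(
    forward = function(features) {
      counter$t <- counter$t + 1
      coords_fn(counter$t)
    },
    vjp = function(features, d_coords) rep(0, feature_width),
    feature_width = feature_width,
    n_res = n_res,
    checksum = function() 0
  ), class = "fold_head")
}

test_that("adapter is the identity at zero init and deterministic under seed", {
  cfg <- adapter_config(hidden_width = 16, seed = 3)
  ad <- build_adapter(cfg, 10)
  x <- rnorm(10)
  expect_equal(saxsfold:::adapter_forward(ad, x)$out, x)
  ad2 <- build_adapter(cfg, 10)
  expect_identical(ad$w1, ad2$w1)
  # closed-form parameter count for a 2-layer residual MLP
  expect_equal(adapter_n_params(ad), 16 * 10 + 16 + 10 * 16 + 10)
})

test_that("adapter backward pass matches finite differences", {
  cfg <- adapter_config(hidden_width = 5, seed = 2, zero_init_final = FALSE)
  ad <- build_adapter(cfg, 7)
  set.seed(4)
  x <- rnorm(7)
  cot <- rnorm(7)
  fwd <- saxsfold:::adapter_forward(ad, x)
  back <- saxsfold:::adapter_backward(ad, fwd$cache, cot)
  f <- function(adx) sum(saxsfold:::adapter_forward(adx, x)$out * cot)
  eps <- 1e-6
  for (probe in list(c("w1", 3), c("w2", 11), c("b1", 2), c("b2", 6))) {
    nm <- probe[1]
    k <- as.integer(probe[2])
    adp <- ad; adp[[nm]][k] <- adp[[nm]][k] + eps
    adm <- ad; adm[[nm]][k] <- adm[[nm]][k] - eps
    fd <- (f(adp) - f(adm)) / (2 * eps)
    expect_equal(back[[nm]][k], fd, tolerance = 1e-5)
  }
})

test_that("a fold head ignoring the adapter stalls and stops on patience", {
  n <- 12
  fixed <- coords_matrix(make_chain("helix", n_res = n, seed = 2))
  fold <- scripted_fold(function(t) fixed, n)
  target <- compute_pr(make_chain("extended", n_res = n, seed = 2),
                       dr = 0.5, normalize = TRUE)
  cfg <- adapter_config(patience = 10, max_iterations = 100, seed = 1)
  tr <- optimize_adapter(fold, target, cfg)
  expect_equal(tr$stop_reason, "patience")
  # first iteration improves on Inf; the next `patience` fail to improve
  expect_equal(tr$n_iterations, cfg$patience + 1L)
  expect_true(all(abs(tr$losses - tr$losses[1]) < 1e-12))
})

test_that("strictly decreasing loss under patience 1 runs to the budget", {
  n <- 12
  base <- coords_matrix(make_chain("helix", n_res = n, seed = 2))
  target <- compute_pr(ca_structure(base), dr = 0.5, normalize = TRUE)
  # pure dilation decaying toward the target structure: loss strictly falls
  fold <- scripted_fold(function(t) base * (1 + 0.5 * 0.9^t), n)
  cfg <- adapter_config(patience = 1, max_iterations = 40, seed = 1)
  tr <- optimize_adapter(fold, target, cfg)
  expect_equal(tr$stop_reason, "budget")
  expect_equal(tr$n_iterations, 40L)
  expect_true(all(diff(tr$losses) < 0))
})

test_that("the recovery experiment reduces the loss and moves Rg toward the target", {
  n <- 48
  pair <- make_hinge_pair(n_res = n, angle_open = 10, angle_closed = 110,
                          seed = 1)
  target_s <- pair$open
  target <- compute_pr(target_s, dr = 0.5, normalize = TRUE)
  fold <- surrogate_fold_head(coords_matrix(pair$closed), feature_width = 32,
                              seed = 1)
  cfg <- adapter_config(seed = 1, learning_rate = 0.05, max_iterations = 150,
                        patience = 50)
  tr <- optimize_adapter(fold, target, cfg, bandwidth = 2)
  expect_lt(tr$best_loss, tr$losses[1])
  rg_of <- function(m) sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  rg_start <- rg_of(coords_matrix(pair$closed))
  rg_final <- rg_of(tr$snapshots[[tr$best_iteration]])
  rg_target <- rg_of(coords_matrix(target_s))
  expect_lt(abs(rg_final - rg_target), abs(rg_start - rg_target))
  # frozen-trunk contract
  expect_identical(tr$frozen_checksum[["before"]],
                   tr$frozen_checksum[["after"]])
  # stopping iteration matches the reference simulation of the rule
  ref <- reference_stop(tr$losses, cfg$patience,
                        max_iterations = cfg$max_iterations)
  expect_equal(tr$n_iterations, ref$stop)
  expect_equal(tr$stop_reason, ref$reason)
  # the retained ensemble contains non-duplicate conformations
  top <- select_top_k(tr, 50)
  expect_gt(intra_ensemble_rmsd(top$structures), 0)
})

test_that("select_top_k equals full sort plus head", {
  n <- 6
  snaps <- lapply(1:10, function(i) matrix(rnorm(n * 3), n, 3))
  losses <- c(3, 1, 2, 5, 0.5, 4, 2.5, 0.7, 6, 1.5)
  trace <- structure(list(losses = losses, snapshots = snaps,
                          n_iterations = 10L),
                     class = "optimization_trace")
  # shorter trace than k returns everything
  expect_length(select_top_k(trace, 50)$structures, 10)
  top2 <- select_top_k(trace, 2)
  expect_equal(top2$iterations, c(5L, 8L))
  # random long trace against the sort oracle
  set.seed(31)
  big_losses <- runif(500)
  big <- structure(list(losses = big_losses,
                        snapshots = as.list(seq_len(500)),
                        n_iterations = 500L),
                   class = "optimization_trace")
  topk <- select_top_k(big, 50)
  expect_equal(topk$losses, sort(big_losses)[1:50])
  expect_equal(unlist(topk$structures), order(big_losses)[1:50])
})

test_that("surrogate fold head is deterministic, frozen and differentiable", {
  base <- coords_matrix(make_chain("helix", n_res = 20, seed = 3))
  fold <- surrogate_fold_head(base, feature_width = 8, seed = 5)
  f <- rnorm(8)
  expect_identical(fold$forward(f), surrogate_fold_head(base, 8, 5)$forward(f))
  expect_equal(nrow(fold$forward(f)), 20)
  expect_equal(fold$forward(rep(0, 8)), base)
  # vjp against finite differences of an arbitrary scalar of the coords
  set.seed(6)
  w <- matrix(rnorm(60), 20, 3)
  g <- fold$vjp(f, w)
  eps <- 1e-6
  for (k in c(1, 4, 8)) {
    fp <- f; fp[k] <- fp[k] + eps
    fm <- f; fm[k] <- fm[k] - eps
    fd <- (sum(fold$forward(fp) * w) - sum(fold$forward(fm) * w)) / (2 * eps)
    expect_equal(g[k], fd, tolerance = 1e-6)
  }
  # gradient of the SAXS loss w.r.t. features is nonzero for generic inputs
  target <- compute_pr(make_chain("extended", n_res = 20, seed = 3),
                       dr = 0.5, normalize = TRUE)
  nb <- 80
  tp <- resample_pr(target, (seq_len(nb) - 0.5) * 0.5)$p
  res <- saxsfold:::soft_l1_grad(fold$forward(f), rep(6, 20), tp, 0.5, 1, nb, 0)
  expect_gt(max(abs(fold$vjp(f, res$grad))), 0)
})

test_that("non-finite losses abort with a diagnostic condition", {
  n <- 10
  base <- coords_matrix(make_chain("helix", n_res = n, seed = 1))
  fold <- scripted_fold(function(t) if (t >= 4) base * NaN else base, n)
  target <- compute_pr(ca_structure(base), dr = 0.5, normalize = TRUE)
  cfg <- adapter_config(patience = 50, max_iterations = 60, seed = 1)
  expect_error(optimize_adapter(fold, target, cfg),
               class = "saxsfold_nonfinite_loss")
})
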