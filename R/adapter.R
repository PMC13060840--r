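#' Configuration for inference-time adapter optimization
#'
#' Defaults mirror the optimization protocol: at most 500 gradient
#' iterations, early stopping after 50 iterations without improvement of the
#' best SAXS loss, and retention of the 50 lowest-loss snapshots.
#'
#' @param hidden_width adapter hidden layer width.
#' @param learning_rate Adam step size.
#' @param max_iterations iteration budget (>= patience).
#' @param patience consecutive non-improving iterations before stopping.
#' @param top_k ensemble size retained from the trace.
#' @param seed integer seed covering all stochasticity of a run.
#' @param zero_init_final zero the adapter's final layer so it starts as the
#'   identity map.
#' @param improve_tol minimum absolute decrease of the best loss that counts
#'   as an improvement.
#' @param chain_weight weight of the smooth consecutive-CA bond-length
#'   penalty added to the SAXS loss during optimization.
#' @return object of class `adapter_config`.
#' @export
adapter_config <- function(hidden_width = 32, learning_rate = 1e-3,
                           max_iterations = 500, patience = 50, top_k = 50,
                           seed = 1, zero_init_final = TRUE,
                           improve_tol = 1e-6, chain_weight = 1e-4) {
  stopifnot(max_iterations >= patience, patience >= 1, top_k >= 1,
            hidden_width >= 1, learning_rate > 0)
  structure(list(hidden_width = hidden_width, learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience), top_k = as.integer(top_k),
                 seed = as.integer(seed), zero_init_final = zero_init_final,
                 improve_tol = improve_tol, chain_weight = chain_weight),
            class = "adapter_config")
}

#' Build a two-layer residual MLP adapter
#'
#' out = x + W2 tanh(W1 x + b1) + b2. With the final layer zero-initialized
#' the adapter is exactly the identity, so iteration 0 reproduces the frozen
#' predictor's output.
#'
#' @param config an `adapter_config`.
#' @param feature_width width of the feature vector the adapter transforms.
#' @return object of class `mlp_adapter` holding the named parameter tensors.
#' @export
build_adapter <- function(config, feature_width) {
  stopifnot(feature_width >= 1)
  h <- config$hidden_width
  w1 <- init_matrix(h, feature_width, config$seed, "adapter_w1")
  b1 <- rep(0, h)
  w2 <- if (config$zero_init_final) {
    matrix(0, feature_width, h)
  } else {
    init_matrix(feature_width, h, config$seed, "adapter_w2")
  }
  b2 <- rep(0, feature_width)
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                 feature_width = feature_width, hidden_width = h),
            class = "mlp_adapter")
}

#' Number of trainable adapter parameters
#' @param adapter an `mlp_adapter`.
#' @return integer count.
#' @export
adapter_n_params <- function(adapter) {
  length(adapter$w1) + length(adapter$b1) + length(adapter$w2) + length(adapter$b2)
}

# Forward pass; cache holds intermediates for the backward pass.
adapter_forward <- function(adapter, x) {
  pre <- as.numeric(adapter$w1 %*% x) + adapter$b1
  act <- tanh(pre)
  out <- x + as.numeric(adapter$w2 %*% act) + adapter$b2
  list(out = out, cache = list(x = x, act = act))
}

# Backward pass: returns gradients w.r.t. every parameter and the input.
adapter_backward <- function(adapter, cache, d_out) {
  d_b2 <- d_out
  d_w2 <- outer(d_out, cache$act)
  d_act <- as.numeric(t(adapter$w2) %*% d_out)
  d_pre <- d_act * (1 - cache$act^2)
  d_b1 <- d_pre
  d_w1 <- outer(d_pre, cache$x)
  d_x <- d_out + as.numeric(t(adapter$w1) %*% d_pre)
  list(w1 = d_w1, b1 = d_b1, w2 = d_w2, b2 = d_b2, d_x = d_x)
}

# Minimal Adam optimizer over a named list of parameter tensors.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
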