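# Deterministic scaled-normal init; one stream per (seed, tag) so parameter
# shapes can change independently without reshuffling everything.
init_matrix <- function(nrow, ncol, seed, tag, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(ncol)
  set.seed((seed + sum(utf8ToInt(tag))) %% .Machine$integer.max)
  matrix(rnorm(nrow * ncol, sd = scale), nrow, ncol)
}

#' Parameters for a SAXS cross-attention module
#'
#' Multi-head cross-attention from a latent representation (queries) onto the
#' per-bin tokens of a P(r) curve (keys/values). The defaults follow the two
#' module variants: 8 heads for the MSA-side module and 4 heads for the
#' pair-side module, both with per-head width c = 32. The output projection
#' is zero-initialized by default so an untrained module is a strict no-op on
#' the trunk.
#'
#' @param n_heads number of attention heads.
#' @param c per-head key/query/value width.
#' @param c_in channel width of the representation being updated.
#' @param c_s token width (defaults to `n_heads * c`).
#' @param seed integer seed for weight initialization.
#' @param zero_init_output zero the output projection (identity module).
#' @return object of class `attention_params`.
#' @export
attention_params <- function(n_heads = 8, c = 32, c_in = 64,
                             c_s = n_heads * c, seed = 1,
                             zero_init_output = TRUE) {
  stopifnot(n_heads >= 1, c >= 1, c_in >= 1, c_s >= 1)
  wq <- lapply(seq_len(n_heads), function(h)
    init_matrix(c_in, c, seed, paste0("wq", h)))
  wk <- lapply(seq_len(n_heads), function(h)
    init_matrix(c_s, c, seed, paste0("wk", h)))
  wv <- lapply(seq_len(n_heads), function(h)
    init_matrix(c_s, c, seed, paste0("wv", h)))
  wo <- if (zero_init_output) {
    matrix(0, n_heads * c, c_in)
  } else {
    init_matrix(n_heads * c, c_in, seed, "wo")
  }
  structure(list(n_heads = n_heads, c = c, c_in = c_in, c_s = c_s,
                 seed = seed, wq = wq, wk = wk, wv = wv, wo = wo),
            class = "attention_params")
}

#' Embed a P(r) curve as attention tokens
#'
#' One token per bin: a learned linear map of the bin density p_k
#' concatenated with a sinusoidal encoding of the bin center r_k. With a
#' zero value map the tokens are identically zero.
#'
#' @param pr a normalized `pr_curve`.
#' @param c_s token width.
#' @param seed seed for the embedding weights.
#' @param n_freq number of sinusoidal frequency pairs encoding r_k.
#' @param zero_init use a zero embedding map (for identity-at-init checks).
#' @return numeric matrix (n_bins x c_s) of class `saxs_tokens`.
#' @export
embed_pr <- function(pr, c_s = 256, seed = 1, n_freq = 8, zero_init = FALSE) {
  if (!pr$normalized) stop("contract violation: embed_pr requires a normalized curve")
  rmax <- max(pr$r)
  freqs <- 2^(seq_len(n_freq) - 1) * pi / rmax
  ang <- outer(pr$r, freqs)
  feats <- cbind(pr$p, sin(ang), cos(ang))       # n_bins x (1 + 2 n_freq)
  w <- if (zero_init) {
    matrix(0, ncol(feats), c_s)
  } else {
    init_matrix(ncol(feats), c_s, seed, "embed")
  }
  tok <- feats %*% w
  class(tok) <- c("saxs_tokens", class(tok))
  tok
}

# Core multi-head cross-attention: queries (n_q x c_in) attend over tokens
# (n_bins x c_s); returns the additive update (n_q x c_in) and, optionally,
# the per-head attention weights.
cross_attention <- function(queries, tokens, params, return_attention = FALSE) {
  if (ncol(queries) != params$c_in) {
    stop("contract error: query width ", ncol(queries),
         " != c_in ", params$c_in)
  }
  if (ncol(tokens) != params$c_s) {
    stop("contract error: token width ", ncol(tokens),
         " != c_s ", params$c_s)
  }
  heads <- vector("list", params$n_heads)
  attn_list <- if (return_attention) vector("list", params$n_heads) else NULL
  inv_sqrt_c <- 1 / sqrt(params$c)
  for (h in seq_len(params$n_heads)) {
    qh <- queries %*% params$wq[[h]]             # n_q x c
    kh <- tokens %*% params$wk[[h]]              # n_bins x c
    vh <- tokens %*% params$wv[[h]]              # n_bins x c
    logits <- (qh %*% t(kh)) * inv_sqrt_c        # n_q x n_bins
    logits <- logits - apply(logits, 1, max)
    a <- exp(logits)
    a <- a / rowSums(a)
    heads[[h]] <- a %*% vh
    if (return_attention) attn_list[[h]] <- a
  }
  update <- do.call(cbind, heads) %*% params$wo
  if (return_attention) list(update = update, attention = attn_list) else update
}

#' SAXS cross-attention update for an MSA representation
#'
#' Every (cluster, residue) position of the MSA representation forms a query
#' over the P(r) tokens; softmax attention weights decide how strongly each
#' distance bin influences that position. The returned tensor has the shape
#' of the input and is meant to be ADDED to it by the caller before the
#' Evoformer trunk.
#'
#' @param msa 3-d array (n_clust, n_res, c_m).
#' @param tokens `saxs_tokens` from [embed_pr()].
#' @param params `attention_params` with `c_in` equal to c_m.
#' @param return_attention also return per-head attention weight matrices.
#' @return additive update array of the same shape as `msa` (or a list with
#'   `update` and `attention`).
#' @export
saxs_msa_attention <- function(msa, tokens, params, return_attention = FALSE) {
  stopifnot(length(dim(msa)) == 3)
  d <- dim(msa)
  queries <- matrix(msa, d[1] * d[2], d[3])
  out <- cross_attention(queries, tokens, params, return_attention)
  if (return_attention) {
    list(update = array(out$update, d), attention = out$attention)
  } else {
    array(out, d)
  }
}

#' SAXS cross-attention update for a pair representation
#'
#' One query per residue pair (i, j); no weight sharing across the symmetric
#' positions (i, j) and (j, i), matching the asymmetry of trunk pair
#' activations.
#'
#' @param pair 3-d array (n_res, n_res, c_z).
#' @inheritParams saxs_msa_attention
#' @return additive update array of the same shape as `pair`.
#' @export
saxs_pair_attention <- function(pair, tokens, params, return_attention = FALSE) {
  stopifnot(length(dim(pair)) == 3, dim(pair)[1] == dim(pair)[2])
  d <- dim(pair)
  queries <- matrix(pair, d[1] * d[2], d[3])
  out <- cross_attention(queries, tokens, params, return_attention)
  if (return_attention) {
    list(update = array(out$update, d), attention = out$attention)
  } else {
    array(out, d)
  }
}

#' Save / load conditioning-module parameters
#'
#' A checkpoint is a single file holding the named tensors of one or more
#' modules plus their configuration.
#'
#' @param params named list of `attention_params` (and any extra config).
#' @param path checkpoint file path.
#' @return `load_checkpoint` returns the named list.
#' @export
save_checkpoint <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
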