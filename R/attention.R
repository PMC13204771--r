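# Multi-head attention with a fused input projection (one (D x 3D) weight for
# the query/key/value paths, parameter-equivalent to three separate D x D
# projections) and a D x D output projection, both with bias.  Queries, keys
# and values may come from different tensors (self-attention passes the same
# matrix three times; cross-attention and latent pooling do not).

mha_init <- function(d, sd = 0.02) {
  list(
    W_in = trunc_normal_init(d, 3L * d, sd),
    b_in = numeric(3L * d),
    W_out = trunc_normal_init(d, d, sd),
    b_out = numeric(d)
  )
}

#' Multi-head attention forward pass
#'
#' @param p parameter list from [mha_init()].
#' @param xq,xk,xv query/key/value input matrices (tokens x D).
#' @param n_heads number of attention heads; D must be divisible by it.
#' @param causal apply a causal (lower-triangular) mask; requires
#'   `nrow(xq) == nrow(xk)`.
#' @param dropout attention-probability dropout rate (active only when
#'   `training` is `TRUE`).
#' @param keep_attn retain per-head attention probability matrices in the
#'   cache (needed for attention inspection and Grad-CAM).
#' @return list(out, cache); `cache$P` holds per-head probabilities when kept.
#' @keywords internal
mha_fwd <- function(p, xq, xk, xv, n_heads, causal = FALSE,
                    dropout = 0, training = FALSE, keep_attn = FALSE) {
  d <- ncol(xq)
  stopifnot(d %% n_heads == 0)
  dk <- d %/% n_heads
  Wq <- p$W_in[, seq_len(d), drop = FALSE]
  Wk <- p$W_in[, d + seq_len(d), drop = FALSE]
  Wv <- p$W_in[, 2L * d + seq_len(d), drop = FALSE]
  Q <- sweep(xq %*% Wq, 2, p$b_in[seq_len(d)], `+`)
  K <- sweep(xk %*% Wk, 2, p$b_in[d + seq_len(d)], `+`)
  V <- sweep(xv %*% Wv, 2, p$b_in[2L * d + seq_len(d)], `+`)

  Tq <- nrow(xq)
  O <- matrix(0, Tq, d)
  P_list <- vector("list", n_heads)
  mask_list <- vector("list", n_heads)
  scale <- 1 / sqrt(dk)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * scale
    if (causal) S[upper.tri(S)] <- -Inf
    P <- softmax_rows(S)
    dr <- dropout_fwd(P, dropout, training)
    O[, idx] <- dr$out %*% V[, idx, drop = FALSE]
    P_list[[h]] <- P
    mask_list[h] <- list(dr$mask)
  }
  out <- sweep(O %*% p$W_out, 2, p$b_out, `+`)
  cache <- list(
    xq = xq, xk = xk, xv = xv, Q = Q, K = K, V = V, O = O,
    P = P_list, masks = mask_list, causal = causal, n_heads = n_heads
  )
  if (!keep_attn && !training) cache$masks <- NULL
  list(out = out, cache = cache)
}

#' Multi-head attention backward pass
#'
#' @param return_dP also return the gradient of the scalar objective with
#'   respect to each head's attention probabilities (used by Grad-CAM).
#' @return list(dxq, dxk, dxv, grads, dP).
#' @keywords internal
mha_bwd <- function(p, cache, dout, return_dP = FALSE) {
  d <- ncol(cache$xq)
  n_heads <- cache$n_heads
  dk <- d %/% n_heads
  scale <- 1 / sqrt(dk)

  gW_out <- crossprod(cache$O, dout)
  gb_out <- colSums(dout)
  dO <- dout %*% t(p$W_out)

  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  dP_out <- if (return_dP) vector("list", n_heads) else NULL

  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    P <- cache$P[[h]]
    mask <- if (!is.null(cache$masks)) cache$masks[[h]] else NULL
    Pd <- if (is.null(mask)) P else P * mask
    dOh <- dO[, idx, drop = FALSE]
    dPd <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Pd, dOh)
    dP <- if (is.null(mask)) dPd else dPd * mask
    if (return_dP) dP_out[[h]] <- dP
    # softmax backward per row
    dS <- P * (dP - rowSums(dP * P))
    if (cache$causal) dS[upper.tri(dS)] <- 0
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] * scale
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) * scale
  }

  Wq <- p$W_in[, seq_len(d), drop = FALSE]
  Wk <- p$W_in[, d + seq_len(d), drop = FALSE]
  Wv <- p$W_in[, 2L * d + seq_len(d), drop = FALSE]
  gW_in <- cbind(
    crossprod(cache$xq, dQ),
    crossprod(cache$xk, dK),
    crossprod(cache$xv, dV)
  )
  gb_in <- c(colSums(dQ), colSums(dK), colSums(dV))
  list(
    dxq = dQ %*% t(Wq),
    dxk = dK %*% t(Wk),
    dxv = dV %*% t(Wv),
    grads = list(W_in = gW_in, b_in = gb_in, W_out = gW_out, b_out = gb_out),
    dP = dP_out
  )
}
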