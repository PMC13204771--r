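# Learnable Query Attention Pooling (LQAP): trainable latent queries attend
# over a token set to produce a fixed-size, content-adaptive summary.  The
# inter-slice (latent) pool compresses the 985-token concatenation of 5
# encoded slices into a 197-token patient-level context; the patient pool
# compresses that context into a single 768-vector.  Query, key and value
# inputs pass through independent LayerNorms; the residual adds the raw
# (pre-LN) queries; an LN + 4x GELU MLP with residual refines the result.
# Mean/max/single-head baseline pools are included for the pooling ablation.

#' LQAP configuration
#'
#' @param n_latent number of latent queries (197 for the inter-slice pool,
#'   1 for the patient pool).
#' @param embed_dim token width D.
#' @param heads attention heads.
#' @param mlp_ratio MLP expansion ratio.
#' @param dropout dropout rate (training mode only).
#' @export
lqap_config <- function(n_latent = 197L, embed_dim = 768L, heads = 12L,
                        mlp_ratio = 4L, dropout = 0.1) {
  if (n_latent < 1) stop("n_latent must be >= 1")
  structure(
    list(
      n_latent = as.integer(n_latent), embed_dim = as.integer(embed_dim),
      heads = as.integer(heads), head_dim = as.integer(embed_dim %/% heads),
      mlp_ratio = as.integer(mlp_ratio), dropout = dropout
    ),
    class = "lqap_config"
  )
}

#' Initialise an LQAP block (queries Xavier-uniform, as published)
#' @param config an [lqap_config()].
#' @return nested parameter list.
#' @export
lqap_init <- function(config) {
  d <- config$embed_dim
  list(
    queries = xavier_uniform_init(config$n_latent, d),
    ln_q = ln_init(d), ln_k = ln_init(d), ln_v = ln_init(d),
    attn = mha_init(d),
    ln_mlp = ln_init(d),
    mlp = mlp_init(d, config$mlp_ratio)
  )
}

#' Concatenate per-slice token sequences along the token dimension
#'
#' @param per_slice list of exactly 5 (n_tokens x D) matrices.
#' @return (5 * n_tokens x D) matrix.
#' @export
concat_slices <- function(per_slice) {
  if (length(per_slice) != 5L) {
    stop(sprintf("expected exactly 5 slice sequences, got %d", length(per_slice)))
  }
  widths <- vapply(per_slice, ncol, integer(1))
  if (length(unique(widths)) != 1L) stop("slice sequences differ in width")
  do.call(rbind, per_slice)
}

#' Split a concatenated token matrix back into the 5 slice blocks
#' @param tokens (5 * n_tokens x D) matrix.
#' @return list of 5 matrices.
#' @export
split_slices <- function(tokens) {
  n <- nrow(tokens) %/% 5L
  lapply(seq_len(5L), function(i) tokens[(i - 1L) * n + seq_len(n), , drop = FALSE])
}

#' LQAP forward pass
#'
#' `A = MHA(LN(Q), LN(X), LN(X)) + Q` followed by `Z = A + MLP(LN(A))`.
#' Output always has `n_latent` rows regardless of the input token count;
#' permuting input rows leaves the output unchanged (attention over a
#' permuted key set is order-free).
#'
#' @param params parameters from [lqap_init()].
#' @param tokens (T x D) input token matrix.
#' @param config the [lqap_config()].
#' @param training enable dropout.
#' @param keep_attn retain attention probabilities.
#' @return list(out = (n_latent x D) matrix, cache).
#' @export
lqap_fwd <- function(params, tokens, config, training = FALSE,
                     keep_attn = FALSE) {
  if (!all(is.finite(tokens))) stop("non-finite values in pooled tokens")
  if (ncol(tokens) != config$embed_dim) {
    stop("token width does not match embed_dim")
  }
  lq <- ln_fwd(params$ln_q, params$queries)
  lk <- ln_fwd(params$ln_k, tokens)
  lv <- ln_fwd(params$ln_v, tokens)
  at <- mha_fwd(params$attn, lq$out, lk$out, lv$out, config$heads,
    dropout = config$dropout, training = training, keep_attn = keep_attn
  )
  dr1 <- dropout_fwd(at$out, config$dropout, training)
  a <- dr1$out + params$queries # residual adds the RAW queries
  lm <- ln_fwd(params$ln_mlp, a)
  ml <- mlp_fwd(params$mlp, lm$out, dropout = config$dropout, training = training)
  dr2 <- dropout_fwd(ml$out, config$dropout, training)
  out <- a + dr2$out
  list(out = out, cache = list(lq = lq, lk = lk, lv = lv, at = at,
                               m1 = dr1$mask, lm = lm, ml = ml, m2 = dr2$mask))
}

#' LQAP backward pass
#' @param params,cache,dout as usual; `config` the [lqap_config()].
#' @return list(dtokens, grads).
#' @export
lqap_bwd <- function(params, cache, dout, config) {
  dml <- dropout_bwd(cache$m2, dout)
  mb <- mlp_bwd(params$mlp, cache$ml$cache, dml)
  lmb <- ln_bwd(params$ln_mlp, cache$lm$cache, mb$dx)
  da <- dout + lmb$dx
  dat <- dropout_bwd(cache$m1, da)
  ab <- mha_bwd(params$attn, cache$at$cache, dat)
  lqb <- ln_bwd(params$ln_q, cache$lq$cache, ab$dxq)
  lkb <- ln_bwd(params$ln_k, cache$lk$cache, ab$dxk)
  lvb <- ln_bwd(params$ln_v, cache$lv$cache, ab$dxv)
  dqueries <- da + lqb$dx # residual path + LN(query) path
  list(
    dtokens = lkb$dx + lvb$dx,
    grads = list(
      queries = dqueries,
      ln_q = lqb$grads, ln_k = lkb$grads, ln_v = lvb$grads,
      attn = ab$grads, ln_mlp = lmb$grads, mlp = mb$grads
    )
  )
}

#' Closed-form trainable parameter count of an LQAP block
#' @param config an [lqap_config()].
#' @return integer count.
#' @export
lqap_param_count <- function(config) {
  d <- config$embed_dim
  config$n_latent * d +        # latent queries
    3 * 2 * d +                # independent Q/K/V LayerNorms
    (d * 3 * d + 3 * d) +      # fused in-projection
    (d * d + d) +              # out-projection
    2 * d +                    # pre-MLP LayerNorm
    (d * config$mlp_ratio * d + config$mlp_ratio * d) +
    (config$mlp_ratio * d * d + d)
}

#' Baseline pooling for the ablation study
#'
#' Mean or max over tokens per feature, or a single-head attention pool with
#' one learnable query.  All three collapse the token set to one vector and
#' therefore cannot feed the cross-attention decoder.
#'
#' @param tokens (T x D) matrix.
#' @param mode `"mean"`, `"max"` or `"single_head_attn"`.
#' @param params for `"single_head_attn"`, a list with `query` (length-D),
#'   `W_q`, `W_k` (D x D); see [single_head_pool_init()].
#' @return length-D patient embedding vector.
#' @export
baseline_pool <- function(tokens, mode = c("mean", "max", "single_head_attn"),
                          params = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    mean = colMeans(tokens),
    max = apply(tokens, 2, max),
    single_head_attn = {
      if (is.null(params)) stop("single_head_attn requires params")
      q <- params$query %*% params$W_q # 1 x D
      k <- tokens %*% params$W_k # T x D
      logits <- as.vector(k %*% t(q)) / sqrt(ncol(tokens))
      w <- exp(logits - max(logits))
      w <- w / sum(w)
      as.vector(crossprod(tokens, w))
    }
  )
}

#' Initialise a single-head attention pool
#' @param d token width.
#' @return parameter list for [baseline_pool()].
#' @export
single_head_pool_init <- function(d) {
  list(
    query = matrix(stats::rnorm(d, 0, 0.02), 1, d),
    W_q = trunc_normal_init(d, d),
    W_k = trunc_normal_init(d, d)
  )
}

## ---- classification head ----------------------------------------------------

#' Initialise the classification head
#'
#' `LN -> Linear(D -> hidden) -> GELU -> Linear(hidden -> 3)`; hidden width
#' defaults to 256.
#' @param d patient-embedding width.
#' @param hidden hidden width.
#' @param n_classes number of classes (Normal, SCLC, NSCLC).
#' @export
head_init <- function(d, hidden = 256L, n_classes = 3L) {
  list(ln = ln_init(d), fc1 = linear_init(d, hidden),
       fc2 = linear_init(hidden, n_classes))
}

head_fwd <- function(params, z) {
  zm <- matrix(z, 1)
  l <- ln_fwd(params$ln, zm)
  f1 <- linear_fwd(params$fc1, l$out)
  a <- gelu(f1$out)
  f2 <- linear_fwd(params$fc2, a)
  list(out = as.vector(f2$out), cache = list(l = l, f1 = f1, pre = f1$out, f2 = f2))
}

head_bwd <- function(params, cache, dlogits) {
  b2 <- linear_bwd(params$fc2, cache$f2$cache, matrix(dlogits, 1))
  dpre <- b2$dx * gelu_grad(cache$pre)
  b1 <- linear_bwd(params$fc1, cache$f1$cache, dpre)
  lb <- ln_bwd(params$ln, cache$l$cache, b1$dx)
  list(dz = as.vector(lb$dx),
       grads = list(ln = lb$grads, fc1 = b1$grads, fc2 = b2$grads))
}

#' Closed-form parameter count of the classification head
#' @param d,hidden,n_classes as in [head_init()].
#' @export
head_param_count <- function(d, hidden = 256L, n_classes = 3L) {
  2 * d + (d * hidden + hidden) + (hidden * n_classes + n_classes)
}

#' Classify a patient embedding
#'
#' @param params head parameters from [head_init()].
#' @param embedding length-D patient embedding.
#' @param label optional 1-based true class index for the cross-entropy loss.
#' @return object of class `class_prediction`: logits (Normal, SCLC, NSCLC),
#'   probabilities, `predicted_class`, `max_confidence`, and `loss` when a
#'   label is given.
#' @export
classify <- function(params, embedding, label = NULL) {
  hf <- head_fwd(params, embedding)
  z <- hf$out - max(hf$out)
  p <- exp(z) / sum(exp(z))
  structure(
    list(
      logits = hf$out,
      probabilities = stats::setNames(p, CLASS_LEVELS[seq_along(p)]),
      predicted_class = CLASS_LEVELS[which.max(p)],
      max_confidence = max(p),
      loss = if (!is.null(label)) -log(p[label]) else NULL
    ),
    class = "class_prediction"
  )
}
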