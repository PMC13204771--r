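# GPT-2-style text decoder with cross-attention to the LQAP context.  Twelve
# pre-norm blocks, each: masked self-attention, cross-attention (LayerNorm on
# the text/query path only; keys and values are the raw visual context), and
# a 4x GELU MLP, all residual.  The LM head is weight-tied to the token
# embedding.  Teacher forcing computes all next-token logits in one pass;
# inference is an autoregressive greedy loop conditioned on the fixed
# context, started and terminated by `<|endoftext|>`.

#' Decoder configuration
#'
#' @param vocab vocabulary size (default the 50,257-token GPT-2 BPE space,
#'   shared by the TR and EN scenarios).
#' @param embed_dim token width D.
#' @param layers decoder blocks.
#' @param heads attention heads.
#' @param max_positions learned positional embedding capacity.
#' @param mlp_ratio MLP expansion ratio.
#' @param dropout dropout rate (attention/MLP/embedding; training only).
#' @param max_generate generation cap in tokens.
#' @param temperature,top_k sampling controls; the default (`top_k = 0`,
#'   temperature 0) is greedy decoding.
#' @export
decoder_config <- function(vocab = GPT2_VOCAB_SIZE, embed_dim = 768L,
                           layers = 12L, heads = 12L, max_positions = 1024L,
                           mlp_ratio = 4L, dropout = 0.1, max_generate = 64L,
                           temperature = 0, top_k = 0L) {
  if (vocab <= 0) stop("vocab must be positive")
  if (max_generate > max_positions) stop("max_generate must be <= max_positions")
  structure(
    list(
      vocab = as.integer(vocab), embed_dim = as.integer(embed_dim),
      layers = as.integer(layers), heads = as.integer(heads),
      max_positions = as.integer(max_positions),
      mlp_ratio = as.integer(mlp_ratio), dropout = dropout,
      max_generate = as.integer(max_generate),
      temperature = temperature, top_k = as.integer(top_k),
      eot_id = as.integer(vocab - 1L)
    ),
    class = "decoder_config"
  )
}

decoder_block_init <- function(d, ratio) {
  list(
    ln1 = ln_init(d), self_attn = mha_init(d),
    ln2 = ln_init(d), cross_attn = mha_init(d),
    ln3 = ln_init(d), mlp = mlp_init(d, ratio)
  )
}

#' Initialise decoder parameters (token embedding doubles as the LM head)
#' @param config a [decoder_config()].
#' @export
decoder_init <- function(config) {
  d <- config$embed_dim
  list(
    tok_emb = trunc_normal_init(config$vocab, d),
    pos_emb = trunc_normal_init(config$max_positions, d),
    blocks = lapply(seq_len(config$layers), function(i) {
      decoder_block_init(d, config$mlp_ratio)
    }),
    ln_f = ln_init(d)
  )
}

decoder_block_fwd <- function(p, h, context, heads, dropout = 0,
                              training = FALSE, keep_attn = FALSE) {
  l1 <- ln_fwd(p$ln1, h)
  sa <- mha_fwd(p$self_attn, l1$out, l1$out, l1$out, heads,
    causal = TRUE, dropout = dropout, training = training, keep_attn = keep_attn
  )
  d1 <- dropout_fwd(sa$out, dropout, training)
  h1 <- h + d1$out
  l2 <- ln_fwd(p$ln2, h1)
  ca <- mha_fwd(p$cross_attn, l2$out, context, context, heads,
    dropout = dropout, training = training, keep_attn = keep_attn
  )
  d2 <- dropout_fwd(ca$out, dropout, training)
  h2 <- h1 + d2$out
  l3 <- ln_fwd(p$ln3, h2)
  ml <- mlp_fwd(p$mlp, l3$out, dropout = dropout, training = training)
  d3 <- dropout_fwd(ml$out, dropout, training)
  list(out = h2 + d3$out, cache = list(
    l1 = l1, sa = sa, m1 = d1$mask, l2 = l2, ca = ca, m2 = d2$mask,
    l3 = l3, ml = ml, m3 = d3$mask
  ))
}

decoder_block_bwd <- function(p, cache, dout) {
  dm <- dropout_bwd(cache$m3, dout)
  mb <- mlp_bwd(p$mlp, cache$ml$cache, dm)
  l3b <- ln_bwd(p$ln3, cache$l3$cache, mb$dx)
  dh2 <- dout + l3b$dx
  dca <- dropout_bwd(cache$m2, dh2)
  cb <- mha_bwd(p$cross_attn, cache$ca$cache, dca)
  l2b <- ln_bwd(p$ln2, cache$l2$cache, cb$dxq)
  dh1 <- dh2 + l2b$dx
  dsa <- dropout_bwd(cache$m1, dh1)
  sb <- mha_bwd(p$self_attn, cache$sa$cache, dsa)
  l1b <- ln_bwd(p$ln1, cache$l1$cache, sb$dxq + sb$dxk + sb$dxv)
  list(
    dh = dh1 + l1b$dx,
    dcontext = cb$dxk + cb$dxv,
    grads = list(
      ln1 = l1b$grads, self_attn = sb$grads, ln2 = l2b$grads,
      cross_attn = cb$grads, ln3 = l3b$grads, mlp = mb$grads
    )
  )
}

#' Teacher-forced decoder pass with language-modeling loss
#'
#' Feeds the whole token sequence in parallel under a causal mask; each
#' position predicts the next token.  The loss is the token-mean
#' cross-entropy over non-masked target positions.
#'
#' @param params decoder parameters.
#' @param token_ids integer vector (1-based internally; raw ids 0-based).
#' @param context (n_context x D) visual context from the latent pool.
#' @param config a [decoder_config()].
#' @param training enable dropout.
#' @param loss_mask optional logical vector over target positions
#'   (length `length(token_ids) - 1`); `FALSE` positions (padding) are
#'   excluded from the loss.
#' @param keep_cache retain caches for backpropagation.
#' @return list(logits = (T x vocab), loss, cache).
#' @export
decode_teacher_forced <- function(params, token_ids, context, config,
                                  training = FALSE, loss_mask = NULL,
                                  keep_cache = TRUE) {
  if (ncol(context) != config$embed_dim) {
    stop("context width does not match decoder embed_dim")
  }
  if (any(token_ids < 0 | token_ids >= config$vocab)) {
    stop("token id out of vocabulary range")
  }
  TT <- length(token_ids)
  if (TT > config$max_positions) stop("sequence exceeds max_positions")
  idx <- token_ids + 1L
  h <- params$tok_emb[idx, , drop = FALSE] +
    params$pos_emb[seq_len(TT), , drop = FALSE]
  emb_mask <- dropout_fwd(h, config$dropout, training)
  h <- emb_mask$out
  caches <- if (keep_cache) vector("list", config$layers) else NULL
  for (l in seq_len(config$layers)) {
    bl <- decoder_block_fwd(params$blocks[[l]], h, context, config$heads,
      dropout = config$dropout, training = training
    )
    h <- bl$out
    if (keep_cache) caches[[l]] <- bl$cache
  }
  fin <- ln_fwd(params$ln_f, h)
  logits <- tcrossprod(fin$out, params$tok_emb) # weight-tied LM head

  loss <- NA_real_
  dlogits <- NULL
  if (TT >= 2L) {
    targets <- idx[-1L]
    mask <- if (is.null(loss_mask)) rep(TRUE, TT - 1L) else loss_mask
    n_eff <- sum(mask)
    dlogits <- matrix(0, TT, config$vocab)
    total <- 0
    for (t in seq_len(TT - 1L)) {
      if (!mask[t]) next
      ce <- cross_entropy(logits[t, ], targets[t])
      total <- total + ce$loss
      dlogits[t, ] <- ce$dlogits / n_eff
    }
    loss <- total / n_eff
  }
  list(
    logits = logits, loss = loss,
    cache = list(idx = idx, emb_mask = emb_mask$mask, caches = caches,
                 fin = fin, dlogits = dlogits, TT = TT)
  )
}

#' Backward pass of the teacher-forced decoder
#'
#' @param params decoder parameters.
#' @param fwd result of [decode_teacher_forced()] (with caches).
#' @param config a [decoder_config()].
#' @param dloss upstream scale on the language-modeling loss.
#' @return list(grads, dcontext).
#' @export
decoder_bwd <- function(params, fwd, config, dloss = 1) {
  cache <- fwd$cache
  dlogits <- cache$dlogits * dloss
  H <- cache$fin$out
  g_tok_head <- crossprod(dlogits, H) # head side of the tied embedding
  dH <- dlogits %*% params$tok_emb
  fb <- ln_bwd(params$ln_f, cache$fin$cache, dH)
  dh <- fb$dx
  block_grads <- vector("list", config$layers)
  dcontext <- 0
  for (l in rev(seq_len(config$layers))) {
    bb <- decoder_block_bwd(params$blocks[[l]], cache$caches[[l]], dh)
    dh <- bb$dh
    dcontext <- dcontext + bb$dcontext
    block_grads[[l]] <- bb$grads
  }
  dh <- dropout_bwd(cache$emb_mask, dh)
  g_tok <- g_tok_head
  for (t in seq_len(cache$TT)) {
    g_tok[cache$idx[t], ] <- g_tok[cache$idx[t], ] + dh[t, ]
  }
  g_pos <- matrix(0, config$max_positions, config$embed_dim)
  g_pos[seq_len(cache$TT), ] <- dh
  list(
    grads = list(tok_emb = g_tok, pos_emb = g_pos, blocks = block_grads,
                 ln_f = fb$grads),
    dcontext = dcontext
  )
}

#' Autoregressive report generation
#'
#' Starts from `<|endoftext|>`, re-attends to the fixed context at each step,
#' and stops at `<|endoftext|>` or `max_generate` tokens.  Greedy by default;
#' `temperature > 0` enables (optionally top-k) sampling.
#'
#' @param params decoder parameters.
#' @param context (n_context x D) visual context.
#' @param config a [decoder_config()].
#' @param max_generate optional override of the configured cap.
#' @return integer vector of generated token ids (without the BOS,
#'   including the terminating EOS if emitted).
#' @export
generate_report_ids <- function(params, context, config,
                                max_generate = config$max_generate) {
  ids <- config$eot_id
  for (step in seq_len(max_generate)) {
    fwd <- decode_teacher_forced(params, ids, context, config,
      training = FALSE, keep_cache = FALSE
    )
    logits <- fwd$logits[length(ids), ]
    nxt <- if (config$temperature > 0) {
      z <- logits / config$temperature
      if (config$top_k > 0) {
        keep <- order(z, decreasing = TRUE)[seq_len(min(config$top_k, length(z)))]
        z[-keep] <- -Inf
      }
      p <- exp(z - max(z))
      sample.int(length(z), 1, prob = p / sum(p)) - 1L
    } else {
      which.max(logits) - 1L
    }
    ids <- c(ids, nxt)
    if (nxt == config$eot_id) break
  }
  ids[-1L]
}

#' Closed-form trainable parameter count of the decoder
#'
#' Token + positional embeddings, per-block (self-attention, cross-attention,
#' MLP, three LayerNorms), final LayerNorm; the LM head is tied and not
#' counted separately.
#' @param config a [decoder_config()].
#' @export
decoder_param_count <- function(config) {
  d <- config$embed_dim
  attn <- (d * 3 * d + 3 * d) + (d * d + d)
  mlp <- (d * config$mlp_ratio * d + config$mlp_ratio * d) +
    (config$mlp_ratio * d * d + d)
  per_block <- 2 * attn + mlp + 3 * 2 * d
  config$vocab * d + config$max_positions * d +
    config$layers * per_block + 2 * d
}

## ---- pretrained checkpoint loading ------------------------------------------

nl_assign <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  keyname <- function(k) {
    kk <- suppressWarnings(as.integer(k))
    if (!is.na(kk)) kk else k
  }
  assign_rec <- function(node, keys, value) {
    if (length(keys) == 1L) {
      node[[keyname(keys[1])]] <- value
      return(node)
    }
    k <- keyname(keys[1])
    node[[k]] <- assign_rec(node[[k]], keys[-1], value)
    node
  }
  assign_rec(params, keys, value)
}

#' Load shape-matching tensors from a pretrained language-model checkpoint
#'
#' Tensors whose name and shape match the decoder's are copied; the
#' cross-attention sublayers, absent from a text-only language model, are
#' always left at their fresh initialisation.
#'
#' @param params decoder parameters from [decoder_init()].
#' @param checkpoint either a path to an RDS file or a named flat list of
#'   arrays keyed by dot-joined parameter paths (e.g.
#'   `"blocks.1.self_attn.W_in"`).
#' @return list(params = updated parameters, report = tibble with one row per
#'   decoder tensor and a `status` of `"copied"` or `"fresh"`).
#' @export
load_pretrained_lm <- function(params, checkpoint) {
  if (is.character(checkpoint)) {
    if (!file.exists(checkpoint)) {
      stop(sprintf("pretrained checkpoint not found: %s", checkpoint))
    }
    checkpoint <- readRDS(checkpoint)
  }
  flat <- nl_flatten(params)
  status <- character(length(flat))
  for (i in seq_along(flat)) {
    nm <- names(flat)[i]
    own <- flat[[i]]
    ck <- checkpoint[[nm]]
    same_shape <- !is.null(ck) &&
      identical(dim(ck), dim(own)) && length(ck) == length(own)
    if (same_shape && !grepl("cross_attn", nm)) {
      params <- nl_assign(params, nm, ck)
      status[i] <- "copied"
    } else {
      status[i] <- "fresh"
    }
  }
  list(
    params = params,
    report = tibble::tibble(tensor = names(flat), status = status)
  )
}
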