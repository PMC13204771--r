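# Per-slice ViT encoder: patch tokenization, CLS token, learnable positional
# embeddings, and pre-norm transformer blocks (attention and MLP sublayers
# each wrapped as x + Sublayer(LN(x))), with a final LayerNorm after the last
# block.  The base profile is ViT-Base/16 (224 input, 12 layers, 12 heads,
# D = 768, 85.80 M trainable parameters).

#' Encoder configuration
#'
#' @param image_size input side length (must be divisible by `patch_size`).
#' @param patch_size patch side length.
#' @param embed_dim token width D (divisible by `heads`).
#' @param layers number of transformer blocks.
#' @param heads attention heads.
#' @param mlp_ratio MLP expansion ratio.
#' @param dropout dropout rate for attention probabilities, MLP and residual
#'   branches (active in training mode only).
#' @return object of class `encoder_config`; `n_patches` and `n_tokens` are
#'   derived.
#' @export
encoder_config <- function(image_size = 224L, patch_size = 16L,
                           embed_dim = 768L, layers = 12L, heads = 12L,
                           mlp_ratio = 4L, dropout = 0.1) {
  if (image_size %% patch_size != 0) {
    stop("image_size must be divisible by patch_size")
  }
  if (embed_dim %% heads != 0) stop("embed_dim must be divisible by heads")
  n <- (image_size %/% patch_size)^2
  structure(
    list(
      image_size = as.integer(image_size), patch_size = as.integer(patch_size),
      n_patches = as.integer(n), n_tokens = as.integer(n + 1L),
      embed_dim = as.integer(embed_dim), layers = as.integer(layers),
      heads = as.integer(heads), head_dim = as.integer(embed_dim %/% heads),
      mlp_ratio = as.integer(mlp_ratio), dropout = dropout
    ),
    class = "encoder_config"
  )
}

#' Split an image into non-overlapping flattened patches
#'
#' Patches are ordered row-major over the patch grid; each patch is the
#' column-major vectorisation of its (p, p, C) block.
#'
#' @param image (side x side x C) numeric array.
#' @param p patch side length.
#' @return (n_patches x p*p*C) matrix.
#' @export
patchify <- function(image, p) {
  side <- dim(image)[1]
  if (side %% p != 0) stop("image side must be divisible by the patch size")
  g <- side %/% p
  ch <- dim(image)[3]
  out <- matrix(0, g * g, p * p * ch)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      blk <- image[(i - 1) * p + seq_len(p), (j - 1) * p + seq_len(p), , drop = FALSE]
      out[(i - 1) * g + j, ] <- as.vector(blk)
    }
  }
  out
}

#' Inverse of [patchify()]
#' @param patches (n_patches x p*p*C) matrix.
#' @param p patch side length.
#' @param channels channel count C.
#' @return (side x side x C) array.
#' @export
unpatchify <- function(patches, p, channels = 3L) {
  g <- as.integer(sqrt(nrow(patches)))
  side <- g * p
  out <- array(0, dim = c(side, side, channels))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      out[(i - 1) * p + seq_len(p), (j - 1) * p + seq_len(p), ] <-
        array(patches[(i - 1) * g + j, ], dim = c(p, p, channels))
    }
  }
  out
}

encoder_block_init <- function(d, ratio) {
  list(ln1 = ln_init(d), attn = mha_init(d), ln2 = ln_init(d),
       mlp = mlp_init(d, ratio))
}

#' Initialise encoder parameters
#'
#' Patch projection and block weights use truncated normal (sd 0.02); the
#' CLS token and positional embeddings likewise.
#' @param config an [encoder_config()].
#' @return nested parameter list.
#' @export
encoder_init <- function(config) {
  d <- config$embed_dim
  in_dim <- config$patch_size^2 * 3L
  list(
    patch = linear_init(in_dim, d),
    cls = stats::rnorm(d, 0, 0.02),
    pos = trunc_normal_init(config$n_tokens, d),
    blocks = lapply(seq_len(config$layers), function(i) {
      encoder_block_init(d, config$mlp_ratio)
    }),
    ln_f = ln_init(d)
  )
}

#' Embed flattened patches into the layer-0 token sequence
#'
#' Linear projection to D, CLS prepended at position 1, learnable positional
#' embedding added.
#' @param params encoder parameter list.
#' @param patches (n_patches x p*p*C) matrix.
#' @return list(out = (n_tokens x D) matrix, cache).
#' @export
embed_slice <- function(params, patches) {
  if (ncol(patches) != nrow(params$patch$W)) {
    stop(sprintf(
      "patch length %d does not match projection input %d",
      ncol(patches), nrow(params$patch$W)
    ))
  }
  pr <- linear_fwd(params$patch, patches)
  tokens <- rbind(params$cls, pr$out) + params$pos
  list(out = tokens, cache = pr$cache)
}

embed_slice_bwd <- function(params, cache, dout) {
  g_pos <- dout
  g_cls <- dout[1, ]
  bp <- linear_bwd(params$patch, cache$cache, dout[-1, , drop = FALSE])
  list(
    dpatches = bp$dx,
    grads = list(patch = bp$grads, cls = g_cls, pos = g_pos)
  )
}

encoder_block_fwd <- function(p, x, heads, dropout = 0, training = FALSE,
                              keep_attn = FALSE) {
  l1 <- ln_fwd(p$ln1, x)
  at <- mha_fwd(p$attn, l1$out, l1$out, l1$out, heads,
    dropout = dropout, training = training, keep_attn = keep_attn
  )
  dr1 <- dropout_fwd(at$out, dropout, training)
  x1 <- x + dr1$out
  l2 <- ln_fwd(p$ln2, x1)
  ml <- mlp_fwd(p$mlp, l2$out, dropout = dropout, training = training)
  dr2 <- dropout_fwd(ml$out, dropout, training)
  out <- x1 + dr2$out
  list(out = out, cache = list(l1 = l1, at = at, m1 = dr1$mask,
                               l2 = l2, ml = ml, m2 = dr2$mask))
}

encoder_block_bwd <- function(p, cache, dout, return_dP = FALSE) {
  dml <- dropout_bwd(cache$m2, dout)
  mb <- mlp_bwd(p$mlp, cache$ml$cache, dml)
  l2b <- ln_bwd(p$ln2, cache$l2$cache, mb$dx)
  dx1 <- dout + l2b$dx
  dat <- dropout_bwd(cache$m1, dx1)
  ab <- mha_bwd(p$attn, cache$at$cache, dat, return_dP = return_dP)
  dl1 <- ab$dxq + ab$dxk + ab$dxv
  l1b <- ln_bwd(p$ln1, cache$l1$cache, dl1)
  dx <- dx1 + l1b$dx
  list(
    dx = dx,
    grads = list(ln1 = l1b$grads, attn = ab$grads, ln2 = l2b$grads,
                 mlp = mb$grads),
    dP = ab$dP
  )
}

#' Run the encoder blocks over a layer-0 token sequence
#'
#' @param params encoder parameters.
#' @param tokens (n_tokens x D) layer-0 sequence from [embed_slice()].
#' @param config the [encoder_config()].
#' @param training enable dropout.
#' @param keep_cache retain per-layer caches for backpropagation.
#' @param keep_attn retain attention probabilities (Grad-CAM, inspection).
#' @return list(out = (n_tokens x D) after the final LayerNorm, caches).
#' @export
encode_slice <- function(params, tokens, config, training = FALSE,
                         keep_cache = TRUE, keep_attn = FALSE) {
  caches <- if (keep_cache) vector("list", config$layers) else NULL
  x <- tokens
  for (l in seq_len(config$layers)) {
    bl <- encoder_block_fwd(params$blocks[[l]], x, config$heads,
      dropout = config$dropout, training = training, keep_attn = keep_attn
    )
    x <- bl$out
    if (keep_cache) caches[[l]] <- bl$cache
  }
  fin <- ln_fwd(params$ln_f, x)
  list(out = fin$out, caches = caches, ln_f_cache = fin$cache)
}

#' Backward pass through the encoder blocks and embedding
#'
#' @param params encoder parameters.
#' @param fwd result of [encode_slice()] (with caches).
#' @param embed result of [embed_slice()].
#' @param dout upstream gradient (n_tokens x D).
#' @param config the [encoder_config()].
#' @param capture_dP_layer optionally capture the attention-probability
#'   gradient at one block (1-based layer index) for Grad-CAM.
#' @return list(grads, dP) where grads matches [encoder_init()]'s structure.
#' @export
encoder_bwd <- function(params, fwd, embed, dout, config,
                        capture_dP_layer = NULL) {
  fb <- ln_bwd(params$ln_f, fwd$ln_f_cache, dout)
  dx <- fb$dx
  block_grads <- vector("list", config$layers)
  dP <- NULL
  for (l in rev(seq_len(config$layers))) {
    want <- !is.null(capture_dP_layer) && l == capture_dP_layer
    bb <- encoder_block_bwd(params$blocks[[l]], fwd$caches[[l]], dx,
      return_dP = want
    )
    dx <- bb$dx
    block_grads[[l]] <- bb$grads
    if (want) dP <- bb$dP
  }
  eb <- embed_slice_bwd(params, embed, dx)
  list(
    grads = list(
      patch = eb$grads$patch, cls = eb$grads$cls, pos = eb$grads$pos,
      blocks = block_grads, ln_f = fb$grads
    ),
    dP = dP
  )
}

#' Closed-form trainable parameter count of the encoder
#'
#' Patch projection + positional embedding + CLS + per-block
#' (2 LayerNorms, fused QKV with bias, output projection, MLP) + final
#' LayerNorm.
#' @param config an [encoder_config()].
#' @return integer count.
#' @export
encoder_param_count <- function(config) {
  d <- config$embed_dim
  in_dim <- config$patch_size^2 * 3
  per_block <- 2 * 2 * d +               # two LayerNorms
    (d * 3 * d + 3 * d) +                # fused QKV
    (d * d + d) +                        # output projection
    (d * config$mlp_ratio * d + config$mlp_ratio * d) + # MLP fc1
    (config$mlp_ratio * d * d + d)       # MLP fc2
  (in_dim * d + d) + config$n_tokens * d + d +
    config$layers * per_block + 2 * d
}
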