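# Full framework assembly: per-slice ViT encoder -> 5-slice concatenation ->
# inter-slice LQAP (197-token patient context) -> patient-level LQAP pool ->
# classification head, with the GPT-2-style decoder cross-attending to the
# patient context for report generation.  Two profiles are provided: "base"
# (the published ViT-Base/16 + GPT-2 geometry) and "tiny" (a reduced CPU
# profile for tests and smoke runs).

#' Model configuration for a named profile
#'
#' The `"base"` profile is the published geometry: 224x224 input, 16x16
#' patches (196 + CLS = 197 tokens), D = 768, 12 encoder and 12 decoder
#' layers, 12 heads, 197 latent queries, 50,257-token vocabulary.  The
#' `"tiny"` profile (32x32 input, D = 64, 2 + 2 layers, 4 heads, byte-level
#' 257-token vocabulary) preserves every structural relationship (latent
#' query count = per-slice token count; 5 slices; weight tying) at CPU test
#' scale.
#'
#' @param profile `"base"` or `"tiny"`.
#' @param head_hidden classification-head hidden width.
#' @param dropout dropout rate shared by all components.
#' @return object of class `lungformer_config`.
#' @export
model_config <- function(profile = c("tiny", "base"), head_hidden = 256L,
                         dropout = 0.1) {
  profile <- match.arg(profile)
  if (profile == "base") {
    enc <- encoder_config(dropout = dropout)
    dec <- decoder_config(dropout = dropout)
  } else {
    enc <- encoder_config(
      image_size = 32L, patch_size = 16L, embed_dim = 64L,
      layers = 2L, heads = 4L, dropout = dropout
    )
    dec <- decoder_config(
      vocab = 257L, embed_dim = 64L, layers = 2L, heads = 4L,
      max_positions = 160L, dropout = dropout
    )
  }
  structure(
    list(
      profile = profile,
      n_slices = 5L,
      encoder = enc,
      lqap_latent = lqap_config(
        n_latent = enc$n_tokens, embed_dim = enc$embed_dim,
        heads = enc$heads, dropout = dropout
      ),
      lqap_patient = lqap_config(
        n_latent = 1L, embed_dim = enc$embed_dim,
        heads = enc$heads, dropout = dropout
      ),
      decoder = dec,
      head_hidden = as.integer(head_hidden)
    ),
    class = "lungformer_config"
  )
}

#' Instantiate a model
#'
#' @param config a [model_config()] or a profile name.
#' @param seed integer seed for parameter initialisation.
#' @return object of class `lungformer_model` with `$config` and `$params`
#'   (encoder, lqap_latent, lqap_patient, head, decoder).
#' @export
lungformer_model <- function(config = "tiny", seed = 1L) {
  if (is.character(config)) config <- model_config(config)
  with_seed(seed, {
    params <- list(
      encoder = encoder_init(config$encoder),
      lqap_latent = lqap_init(config$lqap_latent),
      lqap_patient = lqap_init(config$lqap_patient),
      head = head_init(config$encoder$embed_dim, config$head_hidden),
      decoder = decoder_init(config$decoder)
    )
    structure(list(config = config, params = params), class = "lungformer_model")
  })
}

#' @export
print.lungformer_model <- function(x, ...) {
  cat(sprintf(
    "<lungformer_model: %s profile, %.2f M trainable parameters>\n",
    x$config$profile, sum(count_params(x)$parameters[1:5]) / 1e6
  ))
  invisible(x)
}

#' End-to-end forward pass for one patient
#'
#' @param model a [lungformer_model()].
#' @param pixels (5 x side x side x 3) standardised pixel array
#'   (see [scale_stack()]).
#' @param label optional 1-based true class (1 Normal, 2 SCLC, 3 NSCLC);
#'   enables the classification loss.
#' @param token_ids optional 0-based report token ids; enables the
#'   teacher-forced language-modeling loss.
#' @param training enable dropout.
#' @param keep_cache retain every cache needed for [model_backward()].
#' @param keep_attn retain attention probabilities (Grad-CAM).
#' @return list with `latent` (patient context), `patient` (embedding),
#'   `prediction` ([classify()] output), `loss_cls`, `loss_report`, and
#'   caches.
#' @export
model_forward <- function(model, pixels, label = NULL, token_ids = NULL,
                          training = FALSE, keep_cache = TRUE,
                          keep_attn = FALSE) {
  cfg <- model$config
  p <- model$params
  embeds <- vector("list", cfg$n_slices)
  encs <- vector("list", cfg$n_slices)
  outs <- vector("list", cfg$n_slices)
  for (i in seq_len(cfg$n_slices)) {
    patches <- patchify(pixels[i, , , ], cfg$encoder$patch_size)
    em <- embed_slice(p$encoder, patches)
    en <- encode_slice(p$encoder, em$out, cfg$encoder,
      training = training, keep_cache = keep_cache, keep_attn = keep_attn
    )
    embeds[[i]] <- em
    encs[[i]] <- en
    outs[[i]] <- en$out
  }
  xcat <- concat_slices(outs)
  lat <- lqap_fwd(p$lqap_latent, xcat, cfg$lqap_latent,
    training = training, keep_attn = keep_attn
  )
  pat <- lqap_fwd(p$lqap_patient, lat$out, cfg$lqap_patient,
    training = training, keep_attn = keep_attn
  )
  z_patient <- as.vector(pat$out)
  pred <- classify(p$head, z_patient, label = label)
  head_cache <- head_fwd(p$head, z_patient)

  dec <- NULL
  if (!is.null(token_ids)) {
    dec <- decode_teacher_forced(p$decoder, token_ids, lat$out, cfg$decoder,
      training = training, keep_cache = keep_cache
    )
  }
  list(
    latent = lat$out, patient = z_patient, prediction = pred,
    loss_cls = if (!is.null(label)) unname(pred$loss) else NA_real_,
    loss_report = if (!is.null(dec)) dec$loss else NA_real_,
    cache = if (keep_cache) list(
      embeds = embeds, encs = encs, lat = lat, pat = pat,
      head = head_cache, dec = dec, label = label
    ) else NULL,
    dec_logits = if (!is.null(dec)) dec$logits else NULL
  )
}

#' Backward pass of the joint objective `L_cls + lambda * L_report`
#'
#' @param model a [lungformer_model()].
#' @param fwd result of [model_forward()] with caches, label and (optionally)
#'   token ids.
#' @param lambda report-loss weight.
#' @return nested gradient list matching `model$params`.
#' @export
model_backward <- function(model, fwd, lambda = 0.3) {
  cfg <- model$config
  p <- model$params
  cache <- fwd$cache
  stopifnot(!is.null(cache), !is.null(cache$label))

  ce <- cross_entropy(fwd$prediction$logits, cache$label)
  hb <- head_bwd(p$head, cache$head$cache, ce$dlogits)
  pb <- lqap_bwd(p$lqap_patient, cache$pat$cache, matrix(hb$dz, 1),
                 cfg$lqap_patient)
  dlatent <- pb$dtokens

  dec_grads <- NULL
  if (!is.null(cache$dec) && lambda > 0) {
    db <- decoder_bwd(p$decoder, cache$dec, cfg$decoder, dloss = lambda)
    dec_grads <- db$grads
    dlatent <- dlatent + db$dcontext
  }

  lb <- lqap_bwd(p$lqap_latent, cache$lat$cache, dlatent, cfg$lqap_latent)
  dslices <- split_slices(lb$dtokens)

  enc_grads <- NULL
  for (i in seq_len(cfg$n_slices)) {
    eb <- encoder_bwd(p$encoder, cache$encs[[i]], cache$embeds[[i]],
      dslices[[i]], cfg$encoder
    )
    enc_grads <- nl_add(enc_grads, eb$grads)
  }
  list(
    encoder = enc_grads,
    lqap_latent = lb$grads,
    lqap_patient = pb$grads,
    head = hb$grads,
    decoder = dec_grads
  )
}

#' Trainable-parameter accounting table
#'
#' One row per component plus the total, in raw counts and millions
#' (2 decimals), mirroring the published hyperparameter table layout.  The
#' decoder's LM head is weight-tied to its token embedding and therefore not
#' counted separately.
#'
#' @param x a `lungformer_model`, a `lungformer_config`, or a profile name.
#' @return tibble with `component`, `parameters`, `millions`.
#' @export
count_params <- function(x = "base") {
  if (is.character(x)) x <- model_config(x)
  if (inherits(x, "lungformer_model")) {
    cfg <- x$config
    counts <- c(
      Encoder = nl_count(x$params$encoder),
      Decoder = nl_count(x$params$decoder),
      `LQAP (Latent)` = nl_count(x$params$lqap_latent),
      `LQAP (Patient)` = nl_count(x$params$lqap_patient),
      `Classification head` = nl_count(x$params$head)
    )
  } else {
    cfg <- x
    # instantiate component by component so peak memory stays bounded
    counts <- c(
      Encoder = nl_count(encoder_init(cfg$encoder)),
      Decoder = nl_count(decoder_init(cfg$decoder)),
      `LQAP (Latent)` = nl_count(lqap_init(cfg$lqap_latent)),
      `LQAP (Patient)` = nl_count(lqap_init(cfg$lqap_patient)),
      `Classification head` = nl_count(head_init(cfg$encoder$embed_dim,
                                                 cfg$head_hidden))
    )
    gc(verbose = FALSE)
  }
  counts <- c(counts, Total = sum(counts))
  tibble::tibble(
    component = names(counts),
    parameters = unname(counts),
    millions = round(unname(counts) / 1e6, 2)
  )
}

#' Predict class (and optionally a report) for one preprocessed stack
#'
#' @param model a trained or fresh [lungformer_model()].
#' @param stack a [build_slice_stack()] result (scaled or raw; raw stacks are
#'   scaled with [scale_stack()] defaults).
#' @param generate also decode a report from the patient context.
#' @param tokenizer a [report_tokenizer()] for decoding generated ids.
#' @return tibble with one row: predicted class, per-class probabilities,
#'   max confidence, and the generated text when requested.
#' @export
predict_patient <- function(model, stack, generate = FALSE,
                            tokenizer = report_tokenizer(model$config$decoder$vocab)) {
  if (is.null(stack$scaled)) stack <- scale_stack(stack)
  fwd <- model_forward(model, stack$pixels, keep_cache = FALSE)
  text <- NA_character_
  if (generate) {
    ids <- generate_report_ids(model$params$decoder, fwd$latent, model$config$decoder)
    text <- tokenizer$decode(ids)
  }
  pr <- fwd$prediction
  tibble::tibble(
    patient_id = stack$patient_id,
    predicted_class = pr$predicted_class,
    p_normal = unname(pr$probabilities[1]),
    p_sclc = unname(pr$probabilities[2]),
    p_nsclc = unname(pr$probabilities[3]),
    max_confidence = pr$max_confidence,
    generated_text = text
  )
}
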