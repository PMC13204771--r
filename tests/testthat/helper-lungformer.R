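# Shared fixtures, all built in code at test time.

tiny_model <- function(seed = 2L, dropout = 0) {
  lungformer_model(model_config("tiny", dropout = dropout), seed = seed)
}

rand_pixels <- function(seed = 7L, side = 32L) {
  set.seed(seed)
  array(rnorm(5 * side * side * 3), dim = c(5, side, side, 3))
}

small_cohort_spec <- function(n_per_class = c(2, 2, 2), seed = 11L,
                              depth = 16L, rows = 48L, cols = 48L) {
  cohort_spec(n_per_class = n_per_class, depth = depth, rows = rows,
              cols = cols, seed = seed)
}

# preprocessed training samples for the tiny profile
make_samples <- function(cohort, language = "EN") {
  mcfg <- model_config("tiny")
  tok <- report_tokenizer(mcfg$decoder$vocab)
  field <- if (language == "TR") "report_tr" else "report_en"
  lapply(cohort, function(p) {
    st <- scale_stack(build_slice_stack(p$volume, p$slice_indices, size = 32L,
                                        patient_id = p$patient_id))
    fr <- filter_report(p[[field]], "parenchyma", language)
    s <- tokenize_report(paste(fr$sentences, collapse = " "), tok, 160L, language)
    list(patient_id = p$patient_id, label_name = p$label,
         label = match(p$label, c("Normal", "SCLC", "NSCLC")),
         pixels = st$pixels, token_ids = s$token_ids)
  })
}

# mask centroid of a lesion on a given slice
mask_centroid <- function(mask_slice) {
  idx <- which(mask_slice, arr.ind = TRUE)
  colMeans(idx)
}
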