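# Masked self-attention + cross-attention decoder: causality, weight tying,
# generation, pretrained-weight transfer.

tiny_decoder <- function(seed = 4L, dropout = 0) {
  cfg <- decoder_config(vocab = 257L, embed_dim = 64L, layers = 2L,
                        heads = 4L, max_positions = 160L, dropout = dropout)
  set.seed(seed)
  list(cfg = cfg, params = decoder_init(cfg), ctx = matrix(rnorm(5 * 64), 5, 64))
}

test_that("teacher forcing yields per-position vocabulary logits and a finite loss", {
  td <- tiny_decoder()
  ids <- c(256L, 10L, 20L, 30L, 256L)
  fwd <- decode_teacher_forced(td$params, ids, td$ctx, td$cfg)
  expect_identical(dim(fwd$logits), c(5L, 257L))
  expect_true(is.finite(fwd$loss))
  expect_error(decode_teacher_forced(td$params, ids, matrix(0, 5, 32), td$cfg),
               "width")
  expect_error(decode_teacher_forced(td$params, c(0L, 300L), td$ctx, td$cfg),
               "vocabulary")
})

test_that("the causal mask makes logits independent of future tokens", {
  td <- tiny_decoder()
  a <- c(256L, 5L, 6L, 7L, 8L, 9L)
  b <- c(256L, 5L, 6L, 99L, 98L, 97L) # identical through position 3
  la <- decode_teacher_forced(td$params, a, td$ctx, td$cfg)$logits
  lb <- decode_teacher_forced(td$params, b, td$ctx, td$cfg)$logits
  expect_equal(la[1:3, ], lb[1:3, ], tolerance = 1e-10)
  expect_gt(max(abs(la[4:6, ] - lb[4:6, ])), 1e-6)
})

test_that("cross-attention rows over the context tokens sum to 1", {
  td <- tiny_decoder()
  ids <- c(256L, 1L, 2L, 3L)
  fwd <- decode_teacher_forced(td$params, ids, td$ctx, td$cfg)
  for (l in seq_len(td$cfg$layers)) {
    for (P in fwd$cache$caches[[l]]$ca$cache$P) {
      expect_identical(dim(P), c(4L, 5L))
      expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
    }
  }
})

test_that("the LM head is weight-tied to the token embedding", {
  td <- tiny_decoder()
  ids <- c(256L, 1L, 2L)
  base <- decode_teacher_forced(td$params, ids, td$ctx, td$cfg)$logits
  mutated <- td$params
  set.seed(77)
  mutated$tok_emb[50, ] <- mutated$tok_emb[50, ] + rnorm(64)
  after <- decode_teacher_forced(mutated, ids, td$ctx, td$cfg)$logits
  # mutating one embedding row moves that vocabulary column of the logits
  expect_gt(max(abs(after[, 50] - base[, 50])), 1e-3)
  expect_equal(after[, 49], base[, 49], tolerance = 1e-10)
})

test_that("greedy generation is deterministic with the prefix property", {
  td <- tiny_decoder()
  g1 <- generate_report_ids(td$params, td$ctx, td$cfg, max_generate = 12L)
  g2 <- generate_report_ids(td$params, td$ctx, td$cfg, max_generate = 12L)
  expect_identical(g1, g2)
  expect_lte(length(g1), 12L)
  longer <- generate_report_ids(td$params, td$ctx, td$cfg, max_generate = 24L)
  expect_identical(longer[seq_along(g1)], g1)
  expect_lte(length(generate_report_ids(td$params, td$ctx, td$cfg)), 64L)
})

test_that("closed-form decoder parameter count matches the instantiated count", {
  td <- tiny_decoder()
  expect_identical(nl_count(td$params), decoder_param_count(td$cfg))
  # published geometry (50,257 vocab, 1024 positions, 12 blocks, tied head)
  expect_identical(decoder_param_count(decoder_config()), 152806656)
})

test_that("pretrained weights transfer by shape while cross-attention stays fresh", {
  td <- tiny_decoder(seed = 4L)
  donor <- tiny_decoder(seed = 99L)
  ckpt <- nl_flatten(donor$params)
  res <- load_pretrained_lm(td$params, ckpt)
  st <- setNames(res$report$status, res$report$tensor)
  expect_identical(unname(st["tok_emb"]), "copied")
  expect_identical(unname(st["pos_emb"]), "copied")
  expect_true(all(st[grepl("cross_attn", names(st))] == "fresh"))
  expect_true(all(st[grepl("self_attn", names(st))] == "copied"))
  expect_equal(res$params$tok_emb, donor$params$tok_emb)
  expect_equal(res$params$blocks[[1]]$cross_attn$W_in,
               td$params$blocks[[1]]$cross_attn$W_in)
  # shape mismatches are left fresh
  short <- list(tok_emb = matrix(0, 10, 64))
  res2 <- load_pretrained_lm(td$params, short)
  expect_identical(
    res2$report$status[res2$report$tensor == "tok_emb"], "fresh"
  )
  expect_error(load_pretrained_lm(td$params, tempfile()), "not found")
})

test_that("a few optimizer steps on a fixed pair reduce the language loss", {
  td <- tiny_decoder(seed = 12L)
  tok <- report_tokenizer(257L)
  ids <- tokenize_report("a small test report.", tok, 64L)$token_ids
  ov <- overfit_decoder(td$params, td$ctx, ids, td$cfg, steps = 40L, lr = 1e-3)
  expect_lt(ov$losses[40], ov$losses[1])
})
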