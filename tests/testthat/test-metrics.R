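# Classification and caption metric engines on worked examples and
# property-style suites.

tr_cm <- matrix(c(26, 0, 0,
                  1, 23, 1,
                  0, 0, 26), nrow = 3, byrow = TRUE,
                dimnames = list(c("Normal", "SCLC", "NSCLC"),
                                c("Normal", "SCLC", "NSCLC")))
en_cm <- matrix(c(26, 0, 0,
                  1, 22, 2,
                  0, 1, 25), nrow = 3, byrow = TRUE,
                dimnames = list(c("Normal", "SCLC", "NSCLC"),
                                c("Normal", "SCLC", "NSCLC")))

test_that("the published per-scenario confusion matrices reproduce the printed metrics", {
  tr <- classification_metrics(tr_cm)
  expect_equal(round(tr$overall$accuracy, 2), 97.40)
  expect_equal(round(tr$overall$macro_f1, 2), 97.35)
  expect_equal(round(tr$overall$macro_specificity, 2), 98.69)
  expect_equal(round(tr$overall$macro_precision, 2), 97.53)
  expect_equal(round(tr$overall$macro_recall, 2), 97.33)
  pc <- tr$per_class
  expect_equal(round(pc$precision[pc$class == "Normal"], 2), 96.30)
  expect_equal(round(pc$recall[pc$class == "SCLC"], 2), 92.00)
  expect_equal(round(pc$specificity[pc$class == "SCLC"], 2), 100.00)
  expect_equal(round(pc$f1[pc$class == "NSCLC"], 2), 98.11)

  en <- classification_metrics(en_cm)
  expect_equal(round(en$overall$accuracy, 2), 94.81)
  # exact macro F1 is 94.71; the printed 94.70 averages per-class values
  # that were already rounded (91.66 for SCLC)
  expect_equal(round(en$overall$macro_f1, 2), 94.71)
  expect_equal(round(en$overall$macro_specificity, 2), 97.40)
  expect_equal(round(en$per_class$specificity[3], 2), 96.08)
})

test_that("identity and degenerate confusion matrices behave correctly", {
  ident <- diag(c(10, 20, 30))
  m <- classification_metrics(ident)
  expect_equal(m$overall$accuracy, 100)
  expect_equal(m$overall$macro_f1, 100)
  expect_true(all(m$per_class$specificity == 100))
  # a class never predicted: precision undefined (NA), never silently zero
  cm <- matrix(c(5, 0, 0, 3, 0, 0, 2, 0, 0), 3, byrow = TRUE)
  m2 <- classification_metrics(cm)
  expect_true(is.na(m2$per_class$precision[2]))
  expect_true(is.na(m2$overall$macro_precision))
  expect_false(isTRUE(m2$per_class$precision[2] == 0))
})

test_that("micro accuracy equals the fraction of correct raw predictions", {
  set.seed(20)
  classes <- c("Normal", "SCLC", "NSCLC")
  truth <- sample(classes, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth, sample(classes, 200, replace = TRUE))
  cm <- confusion_matrix(truth, pred)
  expect_identical(sum(cm), 200L)
  m <- classification_metrics(cm)
  expect_equal(m$overall$accuracy, 100 * mean(truth == pred), tolerance = 1e-12)
})

test_that("specificity of one class equals recall of its complement in a binary reduction", {
  cm2 <- matrix(c(40, 10, 5, 45), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  m <- classification_metrics(cm2)
  expect_equal(m$per_class$specificity[m$per_class$class == "A"],
               m$per_class$recall[m$per_class$class == "B"], tolerance = 1e-12)
})

test_that("one-vs-rest AUC behaves as a rank statistic", {
  classes <- c("Normal", "SCLC", "NSCLC")
  # perfectly separable scores
  truth <- rep(classes, each = 10)
  probs <- matrix(0.05, 30, 3)
  for (i in seq_along(truth)) probs[i, match(truth[i], classes)] <- 0.9
  a <- roc_auc(truth, probs)
  expect_equal(a$auc, rep(1, 3))
  # label-independent scores concentrate near 1/2
  set.seed(21)
  n <- 3000
  truth2 <- sample(classes, n, replace = TRUE)
  raw <- matrix(rexp(n * 3), n, 3)
  probs2 <- raw / rowSums(raw)
  a2 <- roc_auc(truth2, probs2)
  expect_true(all(abs(a2$auc - 0.5) < 0.05))
  # invariance under strictly monotone transforms of the class scores
  ord_before <- roc_auc(truth2, probs2)$auc[1]
  a3 <- as.numeric(pROC::auc(pROC::roc(
    response = truth2 == "Normal", predictor = stats::plogis(5 * probs2[, 1] - 1),
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )))
  expect_equal(a3, ord_before, tolerance = 1e-12)
  # single-class truth is flagged undefined (one warning per missing class)
  w <- capture_warnings(a4 <- roc_auc(rep("Normal", 5),
                                      matrix(rep(c(1, 0, 0), 5), 5,
                                             byrow = TRUE)))
  expect_true(all(grepl("undefined", w)))
  expect_true(is.na(a4$auc[2]))
  expect_error(roc_auc(truth, matrix(1, 30, 3)), "sum to 1")
})

test_that("caption metrics satisfy identity, zero and hand-counted cases", {
  refs <- c("the right lower lobe mass is spiculated .",
            "no focal lesion is observed in either lung .")
  ident <- caption_metrics(refs, refs)
  expect_equal(ident$bleu_1, 1)
  expect_equal(ident$bleu_4, 1)
  expect_equal(ident$rouge_l, 1)
  expect_equal(ident$cider, 10, tolerance = 1e-9)
  expect_gt(ident$meteor, 0.99)
  # no shared token
  expect_equal(bleu_score("xyz qrs", "abc def")[["bleu_1"]], 0)
  # clipped unigram oracle: "a b c" vs "a b d" shares 2 of 3 unigrams
  expect_equal(bleu_score("a b c", "a b d")[["bleu_1"]], 2 / 3, tolerance = 1e-12)
  expect_warning(z <- caption_metrics("", "a b c"), "empty")
  expect_equal(z$bleu_1, 0)
  expect_equal(z$rouge_l, 0)
})

test_that("BLEU-n is non-increasing in n on a template corpus", {
  cands <- c("in the peripheral left lung parenchyma a spiculated lesion is observed",
             "both lung parenchyma are clear with no focal lesion",
             "a smooth solid lesion measuring 18 mm is observed")
  refs <- c("in the peripheral left lung parenchyma a smooth lesion is seen",
            "both lung parenchyma are normal with no lesion",
            "a smooth solid mass measuring 21 mm in long axis is observed")
  b <- bleu_score(cands, refs)
  expect_true(all(diff(b) <= 1e-12))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("ROUGE-L and METEOR reward subsequence and alignment structure", {
  # LCS oracle: candidate "a b c d", reference "a x c" -> LCS = 2 (a, c)
  # P = 2/4, R = 2/3, F1 = 2 PR/(P+R) = 4/7
  expect_equal(rouge_l_score("a b c d", "a x c"), 4 / 7, tolerance = 1e-12)
  expect_equal(rouge_l_score("a b", "c d"), 0)
  # METEOR: perfect match with one chunk -> penalty 0.5 * (1/m)^3
  m <- meteor_score("a b c d", "a b c d")
  expect_equal(m, 1 * (1 - 0.5 * (1 / 4)^3), tolerance = 1e-12)
  expect_equal(meteor_score("a b", "x y"), 0)
  # fragmentation lowers the score at equal match counts
  frag <- meteor_score("a x b y c", "a b c")
  contig <- meteor_score("a b c y z", "a b c")
  expect_lt(frag, contig)
})

test_that("confidence analysis summarises correct and incorrect groups faithfully", {
  preds <- tibble::tibble(
    predicted_class = c("Normal", "SCLC", "NSCLC", "Normal"),
    max_confidence = c(1.0, 0.62, 0.55, 0.97)
  )
  truth <- c("Normal", "SCLC", "SCLC", "Normal")
  ca <- confidence_analysis(preds, truth)
  expect_identical(ca$cases$correct, c(TRUE, TRUE, FALSE, TRUE))
  s <- ca$summary
  expect_equal(s$mean_confidence[s$correct], mean(c(1.0, 0.62, 0.97)))
  expect_equal(s$mean_confidence[!s$correct], 0.55)
  expect_identical(s$n[s$correct], 3L)
  # uniform predictions have confidence 1/3
  hp <- head_init(8)
  hp$fc2$W[] <- 0; hp$fc2$b[] <- 0
  u <- classify(hp, rnorm(8))
  expect_equal(u$max_confidence, 1 / 3, tolerance = 1e-12)
})
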