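# Caption metrics for generated reports: BLEU-1..4 (corpus-level, clipped
# n-gram precision with brevity penalty and uniform weights), ROUGE-L
# (longest-common-subsequence F-measure, beta = 1), METEOR (exact-match
# unigram alignment F-mean with a fragmentation penalty; alpha = 0.9,
# gamma = 0.5, exponent 3) and plain CIDEr (tf-idf weighted n-gram cosine
# consensus, n = 1..4, scaled by 10).  Tokenization is lowercase with
# punctuation split into separate tokens, independent of the model's BPE
# vocabulary.  The corpus is single-reference (one official report per
# patient).

#' Caption-metric tokenizer: lowercase, punctuation-separated word tokens
#' @param text character string.
#' @return character vector of tokens.
#' @export
caption_tokenize <- function(text) {
  x <- tolower(text)
  x <- gsub("([[:punct:]])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  vapply(seq_len(length(tokens) - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "␟")
  }, character(1))
}

#' Corpus-level BLEU-1..4
#'
#' Clipped n-gram counts are pooled over the corpus; BLEU-k uses uniform
#' weights 1/k over n = 1..k and the standard brevity penalty.
#'
#' @param candidates,references character vectors (one reference per
#'   candidate).
#' @param max_n largest n-gram order (default 4).
#' @return named numeric vector `bleu_1` .. `bleu_4`.
#' @export
bleu_score <- function(candidates, references, max_n = 4L) {
  stopifnot(length(candidates) == length(references))
  match_n <- numeric(max_n)
  total_n <- numeric(max_n)
  cand_len <- 0
  ref_len <- 0
  for (i in seq_along(candidates)) {
    ct <- caption_tokenize(candidates[i])
    rt <- caption_tokenize(references[i])
    cand_len <- cand_len + length(ct)
    ref_len <- ref_len + length(rt)
    for (n in seq_len(max_n)) {
      cg <- table(ngrams(ct, n))
      rg <- table(ngrams(rt, n))
      total_n[n] <- total_n[n] + sum(cg)
      if (length(cg)) {
        shared <- intersect(names(cg), names(rg))
        match_n[n] <- match_n[n] + sum(pmin(cg[shared], rg[shared]))
      }
    }
  }
  p <- ifelse(total_n > 0, match_n / total_n, 0)
  bp <- if (cand_len > ref_len || cand_len == 0) 1 else exp(1 - ref_len / cand_len)
  out <- vapply(seq_len(max_n), function(k) {
    if (any(p[seq_len(k)] == 0)) return(0)
    bp * exp(mean(log(p[seq_len(k)])))
  }, numeric(1))
  stats::setNames(out, paste0("bleu_", seq_len(max_n)))
}

lcs_length <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0 || lb == 0) return(0L)
  prev <- integer(lb + 1L)
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    for (j in seq_len(lb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[lb + 1L]
}

# monotone alignment (index pairs) realising the LCS
lcs_align <- function(a, b) {
  la <- length(a); lb <- length(b)
  L <- matrix(0L, la + 1L, lb + 1L)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L else {
        max(L[i, j + 1L], L[i + 1L, j])
      }
    }
  }
  pairs <- matrix(0L, 0, 2)
  i <- la; j <- lb
  while (i > 0 && j > 0) {
    if (a[i] == b[j]) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  pairs
}

#' Mean sentence-level ROUGE-L (F-measure, beta = 1)
#' @param candidates,references character vectors.
#' @export
rouge_l_score <- function(candidates, references) {
  stopifnot(length(candidates) == length(references))
  f <- vapply(seq_along(candidates), function(i) {
    ct <- caption_tokenize(candidates[i])
    rt <- caption_tokenize(references[i])
    if (length(ct) == 0 || length(rt) == 0) return(0)
    l <- lcs_length(ct, rt)
    if (l == 0) return(0)
    p <- l / length(ct)
    r <- l / length(rt)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f)
}

#' Mean sentence-level METEOR (exact-match variant)
#'
#' Unigram alignment by longest common subsequence (monotone, exact match),
#' F-mean with alpha = 0.9, fragmentation penalty gamma * (chunks/m)^3 with
#' gamma = 0.5.
#' @param candidates,references character vectors.
#' @export
meteor_score <- function(candidates, references) {
  stopifnot(length(candidates) == length(references))
  s <- vapply(seq_along(candidates), function(i) {
    ct <- caption_tokenize(candidates[i])
    rt <- caption_tokenize(references[i])
    if (length(ct) == 0 || length(rt) == 0) return(0)
    al <- lcs_align(ct, rt)
    m <- nrow(al)
    if (m == 0) return(0)
    p <- m / length(ct)
    r <- m / length(rt)
    fmean <- p * r / (0.9 * p + 0.1 * r)
    chunks <- 1L + sum(diff(al[, 1]) != 1L | diff(al[, 2]) != 1L)
    penalty <- 0.5 * (chunks / m)^3
    fmean * (1 - penalty)
  }, numeric(1))
  mean(s)
}

#' Plain CIDEr (tf-idf n-gram consensus, n = 1..4, scaled by 10)
#'
#' Document frequencies come from the reference corpus; each candidate is
#' scored by the average cosine similarity between its tf-idf n-gram vector
#' and its reference's, over n = 1..4, times 10.
#' @param candidates,references character vectors.
#' @param max_n largest n-gram order.
#' @export
cider_score <- function(candidates, references, max_n = 4L) {
  stopifnot(length(candidates) == length(references))
  N <- length(references)
  ref_tokens <- lapply(references, caption_tokenize)
  cand_tokens <- lapply(candidates, caption_tokenize)
  sims <- matrix(0, N, max_n)
  for (n in seq_len(max_n)) {
    ref_grams <- lapply(ref_tokens, ngrams, n = n)
    df <- table(unlist(lapply(ref_grams, unique)))
    idf <- log(N / pmax(1, as.numeric(df)))
    names(idf) <- names(df)
    tfidf <- function(grams) {
      if (length(grams) == 0) return(numeric(0))
      tf <- table(grams) / length(grams)
      w <- ifelse(names(tf) %in% names(idf), idf[names(tf)], log(N))
      stats::setNames(as.numeric(tf) * w, names(tf))
    }
    for (i in seq_len(N)) {
      gc_ <- tfidf(ngrams(cand_tokens[[i]], n))
      gr_ <- tfidf(ref_grams[[i]])
      if (length(gc_) == 0 || length(gr_) == 0) next
      shared <- intersect(names(gc_), names(gr_))
      num <- sum(gc_[shared] * gr_[shared])
      den <- sqrt(sum(gc_^2)) * sqrt(sum(gr_^2))
      sims[i, n] <- if (den > 0) num / den else 0
    }
  }
  10 * mean(rowMeans(sims))
}

#' All caption metrics for a single-reference corpus
#'
#' @param candidates generated report texts.
#' @param references ground-truth report texts (one per candidate).
#' @return one-row tibble: `bleu_1..4`, `rouge_l`, `meteor`, `cider`
#'   (fractions; CIDEr in [0, 10]).  Empty candidates score 0 with a warning.
#' @export
caption_metrics <- function(candidates, references) {
  if (any(!nzchar(trimws(candidates)))) {
    warning("empty candidate report(s): scored 0")
  }
  b <- bleu_score(candidates, references)
  tibble::tibble(
    bleu_1 = b[["bleu_1"]], bleu_2 = b[["bleu_2"]],
    bleu_3 = b[["bleu_3"]], bleu_4 = b[["bleu_4"]],
    rouge_l = rouge_l_score(candidates, references),
    meteor = meteor_score(candidates, references),
    cider = cider_score(candidates, references)
  )
}
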