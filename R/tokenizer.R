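# Report tokenization.  The decoder interface assumes a GPT-2-sized
# 50,257-id space with `<|endoftext|>` (id 50256) serving as both BOS and
# EOS.  The built-in tokenizer is byte-level: UTF-8 bytes map to ids 0..255
# and the remaining ids are unused, which keeps the vocabulary contract of
# the decoder while remaining fully self-contained.  A user-supplied
# vocabulary JSON (token string -> id) can override the byte mapping for
# whole-word schemes.

GPT2_VOCAB_SIZE <- 50257L
GPT2_EOT_ID <- 50256L

#' Construct a report tokenizer
#'
#' @param vocab_size total id space (default 50,257; both languages share it).
#' @param vocab_file optional path to a JSON object mapping token strings to
#'   integer ids; when given, text is tokenized by greedy longest-match over
#'   that vocabulary with byte fallback.
#' @return object of class `report_tokenizer` with `$encode(text)` /
#'   `$decode(ids)` closures, `$vocab_size`, `$eot_id`.
#' @export
report_tokenizer <- function(vocab_size = GPT2_VOCAB_SIZE, vocab_file = NULL) {
  eot_id <- vocab_size - 1L
  vocab <- NULL
  if (!is.null(vocab_file)) {
    vocab <- unlist(jsonlite::read_json(vocab_file))
    if (any(vocab >= vocab_size)) stop("vocab ids exceed vocab_size")
  }
  encode <- function(text) {
    if (is.null(vocab)) {
      as.integer(charToRaw(enc2utf8(text)))
    } else {
      ids <- integer(0)
      rest <- enc2utf8(text)
      toks <- names(vocab)[order(-nchar(names(vocab)))]
      while (nzchar(rest)) {
        hit <- toks[startsWith(rest, toks)][1]
        if (is.na(hit)) {
          ids <- c(ids, as.integer(charToRaw(substr(rest, 1, 1))))
          rest <- substr(rest, 2, nchar(rest))
        } else {
          ids <- c(ids, as.integer(vocab[[hit]]))
          rest <- substr(rest, nchar(hit) + 1, nchar(rest))
        }
      }
      ids
    }
  }
  decode <- function(ids) {
    ids <- ids[ids != eot_id]
    if (is.null(vocab)) {
      if (any(ids > 255)) ids <- ids[ids <= 255]
      rawToChar(as.raw(ids))
    } else {
      inv <- stats::setNames(names(vocab), vocab)
      paste(ifelse(
        as.character(ids) %in% names(inv),
        inv[as.character(ids)],
        vapply(ids, function(i) rawToChar(as.raw(i)), character(1))
      ), collapse = "")
    }
  }
  structure(
    list(encode = encode, decode = decode,
         vocab_size = as.integer(vocab_size), eot_id = as.integer(eot_id)),
    class = "report_tokenizer"
  )
}

#' Tokenize a report into a training sample
#'
#' Wraps the token ids in BOS/EOS (`<|endoftext|>` serves as both) and
#' truncates to `max_len`.
#'
#' @param text report text (typically the filtered parenchyma section).
#' @param tokenizer a [report_tokenizer()].
#' @param max_len maximum sequence length including the special tokens.
#' @param language `"TR"` or `"EN"`.
#' @return object of class `report_sample`: list(token_ids, language, text).
#' @export
tokenize_report <- function(text, tokenizer, max_len = 128L, language = "TR") {
  ids <- c(tokenizer$eot_id, tokenizer$encode(text), tokenizer$eot_id)
  if (length(ids) > max_len) ids <- c(ids[seq_len(max_len - 1L)], tokenizer$eot_id)
  structure(
    list(token_ids = as.integer(ids), language = language, text = text),
    class = "report_sample"
  )
}
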