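# Lung-window display mapping, bilinear resizing, 5-slice stacking and
# parenchyma-sentence filtering: everything between a raw HU volume / raw
# report and the model-ready tensors.

#' Display window parameters
#'
#' Defaults are the standard lung parenchyma window: width 1500 HU, level
#' -600 HU.
#' @param width window width in HU (> 0).
#' @param level window level (centre) in HU.
#' @export
window_params <- function(width = 1500, level = -600) {
  if (width <= 0) stop("window width must be > 0")
  structure(list(width = width, level = level), class = "window_params")
}

#' Map HU values to 8-bit display values
#'
#' Linear map of `[level - width/2, level + width/2]` onto `[0, 255]`,
#' clamped outside, rounded half-to-even (monotone nondecreasing in HU).
#'
#' @param volume numeric array of HU values (any shape).
#' @param params a [window_params()].
#' @return integer array of the same shape with values in 0..255.
#' @export
apply_window <- function(volume, params = window_params()) {
  if (!all(is.finite(volume))) stop("HU values must be finite")
  lo <- params$level - params$width / 2
  x <- (volume - lo) / params$width * 255
  x <- pmin(pmax(x, 0), 255)
  out <- as.integer(round(x)) # round() is round-half-even in R
  if (!is.null(dim(volume))) dim(out) <- dim(volume)
  out
}

#' Bilinear resize of a 2-D matrix
#'
#' Half-pixel-centre sampling convention (no corner alignment, no antialias
#' filter), pinned for reproducibility of cached fixtures.  Implemented as
#' two interpolation-matrix multiplications.
#'
#' @param img numeric matrix.
#' @param out_rows,out_cols target size.
#' @return `out_rows` x `out_cols` numeric matrix.
#' @export
resize_bilinear <- function(img, out_rows, out_cols) {
  interp_matrix <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    i0 <- floor(src)
    w1 <- src - i0
    i0 <- as.integer(i0) + 1L
    i1 <- pmin(i0 + 1L, n_in)
    M <- matrix(0, n_out, n_in)
    M[cbind(seq_len(n_out), i0)] <- M[cbind(seq_len(n_out), i0)] + (1 - w1)
    M[cbind(seq_len(n_out), i1)] <- M[cbind(seq_len(n_out), i1)] + w1
    M
  }
  R <- interp_matrix(out_rows, nrow(img))
  Cm <- interp_matrix(out_cols, ncol(img))
  R %*% img %*% t(Cm)
}

#' Build a model-ready 5-slice stack
#'
#' Each selected slice is windowed to 8 bits, bilinearly resized, and
#' replicated to three identical channels; slice order (cranial to caudal)
#' is preserved.
#'
#' @param volume HU array (slices x rows x cols).
#' @param slice_indices 5 strictly increasing 1-based slice levels.
#' @param params a [window_params()].
#' @param size output side length in pixels (default 224).
#' @param patient_id,label optional identifiers carried on the stack.
#' @return object of class `slice_stack`: list with `pixels`
#'   (5 x size x size x 3 array, values 0..255), `patient_id`, `label`.
#' @export
build_slice_stack <- function(volume, slice_indices, params = window_params(),
                              size = 224L, patient_id = NA_character_,
                              label = NULL) {
  if (length(slice_indices) != 5L) stop("exactly 5 slice indices are required")
  depth <- dim(volume)[1]
  bad <- slice_indices[slice_indices < 1 | slice_indices > depth]
  if (length(bad) > 0) {
    stop(sprintf(
      "slice index out of range: %s (volume depth %d)",
      paste(bad, collapse = ", "), depth
    ))
  }
  pixels <- array(0, dim = c(5L, size, size, 3L))
  for (i in seq_len(5L)) {
    sl <- apply_window(volume[slice_indices[i], , ], params)
    rs <- resize_bilinear(matrix(as.numeric(sl), nrow(sl), ncol(sl)), size, size)
    for (ch in 1:3) pixels[i, , , ch] <- rs
  }
  structure(
    list(pixels = pixels, patient_id = patient_id, label = label,
         slice_indices = as.integer(slice_indices), size = as.integer(size)),
    class = "slice_stack"
  )
}

#' Model-side scaling of a slice stack
#'
#' Divides by 255 then standardises per channel with the pretrained
#' backbone's published statistics (ImageNet defaults), both configurable.
#'
#' @param stack a [build_slice_stack()] result.
#' @param mean,sd per-channel statistics.
#' @return the stack with `pixels` replaced by standardised values.
#' @export
scale_stack <- function(stack,
                        mean = c(0.485, 0.456, 0.406),
                        sd = c(0.229, 0.224, 0.225)) {
  for (ch in 1:3) {
    stack$pixels[, , , ch] <- (stack$pixels[, , , ch] / 255 - mean[ch]) / sd[ch]
  }
  stack$scaled <- TRUE
  stack
}

#' Extract one section of a tagged report
#'
#' Reports carry machine-readable sentence tags of the form
#' `"[section] sentence."`.  Only sentences of the requested section are
#' kept, in their original order.  A report with no sentence in the section
#' yields an empty result flagged with `found = FALSE` (and a warning), never
#' a silent drop.
#'
#' @param report UTF-8 report text.
#' @param section_tag section name (default `"parenchyma"`).
#' @param language `"TR"` or `"EN"`, carried through for bookkeeping.
#' @return object of class `filtered_report`: list(sentences, language, found).
#' @export
filter_report <- function(report, section_tag = "parenchyma", language = "TR") {
  if (!nzchar(report)) stop("report must be non-empty")
  m <- gregexpr("\\[([a-z]+)\\]\\s*([^\\[]*)", report)
  pieces <- regmatches(report, m)[[1]]
  tags <- gsub("^\\[([a-z]+)\\].*$", "\\1", pieces)
  sents <- trimws(gsub("^\\[[a-z]+\\]\\s*", "", pieces))
  keep <- tags == section_tag
  if (!any(keep)) {
    warning(sprintf("no '[%s]' section found in report", section_tag))
    return(structure(
      list(sentences = character(0), language = language, found = FALSE),
      class = "filtered_report"
    ))
  }
  structure(
    list(sentences = sents[keep], language = language, found = TRUE),
    class = "filtered_report"
  )
}
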