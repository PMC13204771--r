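# Slice-wise Grad-CAM for the ViT encoder, plus quantitative saliency
# validation against lesion bounding boxes (IoU, Dice, Pointing Game).
#
# The attribution target is the class logit y_c.  For every slice, the
# gradient of y_c with respect to each head's attention probabilities in the
# FINAL encoder block is computed by backpropagation through the
# classification head and both LQAP pools; the CLS-query row over the patch
# tokens provides the spatial map A_k.  Head weights are the spatial mean of
# the gradient (alpha_k = 1/Z sum_uv dy_c/dA_uv), the combined map is
# ReLU(sum_k alpha_k A_k), reshaped row-major to the patch grid, bilinearly
# upsampled and min-max normalised per slice.

#' Slice-wise Grad-CAM saliency maps
#'
#' @param model a [lungformer_model()].
#' @param pixels standardised (5 x side x side x 3) pixel array.
#' @param target_class 1-based class index (1 Normal, 2 SCLC, 3 NSCLC).
#' @param out_size upsampled map side length (default 224).
#' @return list of 5 objects of class `saliency_map`, one per slice, each
#'   with `raw_map` (patch-grid matrix, nonnegative), `upsampled`
#'   (out_size x out_size in [0, 1]), `class_index`, `slice_index`, and a
#'   `degenerate` flag for constant maps.
#' @export
grad_cam <- function(model, pixels, target_class, out_size = 224L) {
  cfg <- model$config
  p <- model$params
  if (target_class < 1 || target_class > 3) {
    stop(sprintf("target class %s out of range 1..3", target_class))
  }
  fwd <- model_forward(model, pixels,
    training = FALSE, keep_cache = TRUE, keep_attn = TRUE
  )
  # d y_c / d logits is the one-hot direction, then back through head & pools
  dlogits <- numeric(3)
  dlogits[target_class] <- 1
  hb <- head_bwd(p$head, fwd$cache$head$cache, dlogits)
  pb <- lqap_bwd(p$lqap_patient, fwd$cache$pat$cache, matrix(hb$dz, 1),
                 cfg$lqap_patient)
  lb <- lqap_bwd(p$lqap_latent, fwd$cache$lat$cache, pb$dtokens,
                 cfg$lqap_latent)
  dslices <- split_slices(lb$dtokens)

  g <- cfg$encoder$image_size %/% cfg$encoder$patch_size
  final_layer <- cfg$encoder$layers
  maps <- vector("list", cfg$n_slices)
  for (i in seq_len(cfg$n_slices)) {
    eb <- encoder_bwd(p$encoder, fwd$cache$encs[[i]], fwd$cache$embeds[[i]],
      dslices[[i]], cfg$encoder, capture_dP_layer = final_layer
    )
    P <- fwd$cache$encs[[i]]$caches[[final_layer]]$at$cache$P
    raw <- numeric(cfg$encoder$n_patches)
    for (k in seq_along(P)) {
      A_k <- P[[k]][1, -1] # CLS-query row over the patch tokens
      alpha_k <- mean(eb$dP[[k]][1, -1])
      raw <- raw + alpha_k * A_k
    }
    raw <- pmax(raw, 0)
    raw_map <- matrix(raw, g, g, byrow = TRUE) # row-major patch order
    up <- resize_bilinear(raw_map, out_size, out_size)
    rng <- range(up)
    degenerate <- diff(rng) <= .Machine$double.eps
    up <- if (degenerate) up * 0 else (up - rng[1]) / diff(rng)
    maps[[i]] <- structure(
      list(raw_map = raw_map, upsampled = up, class_index = target_class,
           slice_index = i, degenerate = degenerate),
      class = "saliency_map"
    )
  }
  maps
}

#' Binarise the top activation quantile of a saliency map
#'
#' The mask is `TRUE` exactly where the map reaches the `(1 - fraction)`
#' quantile of its values (ties included).  A constant map yields an empty
#' mask flagged as degenerate.
#'
#' @param map numeric matrix.
#' @param fraction upper activation fraction (default 0.20).
#' @return logical matrix with attribute `degenerate`.
#' @export
binarize_top_quantile <- function(map, fraction = 0.20) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (diff(range(map)) <= .Machine$double.eps) {
    warning("constant saliency map: empty mask")
    mask <- map > Inf
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  thr <- stats::quantile(map, 1 - fraction, names = FALSE)
  mask <- map >= thr
  attr(mask, "degenerate") <- FALSE
  mask
}

#' Rescale a volume-frame bounding box to the model frame
#'
#' Linear coordinate scaling with floor/ceiling so the scaled box covers at
#' least the original extent.  Boxes are 1-based inclusive
#' `(row0, col0, row1, col1)`.
#'
#' @param box numeric length-4 vector.
#' @param from_rows,from_cols source frame size.
#' @param to_size target frame side length (default 224).
#' @export
rescale_box <- function(box, from_rows, from_cols, to_size = 224L) {
  sr <- to_size / from_rows
  sc <- to_size / from_cols
  c(
    row0 = max(1, floor((box[[1]] - 1) * sr) + 1),
    col0 = max(1, floor((box[[2]] - 1) * sc) + 1),
    row1 = min(to_size, ceiling(box[[3]] * sr)),
    col1 = min(to_size, ceiling(box[[4]] * sc))
  )
}

box_to_mask <- function(box, n_rows, n_cols) {
  m <- matrix(FALSE, n_rows, n_cols)
  m[box[[1]]:box[[3]], box[[2]]:box[[4]]] <- TRUE
  m
}

# first maximal pixel in row-major order
argmax_rowmajor <- function(map) {
  mx <- max(map)
  hits <- which(map == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  hits[1, ]
}

#' Saliency localisation scores for one slice
#'
#' IoU and Dice between the binarised saliency mask and the annotation box,
#' and the Pointing Game hit (is the single highest-activation pixel inside
#' the box, first maximal pixel in row-major order).
#'
#' @param mask logical saliency mask (e.g. [binarize_top_quantile()]).
#' @param box 1-based inclusive `(row0, col0, row1, col1)` in the mask frame.
#' @param map the continuous saliency map (for the pointing game).
#' @return one-row tibble `(iou, dice, pointing_hit, mask_px, box_px)`.
#' @export
saliency_scores <- function(mask, box, map) {
  if (is.null(box) || box[[3]] < box[[1]] || box[[4]] < box[[2]]) {
    stop("annotation box is empty")
  }
  bm <- box_to_mask(box, nrow(mask), ncol(mask))
  inter <- sum(mask & bm)
  uni <- sum(mask | bm)
  iou <- if (uni == 0) 0 else inter / uni
  dice <- if (sum(mask) + sum(bm) == 0) 0 else 2 * inter / (sum(mask) + sum(bm))
  pk <- argmax_rowmajor(map)
  hit <- pk[1] >= box[[1]] && pk[1] <= box[[3]] &&
    pk[2] >= box[[2]] && pk[2] <= box[[4]]
  tibble::tibble(
    iou = iou, dice = dice, pointing_hit = hit,
    mask_px = sum(mask), box_px = sum(bm)
  )
}

#' Per-slice saliency validation for one patient
#'
#' Runs [grad_cam()] for the patient's (true or predicted) class, binarises
#' the top-20% activation of each slice map, rescales that slice's lesion
#' box into the map frame and scores the overlap.
#'
#' @param model a [lungformer_model()].
#' @param patient a `synthetic_patient` with lesion boxes.
#' @param stack the patient's standardised [build_slice_stack()]
#'   (built at `out_size`).
#' @param target_class 1-based class; defaults to the patient's label.
#' @param fraction binarisation fraction.
#' @param out_size map frame size.
#' @return tibble with one row per annotated slice.
#' @export
saliency_validate <- function(model, patient, stack,
                              target_class = match(patient$label, CLASS_LEVELS),
                              fraction = 0.20, out_size = stack$size) {
  maps <- grad_cam(model, stack$pixels, target_class, out_size = out_size)
  rows <- list()
  vr <- dim(patient$volume)[2]
  vc <- dim(patient$volume)[3]
  for (i in seq_along(maps)) {
    box <- patient$boxes[[i]]
    if (is.null(box)) next
    rb <- rescale_box(box, vr, vc, out_size)
    mask <- suppressWarnings(binarize_top_quantile(maps[[i]]$upsampled, fraction))
    sc <- saliency_scores(mask, rb, maps[[i]]$upsampled)
    rows[[length(rows) + 1L]] <- dplyr::mutate(sc,
      patient_id = patient$patient_id, label = patient$label, slice = i,
      .before = 1
    )
  }
  dplyr::bind_rows(rows)
}

#' Cohort-level saliency summary (per class and overall)
#'
#' @param scores tibble from [saliency_validate()] rows.
#' @return tibble with per-class and overall mean +- SD IoU/Dice and
#'   pointing-game accuracy (%), in the standard layout.
#' @export
saliency_summary <- function(scores) {
  summarise_one <- function(df, cls) {
    tibble::tibble(
      class = cls, n_slices = nrow(df),
      iou_mean = mean(df$iou), iou_sd = stats::sd(df$iou),
      dice_mean = mean(df$dice), dice_sd = stats::sd(df$dice),
      pointing_accuracy = 100 * mean(df$pointing_hit)
    )
  }
  per_class <- dplyr::bind_rows(lapply(
    split(scores, scores$label), function(df) summarise_one(df, df$label[1])
  ))
  dplyr::bind_rows(per_class, summarise_one(scores, "Overall"))
}

#' Raster plot of a saliency map
#' @param object a `saliency_map`.
#' @param ... unused.
#' @export
autoplot.saliency_map <- function(object, ...) {
  df <- expand.grid(
    row = seq_len(nrow(object$upsampled)),
    col = seq_len(ncol(object$upsampled))
  )
  df$value <- as.vector(object$upsampled)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Slice %d saliency (class %d)",
                      object$slice_index, object$class_index),
      fill = "activation"
    ) +
    ggplot2::theme_minimal()
}
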