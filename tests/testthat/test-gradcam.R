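# Grad-CAM saliency maps and quantitative localisation metrics.

test_that("one nonnegative, normalised saliency map is produced per slice", {
  model <- tiny_model(seed = 2L)
  px <- rand_pixels(9L)
  maps <- grad_cam(model, px, 2L, out_size = 64L)
  expect_length(maps, 5L)
  for (m in maps) {
    expect_identical(dim(m$raw_map), c(2L, 2L))
    expect_gte(min(m$raw_map), 0)
    expect_identical(dim(m$upsampled), c(64L, 64L))
    expect_gte(min(m$upsampled), 0)
    expect_lte(max(m$upsampled), 1)
    if (!m$degenerate) {
      expect_equal(min(m$upsampled), 0)
      expect_equal(max(m$upsampled), 1)
    }
  }
  expect_error(grad_cam(model, px, 4L), "out of range")
})

test_that("a constant-logit head (zero gradient) yields all-zero raw maps", {
  model <- tiny_model(seed = 2L)
  model$params$head$fc2$W[] <- 0
  model$params$head$fc2$b[] <- 0
  maps <- grad_cam(model, rand_pixels(10L), 1L, out_size = 32L)
  for (m in maps) {
    expect_true(all(m$raw_map == 0))
    expect_true(m$degenerate)
  }
})

test_that("top-quantile binarisation matches a sorting oracle with ties included", {
  # 80 zeros and 20 ones at fraction 0.2: the mask is exactly the ones
  map <- matrix(c(rep(0, 80), rep(1, 20)), 10, 10)
  mask <- binarize_top_quantile(map, 0.2)
  expect_identical(unname(which(mask)), unname(which(map == 1)))
  # near-1 fraction approaches the full mask (at most one excluded pixel)
  near_full <- binarize_top_quantile(map + runif(100) * 0.01, 0.999)
  expect_gte(sum(near_full), 99)
  # random continuous map: mask fraction within a one-pixel tie slack
  set.seed(15)
  for (i in 1:5) {
    m <- matrix(runif(64 * 64), 64, 64)
    msk <- binarize_top_quantile(m, 0.2)
    frac <- sum(msk) / length(msk)
    expect_gte(frac, 0.2 - 1 / length(msk))
    expect_lte(frac, 0.2 + 2 / length(msk))
    # sorting oracle: every selected pixel is at least as large as every excluded one
    expect_gte(min(m[msk]), max(m[!msk]) - 1e-12)
  }
  expect_warning(cm <- binarize_top_quantile(matrix(3, 4, 4)), "constant")
  expect_false(any(cm))
  expect_true(attr(cm, "degenerate"))
  expect_error(binarize_top_quantile(matrix(1:4, 2), 1.2), "fraction")
})

test_that("overlap scores match pixel-count oracles", {
  full <- matrix(FALSE, 10, 10)
  full[3:4, 3:4] <- TRUE
  box <- c(3, 3, 4, 4)
  s <- saliency_scores(full, box, full * 1)
  expect_equal(s$iou, 1)
  expect_equal(s$dice, 1)
  expect_true(s$pointing_hit)
  # disjoint mask and box
  far <- matrix(FALSE, 10, 10)
  far[8:9, 8:9] <- TRUE
  s2 <- saliency_scores(far, box, far * 1)
  expect_equal(s2$iou, 0)
  expect_equal(s2$dice, 0)
  expect_false(s2$pointing_hit)
  # 2x2 mask overlapping a 2x2 box on 2 pixels: |n| = 2, |u| = 6
  m3 <- matrix(FALSE, 10, 10)
  m3[3:4, 2:3] <- TRUE
  s3 <- saliency_scores(m3, c(3, 3, 4, 4), m3 * 1)
  expect_equal(s3$iou, 1 / 3)
  expect_equal(s3$dice, 1 / 2)
  expect_error(saliency_scores(full, c(5, 5, 4, 4), full * 1), "empty")
})

test_that("Dice equals 2 IoU / (1 + IoU) for random mask/box pairs", {
  set.seed(16)
  for (i in 1:20) {
    mask <- matrix(runif(400) < 0.3, 20, 20)
    r <- sort(sample(20, 2)); cc <- sort(sample(20, 2))
    s <- saliency_scores(mask, c(r[1], cc[1], r[2], cc[2]),
                         matrix(runif(400), 20, 20))
    expect_equal(s$dice, 2 * s$iou / (1 + s$iou), tolerance = 1e-12)
  }
})

test_that("the pointing game uses the first maximal pixel in row-major order", {
  map <- matrix(0, 5, 5)
  map[2, 4] <- 1
  map[4, 1] <- 1 # tie; row-major first is (2, 4)
  mask <- map > 0
  hit <- saliency_scores(mask, c(2, 4, 2, 4), map)
  expect_true(hit$pointing_hit)
  miss <- saliency_scores(mask, c(4, 1, 4, 1), map)
  expect_false(miss$pointing_hit)
})

test_that("box rescaling covers the original extent", {
  rb <- rescale_box(c(10, 20, 15, 30), 48, 48, 224)
  expect_gte(rb[["row0"]], 1)
  expect_lte(rb[["row1"]], 224)
  # inverse-mapping the scaled corners recovers at least the source box
  expect_lte((rb[["row0"]] - 1) * 48 / 224, 10 - 1 + 1e-9)
  expect_gte(rb[["row1"]] * 48 / 224, 15 - 1e-9)
  expect_identical(unname(rescale_box(c(1, 1, 48, 48), 48, 48, 224)),
                   c(1, 1, 224, 224))
})

test_that("cohort-level saliency aggregation equals a brute-force recomputation", {
  model <- tiny_model(seed = 3L)
  spec <- small_cohort_spec(n_per_class = c(0, 2, 2), seed = 61L)
  rows <- list()
  for (p in generate_cohort(spec)) {
    st <- scale_stack(build_slice_stack(p$volume, p$slice_indices, size = 32L,
                                        patient_id = p$patient_id))
    rows[[length(rows) + 1L]] <- saliency_validate(model, p, st)
  }
  scores <- dplyr::bind_rows(rows)
  expect_gt(nrow(scores), 0)
  summ <- saliency_summary(scores)
  overall <- summ[summ$class == "Overall", ]
  expect_equal(overall$iou_mean, mean(scores$iou), tolerance = 1e-12)
  expect_equal(overall$dice_sd, sd(scores$dice), tolerance = 1e-12)
  expect_equal(overall$pointing_accuracy, 100 * mean(scores$pointing_hit),
               tolerance = 1e-12)
  sclc <- summ[summ$class == "SCLC", ]
  expect_equal(sclc$iou_mean, mean(scores$iou[scores$label == "SCLC"]),
               tolerance = 1e-12)
  expect_s3_class(autoplot(grad_cam(model, rand_pixels(1L), 1L, 32L)[[1]]),
                  "ggplot")
})
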