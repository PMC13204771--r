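# Synthetic cohort generator: determinism, class-conditional lesion
# morphology, box validity, report templating, and learnable class signal.

test_that("generation is deterministic and order-independent", {
  spec <- small_cohort_spec(seed = 21L)
  a <- generate_patient("SCLC", spec, 3)
  b <- generate_patient("SCLC", spec, 3)
  expect_identical(a$volume, b$volume)
  expect_identical(a$report_tr, b$report_tr)
  expect_identical(a$boxes, b$boxes)
  # generating other patients in between must not perturb patient 3
  invisible(generate_patient("NSCLC", spec, 1))
  c3 <- generate_patient("SCLC", spec, 3)
  expect_identical(a$volume, c3$volume)

  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(cohort_hash(co1), cohort_hash(co2))
  co3 <- generate_cohort(small_cohort_spec(seed = 22L))
  expect_false(cohort_hash(co1) == cohort_hash(co3))
})

test_that("Normal patients have no lesion and evenly spaced slice levels", {
  spec <- small_cohort_spec()
  p <- generate_patient("Normal", spec, 1)
  expect_true(all(vapply(p$boxes, is.null, logical(1))))
  expect_length(p$slice_indices, 5)
  expect_true(all(diff(p$slice_indices) > 0))
  gaps <- diff(p$slice_indices)
  expect_lte(max(gaps) - min(gaps), 1) # even spacing up to rounding
  expect_true(all(p$slice_indices >= 1 & p$slice_indices <= spec$depth))
})

test_that("lesion morphology is class-conditional", {
  spec <- cohort_spec(n_per_class = c(1, 1, 1), depth = 32, rows = 64,
                      cols = 64, seed = 5L)
  for (i in 1:3) {
    sc <- generate_patient("SCLC", spec, i)
    ctr <- mask_centroid(sc$lesion_mask[sc$slice_indices[3], , ])
    # compact central blob: centroid within the central third of rows/cols
    expect_gt(ctr[1], 64 / 3); expect_lt(ctr[1], 2 * 64 / 3)
    expect_gt(ctr[2], 64 / 3); expect_lt(ctr[2], 2 * 64 / 3)

    ns <- generate_patient("NSCLC", spec, i)
    ctr_n <- mask_centroid(ns$lesion_mask[ns$slice_indices[3], , ])
    # peripheral blob: column centroid in the outer thirds
    expect_true(ctr_n[2] < 64 / 3 || ctr_n[2] > 2 * 64 / 3)
  }
})

test_that("malignant slice levels bracket the maximal-area slice and all boxes have positive area", {
  spec <- small_cohort_spec(n_per_class = c(0, 4, 4), seed = 31L)
  for (p in generate_cohort(spec)) {
    areas <- apply(p$lesion_mask, 1, sum)
    idx <- which.max(areas)
    expect_true(idx %in% p$slice_indices)
    expect_true(all(diff(p$slice_indices) == 1))
    for (k in seq_len(5)) {
      b <- p$boxes[[k]]
      expect_false(is.null(b))
      expect_gt((b[["row1"]] - b[["row0"]] + 1) * (b[["col1"]] - b[["col0"]] + 1), 0)
      expect_true(all(b >= 1))
      expect_lte(b[["row1"]], spec$rows)
      expect_lte(b[["col1"]], spec$cols)
    }
  }
})

test_that("volumes are integer HU within the 12-bit CT range", {
  p <- generate_patient("NSCLC", small_cohort_spec(), 1)
  expect_true(is.integer(p$volume))
  expect_gte(min(p$volume), -1024)
  expect_lte(max(p$volume), 3071)
  expect_identical(dim(p$volume), c(16L, 48L, 48L))
  # background is lung parenchyma around -800 HU
  bg <- p$volume[1, , ]
  expect_lt(abs(mean(bg) + 800), 30)
})

test_that("cohorts have the requested composition and unique ids", {
  spec <- small_cohort_spec(n_per_class = c(3, 2, 1))
  co <- generate_cohort(spec)
  labels <- vapply(co, `[[`, character(1), "label")
  expect_identical(unname(table(factor(labels, c("Normal", "SCLC", "NSCLC")))),
                   table(factor(c(rep("Normal", 3), rep("SCLC", 2), "NSCLC"),
                                c("Normal", "SCLC", "NSCLC"))) |> unname())
  ids <- vapply(co, `[[`, character(1), "patient_id")
  expect_false(any(duplicated(ids)))
  expect_length(generate_cohort(small_cohort_spec(n_per_class = c(0, 0, 0))), 0)
})

test_that("reports follow the eight-sentence tagged template and match the blob", {
  p <- generate_patient("SCLC", small_cohort_spec(), 2)
  for (rep_text in c(p$report_tr, p$report_en)) {
    tags <- regmatches(rep_text, gregexpr("\\[[a-z]+\\]", rep_text))[[1]]
    expect_length(tags, 8)
    expect_identical(tags[6], "[parenchyma]")
  }
  # the size slot equals the rendered long axis on the index slice
  size_in_report <- as.integer(sub(".* ([0-9]+) mm.*", "\\1", p$report_en))
  expect_identical(size_in_report, as.integer(p$lesion_size_mm))
  areas <- apply(p$lesion_mask, 1, sum)
  bx <- p$boxes[[which(p$slice_indices == which.max(areas))]]
  expect_identical(
    as.integer(max(bx[["row1"]] - bx[["row0"]], bx[["col1"]] - bx[["col0"]]) + 1),
    as.integer(p$lesion_size_mm)
  )
  # Normal parenchyma sentence reports a clear parenchyma
  n <- generate_patient("Normal", small_cohort_spec(), 1)
  expect_match(filter_report(n$report_en, "parenchyma")$sentences, "no focal lesion")
})

test_that("generator encodes a learnable class signal (mean-intensity probe)", {
  spec <- cohort_spec(n_per_class = c(30, 15, 15), depth = 16, rows = 48,
                      cols = 48, seed = 101L)
  co <- generate_cohort(spec)
  feat <- vapply(co, function(p) {
    mean(apply_window(p$volume[p$slice_indices, , ]))
  }, numeric(1))
  malignant <- vapply(co, `[[`, character(1), "label") != "Normal"
  fit <- suppressWarnings(stats::glm(malignant ~ feat, family = stats::binomial()))
  acc <- mean((stats::predict(fit, type = "response") > 0.5) == malignant)
  expect_gt(acc, 0.9)
})

test_that("degenerate dimensions are rejected explicitly", {
  expect_error(generate_patient("SCLC", cohort_spec(depth = 5, rows = 12,
                                                    cols = 12), 1),
               "too small")
  expect_error(generate_patient("Normal", cohort_spec(depth = 3), 1),
               ">= 5 slices")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(n_per_class = c(1, 2)), "three")
})

test_that("cohorts round-trip through the on-disk format", {
  co <- generate_cohort(small_cohort_spec(n_per_class = c(1, 1, 1)))
  dir <- tempfile("cohort_io_")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  ids_in <- sort(vapply(co, `[[`, character(1), "patient_id"))
  ids_out <- sort(vapply(back, `[[`, character(1), "patient_id"))
  expect_identical(ids_in, ids_out)
  names(back) <- vapply(back, `[[`, character(1), "patient_id")
  for (p in co) {
    q <- back[[p$patient_id]]
    expect_identical(q$volume, p$volume)
    expect_identical(q$slice_indices, p$slice_indices)
    expect_identical(q$report_tr, p$report_tr)
    expect_equal(q$boxes, p$boxes)
  }
  unlink(dir, recursive = TRUE)
})
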