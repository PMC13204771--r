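# Lung-window mapping, bilinear resize, slice stacking and report filtering.

test_that("lung window maps HU boundaries and centre as specified", {
  wp <- window_params() # width 1500, level -600
  expect_identical(apply_window(-1350, wp), 0L) # lower clamp boundary
  expect_identical(apply_window(150, wp), 255L) # upper clamp boundary
  # centre: (-600 + 1350)/1500 * 255 = 127.5, round-half-even -> 128
  expect_identical(apply_window(-600, wp), 128L)
  expect_identical(apply_window(c(-5000, 5000), wp), c(0L, 255L))
  expect_error(window_params(width = 0), "width")
  expect_error(apply_window(c(0, NA), wp), "finite")
})

test_that("windowing is monotone and clamp-stable", {
  set.seed(3)
  wp <- window_params()
  for (i in 1:50) {
    hu <- sort(runif(2, -2000, 2000))
    out <- apply_window(hu, wp)
    expect_lte(out[1], out[2])
  }
  # clamping the input to the window interval does not change the output
  hu <- runif(1000, -3000, 3000)
  clamped <- pmin(pmax(hu, -1350), 150)
  expect_identical(apply_window(hu, wp), apply_window(clamped, wp))
})

test_that("bilinear resize is exact for identity and constants and preserves range", {
  set.seed(4)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_equal(resize_bilinear(img, 32, 32), img, tolerance = 1e-12)
  const <- matrix(7.5, 10, 10)
  expect_equal(resize_bilinear(const, 224, 224),
               matrix(7.5, 224, 224), tolerance = 1e-12)
  up <- resize_bilinear(img, 224, 224)
  expect_gte(min(up), min(img))
  expect_lte(max(up), max(img))
})

test_that("slice stacks have the contracted shape with replicated channels", {
  p <- generate_patient("SCLC", small_cohort_spec(), 1)
  st <- build_slice_stack(p$volume, p$slice_indices, size = 224L,
                          patient_id = p$patient_id)
  expect_identical(dim(st$pixels), c(5L, 224L, 224L, 3L))
  expect_identical(st$pixels[, , , 1], st$pixels[, , , 2])
  expect_identical(st$pixels[, , , 1], st$pixels[, , , 3])
  expect_gte(min(st$pixels), 0)
  expect_lte(max(st$pixels), 255)
  # constant-HU slice stays constant after windowing + resize
  vol <- array(-600L, dim = c(6, 20, 20))
  st2 <- build_slice_stack(vol, 1:5, size = 64L)
  expect_true(all(st2$pixels == 128))
})

test_that("invalid slice indices are reported by name", {
  p <- generate_patient("Normal", small_cohort_spec(), 1)
  expect_error(build_slice_stack(p$volume, c(1, 2, 3, 4, 99)), "99")
  expect_error(build_slice_stack(p$volume, 1:4), "5 slice indices")
})

test_that("model-side scaling applies the configured channel statistics", {
  vol <- array(150L, dim = c(6, 8, 8)) # windows to 255 everywhere
  st <- scale_stack(build_slice_stack(vol, 1:5, size = 16L))
  expect_equal(st$pixels[1, 1, 1, 1], (1 - 0.485) / 0.229, tolerance = 1e-12)
  expect_equal(st$pixels[1, 1, 1, 3], (1 - 0.406) / 0.225, tolerance = 1e-12)
})

test_that("report filtering keeps exactly the tagged section, preserving order", {
  p <- generate_patient("NSCLC", small_cohort_spec(), 1)
  fr <- filter_report(p$report_en, "parenchyma", "EN")
  expect_true(fr$found)
  expect_length(fr$sentences, 1)
  expect_match(fr$sentences, "lesion")
  # a report equal to its parenchyma section is returned unchanged
  only <- "[parenchyma] Both lung parenchyma are clear with no focal lesion."
  fr2 <- filter_report(only, "parenchyma")
  expect_identical(fr2$sentences,
                   "Both lung parenchyma are clear with no focal lesion.")
  # missing section: flagged empty, not silently dropped
  expect_warning(fr3 <- filter_report(p$report_en, "angiography"), "no")
  expect_false(fr3$found)
  expect_length(fr3$sentences, 0)
  expect_error(filter_report(""), "non-empty")
  # multi-sentence sections are preserved in order
  two <- "[parenchyma] First. [bones] Other. [parenchyma] Second."
  expect_identical(filter_report(two, "parenchyma")$sentences,
                   c("First.", "Second."))
})

test_that("byte-level tokenizer round-trips bilingual text within the GPT-2 id space", {
  tok <- report_tokenizer()
  for (txt in c("Solid lesion, 23 mm.",
                "Santral perihiler akciğer parankimi doğaldır.")) {
    ids <- tok$encode(txt)
    expect_true(all(ids >= 0 & ids < 50257))
    expect_identical(tok$decode(ids), txt)
  }
  s <- tokenize_report("abc", tok, max_len = 10L)
  expect_identical(s$token_ids[1], 50256L)
  expect_identical(s$token_ids[length(s$token_ids)], 50256L)
  long <- tokenize_report(strrep("x", 50), tok, max_len = 10L)
  expect_length(long$token_ids, 10L)
  expect_identical(long$token_ids[10], 50256L) # truncation keeps the EOS
})
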