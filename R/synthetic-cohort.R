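# Seeded synthetic lung-CT cohort generator.  Emulates the statistical
# structure the framework assumes: per-patient HU volumes with
# class-conditional lesion morphology (compact central blob for SCLC-like
# cases, heterogeneous peripheral blob for NSCLC-like cases, none for
# Normal), five selected axial levels, eight-sentence bilingual templated
# reports with a tagged "Lung Parenchyma" sentence, and per-slice lesion
# bounding boxes.  Nothing here claims anatomic realism; the generator
# exists so that every downstream stage is exercisable end to end.

CLASS_LEVELS <- c("Normal", "SCLC", "NSCLC")
HU_MIN <- -1024L
HU_MAX <- 3071L
PARENCHYMA_HU <- -800

#' Specify a synthetic cohort
#'
#' @param n_per_class named integer vector of patients per class in the order
#'   (Normal, SCLC, NSCLC).  The default mirrors a balanced three-class
#'   chest-CT cohort of 767 patients (256/248/263).
#' @param depth,rows,cols volume dimensions (slices x rows x cols).
#' @param lesion_intensity_range HU interval lesion voxels are drawn from.
#' @param noise_sd standard deviation (HU) of parenchymal Gaussian noise.
#' @param spacing_mm in-plane pixel spacing used to convert lesion extent to a
#'   long-axis size in millimetres for the report text.
#' @param seed integer seed; the whole cohort is a pure function of this spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(Normal = 256, SCLC = 248, NSCLC = 263),
                        depth = 24L, rows = 64L, cols = 64L,
                        lesion_intensity_range = c(-20, 80),
                        noise_sd = 25, spacing_mm = 1, seed = 1L) {
  if (length(n_per_class) != 3L || any(n_per_class < 0)) {
    stop("`n_per_class` must give three nonnegative counts (Normal, SCLC, NSCLC)")
  }
  names(n_per_class) <- CLASS_LEVELS
  if (depth < 1 || rows < 1 || cols < 1) stop("volume dimensions must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(
    list(
      n_per_class = as.integer(n_per_class),
      depth = as.integer(depth), rows = as.integer(rows), cols = as.integer(cols),
      lesion_intensity_range = lesion_intensity_range,
      noise_sd = noise_sd, spacing_mm = spacing_mm, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Deterministic per-patient seed below 2^31, a pure function of
# (cohort seed, class, index) so generation order never matters.
patient_seed <- function(seed, label, index) {
  cls <- match(label, CLASS_LEVELS)
  ((as.numeric(seed) %% 2147483647) * 48271 + cls * 1299709 + index * 7919) %%
    2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic patient
#'
#' SCLC-like patients carry one compact, near-homogeneous high-HU blob near
#' the volume centre (a central/hilar analogue); NSCLC-like patients carry an
#' irregular multi-lobed blob near the lateral periphery with internal
#' intensity heterogeneity; Normal patients carry none.  For malignant labels
#' the five selected slice indices bracket the blob's maximal-area slice
#' (index slice +-2); Normal patients get five evenly spaced depths, a
#' stand-in for the anatomy-defined landmark levels used on real data.
#'
#' @param label one of `"Normal"`, `"SCLC"`, `"NSCLC"`.
#' @param spec a [cohort_spec()].
#' @param index nonnegative patient index within the class.
#' @return an object of class `synthetic_patient` with fields `patient_id`,
#'   `label`, `volume` (integer HU array, slices x rows x cols),
#'   `slice_indices` (5 strictly increasing 1-based levels), `report_tr`,
#'   `report_en`, `boxes` (per selected slice, `NULL` or inclusive 1-based
#'   `c(row0, col0, row1, col1)`), `lesion_mask`, and `lesion_size_mm`.
#' @export
generate_patient <- function(label, spec, index) {
  label <- match.arg(label, CLASS_LEVELS)
  stopifnot(inherits(spec, "cohort_spec"), index >= 0)
  d <- spec$depth; r <- spec$rows; cc <- spec$cols
  if (label == "Normal") {
    if (d < 5) stop("volume depth too small: Normal patients need >= 5 slices")
  } else if (d < 7 || r < 24 || cc < 24) {
    stop("volume dimensions too small to place a lesion blob (need depth >= 7, rows/cols >= 24)")
  }

  with_seed(patient_seed(spec$seed, label, index), {
    vol <- PARENCHYMA_HU + stats::rnorm(d * r * cc, 0, spec$noise_sd)
    dim(vol) <- c(d, r, cc)

    if (label == "Normal") {
      slice_idx <- unique(round(seq(1, d, length.out = 5)))
      if (length(slice_idx) < 5) slice_idx <- seq_len(5)
      lesion_mask <- NULL
      boxes <- vector("list", 5L)
      size_mm <- NA_real_
    } else {
      px <- r / 64 # morphology scales with the field of view
      if (label == "SCLC") {
        ctr <- c(
          z = stats::runif(1, 0.45, 0.55) * d,
          x = stats::runif(1, 0.44, 0.56) * r,
          y = stats::runif(1, 0.44, 0.56) * cc
        )
        n_comp <- 1L
        het_sd <- 10
      } else {
        side <- sample(c(0.22, 0.78), 1)
        ctr <- c(
          z = stats::runif(1, 0.40, 0.60) * d,
          x = stats::runif(1, 0.35, 0.65) * r,
          y = (side + stats::runif(1, -0.04, 0.04)) * cc
        )
        n_comp <- 3L
        het_sd <- 40
      }
      ctr["z"] <- min(max(ctr["z"], 3), d - 2)

      # anisotropic Gaussian-smoothed ellipsoid(s); mask = half-max threshold
      zi <- slice.index(vol, 1); xi <- slice.index(vol, 2); yi <- slice.index(vol, 3)
      field <- array(0, dim = c(d, r, cc))
      rx0 <- stats::runif(1, 5, 10) * px
      for (j in seq_len(n_comp)) {
        jit <- if (j == 1L) c(0, 0, 0) else stats::runif(3, -0.6, 0.6) * c(1, rx0, rx0)
        rz <- stats::runif(1, 2.6, 4)
        rx <- rx0 * stats::runif(1, 0.75, 1.05)
        ry <- rx0 * stats::runif(1, 0.6, 1.0)
        d2 <- ((zi - ctr["z"] - jit[1]) / rz)^2 +
          ((xi - ctr["x"] - jit[2]) / rx)^2 +
          ((yi - ctr["y"] - jit[3]) / ry)^2
        field <- pmax(field, exp(-0.5 * d2))
      }
      lesion_mask <- field >= 0.5
      if (!any(lesion_mask)) stop("volume dimensions too small to place a lesion blob")

      base_hu <- stats::runif(
        1, spec$lesion_intensity_range[1], spec$lesion_intensity_range[2]
      )
      lesion_hu <- base_hu + stats::rnorm(length(vol), 0, het_sd)
      w <- pmin(1, field / 0.5)
      w[field < 0.1] <- 0
      vol <- vol + w * (lesion_hu - vol)

      areas <- apply(lesion_mask, 1, sum)
      idx <- which.max(areas)
      lo <- min(max(idx - 2L, 1L), d - 4L)
      slice_idx <- lo + 0:4
      boxes <- lapply(slice_idx, function(s) {
        m <- lesion_mask[s, , ]
        if (!any(m)) return(NULL)
        rr <- range(which(rowSums(m) > 0))
        rc <- range(which(colSums(m) > 0))
        c(row0 = rr[1], col0 = rc[1], row1 = rr[2], col1 = rc[2])
      })
      bx <- boxes[[which(slice_idx == idx)]]
      size_mm <- round(max(bx["row1"] - bx["row0"], bx["col1"] - bx["col0"]) + 1) *
        spec$spacing_mm
    }

    vol <- array(as.integer(round(pmin(pmax(vol, HU_MIN), HU_MAX))), dim = dim(vol))
    reports <- build_reports(label, size_mm, ctr_side(label, spec, boxes, slice_idx))
    structure(
      list(
        patient_id = sprintf("%s_%04d", tolower(label), index),
        label = label,
        volume = vol,
        slice_indices = as.integer(slice_idx),
        report_tr = reports$tr,
        report_en = reports$en,
        boxes = boxes,
        lesion_mask = lesion_mask,
        lesion_size_mm = size_mm
      ),
      class = "synthetic_patient"
    )
  })
}

# laterality of the lesion (by box centroid column) for the report slot
ctr_side <- function(label, spec, boxes, slice_idx) {
  if (label != "NSCLC") return(NA_character_)
  bx <- boxes[[3L]]
  if (is.null(bx)) bx <- boxes[[which(!vapply(boxes, is.null, logical(1)))[1]]]
  mid <- (bx["col0"] + bx["col1"]) / 2
  if (mid < spec$cols / 2) "right" else "left"
}

build_reports <- function(label, size_mm, side) {
  if (label == "Normal") {
    par_tr <- "Her iki akciğer parankimi doğaldır; fokal lezyon izlenmemiştir."
    par_en <- "Both lung parenchyma are clear with no focal lesion."
    imp_tr <- "Patolojik bulgu saptanmamıştır."
    imp_en <- "No pathological finding is identified."
  } else {
    if (label == "SCLC") {
      loc_tr <- "Santral perihiler"; loc_en <- "central perihilar"
      mar_tr <- "düzgün konturlu"; mar_en <- "smooth, well-defined"
    } else {
      loc_tr <- paste("Periferik", if (side == "right") "sağ" else "sol")
      loc_en <- paste("peripheral", side)
      mar_tr <- "spiküle konturlu, düzensiz"; mar_en <- "spiculated, irregular"
    }
    par_tr <- sprintf(
      "%s akciğer parankiminde uzun aksi %d mm olan %s solid lezyon izlendi.",
      loc_tr, as.integer(size_mm), mar_tr
    )
    par_en <- sprintf(
      "In the %s lung parenchyma, a %s solid lesion measuring %d mm in long axis is observed.",
      loc_en, mar_en, as.integer(size_mm)
    )
    imp_tr <- "Tanımlanan bulgular malignite ile uyumlu olabilir; Akciğer CA?"
    imp_en <- "Described findings may be consistent with malignancy; Lung CA?"
  }
  tr <- c(
    "[technique] Toraks BT incelemesi aksiyel planda elde olunmuştur.",
    "[mediastinum] Mediastinal ana vasküler yapılar doğaldır.",
    "[heart] Kalp boyutları normal sınırlardadır.",
    "[pleura] Plevral efüzyon saptanmamıştır.",
    "[airways] Trakea ve ana bronşlar açıktır.",
    paste("[parenchyma]", par_tr),
    "[bones] Kemik yapılarda litik destrüktif lezyon izlenmemiştir.",
    paste("[impression]", imp_tr)
  )
  en <- c(
    "[technique] Axial thoracic CT examination was obtained.",
    "[mediastinum] Main mediastinal vascular structures are unremarkable.",
    "[heart] Cardiac size is within normal limits.",
    "[pleura] No pleural effusion is detected.",
    "[airways] The trachea and main bronchi are patent.",
    paste("[parenchyma]", par_en),
    "[bones] No lytic destructive bone lesion is seen.",
    paste("[impression]", imp_en)
  )
  list(tr = paste(tr, collapse = " "), en = paste(en, collapse = " "))
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of [generate_patient()] results, `n_per_class` per class,
#'   deterministic under the spec's seed.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- list()
  for (k in seq_along(CLASS_LEVELS)) {
    n <- spec$n_per_class[k]
    if (n == 0L) next
    patients <- c(patients, lapply(
      seq_len(n), function(i) generate_patient(CLASS_LEVELS[k], spec, i)
    ))
  }
  patients
}

#' Tidy manifest of a generated cohort
#'
#' @param cohort list of `synthetic_patient` objects.
#' @return a tibble with one row per patient: id, class label, number of
#'   lesion boxes, selected slice levels, lesion long-axis size and mean HU.
#' @export
cohort_manifest <- function(cohort) {
  purrr::map_dfr(cohort, function(p) {
    tibble::tibble(
      patient_id = p$patient_id,
      label = p$label,
      n_boxes = sum(!vapply(p$boxes, is.null, logical(1))),
      slice_indices = paste(p$slice_indices, collapse = ";"),
      lesion_size_mm = p$lesion_size_mm,
      mean_hu = mean(p$volume[p$slice_indices, , ])
    )
  })
}

#' Deterministic content hash of a cohort
#'
#' MD5 over the serialised volumes, reports, boxes and manifest; a pure
#' function of the generating [cohort_spec()].
#' @param cohort list of `synthetic_patient` objects.
#' @return character MD5 digest.
#' @export
cohort_hash <- function(cohort) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  payload <- lapply(cohort, function(p) {
    p[c("patient_id", "label", "volume", "slice_indices",
        "report_tr", "report_en", "boxes")]
  })
  saveRDS(payload, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write a cohort to disk (NIfTI volumes + JSON sidecars + CSV manifest)
#'
#' @param cohort list of `synthetic_patient` objects.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    RNifti::writeNifti(p$volume, file.path(dir, paste0(p$patient_id, ".nii.gz")))
    sidecar <- list(
      patient_id = p$patient_id, label = p$label,
      slice_indices = p$slice_indices,
      report_tr = p$report_tr, report_en = p$report_en,
      boxes = lapply(p$boxes, function(b) if (is.null(b)) NULL else unname(b)),
      lesion_size_mm = p$lesion_size_mm
    )
    jsonlite::write_json(sidecar, file.path(dir, paste0(p$patient_id, ".json")),
      auto_unbox = TRUE, null = "null", na = "null", digits = NA
    )
  }
  utils::write.csv(cohort_manifest(cohort), file.path(dir, "manifest.csv"),
    row.names = FALSE
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing NIfTI volumes and JSON sidecars.
#' @return list of `synthetic_patient` objects (without lesion masks).
#' @export
read_cohort <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  lapply(sidecars, function(f) {
    meta <- jsonlite::read_json(f, simplifyVector = FALSE)
    vol <- RNifti::readNifti(sub("\\.json$", ".nii.gz", f))
    boxes <- lapply(meta$boxes, function(b) {
      b <- unlist(b)
      if (is.null(b) || length(b) == 0) NULL
      else stats::setNames(as.numeric(b), c("row0", "col0", "row1", "col1"))
    })
    structure(
      list(
        patient_id = meta$patient_id, label = meta$label,
        volume = array(as.integer(round(vol)), dim = dim(vol)),
        slice_indices = as.integer(unlist(meta$slice_indices)),
        report_tr = meta$report_tr, report_en = meta$report_en,
        boxes = boxes, lesion_mask = NULL,
        lesion_size_mm = if (is.null(meta$lesion_size_mm)) NA_real_
                         else meta$lesion_size_mm
      ),
      class = "synthetic_patient"
    )
  })
}
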