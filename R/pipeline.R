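# Pipeline orchestration: a single configuration object binds the stages
# (fixtures -> preprocess -> train -> evaluate -> explain), each stage writes
# immutable artifacts into one flat run directory together with a structured
# JSONL log line, and every output is accompanied by the hash of the
# configuration that produced it.

RUN_CONFIG_SCHEMA <- list(
  seed = "integer", profile = "character", run_dir = "character",
  language = "character", fractions = "numeric",
  cohort = list(
    n_per_class = "numeric", depth = "numeric", rows = "numeric",
    cols = "numeric", noise_sd = "numeric"
  ),
  train = list(
    lambda_report = "numeric", max_lr = "numeric", batch_size = "numeric",
    max_epochs = "numeric", max_steps = "numeric",
    early_stop_patience = "numeric"
  )
)

check_keys <- function(x, schema, path = "") {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" under ", path) else "",
                 paste(unknown, collapse = ", ")))
  }
  for (k in names(x)) {
    if (is.list(schema[[k]])) check_keys(x[[k]], schema[[k]], k)
  }
}

#' Build or load a run configuration
#'
#' @param file optional YAML file; explicitly given arguments override it.
#'   Unknown keys are rejected.
#' @param seed run seed (drives cohort generation, splitting and training).
#' @param profile `"tiny"` or `"base"`.
#' @param run_dir output directory for all stage artifacts.
#' @param language `"TR"` or `"EN"` reporting scenario.
#' @param fractions train/val/test split fractions (default 0.7/0.2/0.1).
#' @param cohort,train optional nested overrides (see the YAML schema).
#' @return object of class `run_config`.
#' @export
run_config <- function(file = NULL, seed = 1L, profile = "tiny",
                       run_dir = tempfile("lungformer_run_"),
                       language = "TR", fractions = c(0.7, 0.2, 0.1),
                       cohort = list(), train = list()) {
  cfg <- list(seed = seed, profile = profile, run_dir = run_dir,
              language = language, fractions = fractions,
              cohort = cohort, train = train)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    check_keys(from_file, RUN_CONFIG_SCHEMA)
    cfg <- utils::modifyList(from_file, cfg[!vapply(cfg, is.null, logical(1))])
  }
  check_keys(cfg, RUN_CONFIG_SCHEMA)
  cohort_defaults <- list(n_per_class = c(4, 4, 4), depth = 16, rows = 48,
                          cols = 48, noise_sd = 25)
  train_defaults <- list(lambda_report = 0.3, max_lr = 1e-3, batch_size = 4,
                         max_epochs = 3, max_steps = NULL,
                         early_stop_patience = 5)
  cfg$cohort <- utils::modifyList(cohort_defaults, as.list(cfg$cohort))
  cfg$train <- utils::modifyList(train_defaults, as.list(cfg$train))
  cfg$seed <- as.integer(cfg$seed)
  cfg$profile <- match.arg(cfg$profile, c("tiny", "base"))
  cfg$language <- match.arg(toupper(cfg$language), c("TR", "EN"))
  structure(cfg, class = "run_config")
}

#' Canonical YAML form of a configuration (sorted keys)
#' @param config a [run_config()].
#' @return single YAML string.
#' @export
serialize_config <- function(config) {
  sort_rec <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[order(names(x))]
    lapply(x, sort_rec)
  }
  yaml::as.yaml(sort_rec(unclass(config)))
}

#' Stable hash of a configuration
#' @param config a [run_config()].
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(serialize_config(config), tmp)
  unname(tools::md5sum(tmp))
}

log_stage <- function(config, stage, t0, extra = list()) {
  line <- c(
    list(
      stage = stage, seed = config$seed,
      config_hash = config_hash(config),
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    ),
    extra
  )
  cat(jsonlite::toJSON(line, auto_unbox = TRUE),
    "\n",
    file = file.path(config$run_dir, "pipeline.jsonl"), append = TRUE, sep = ""
  )
}

require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stop(sprintf(
      "stage '%s' requires artifact '%s' produced by stage '%s'; run that stage first",
      needed_by, path, stage
    ))
  }
  path
}

prepare_samples <- function(cohort, config, mcfg) {
  tok <- report_tokenizer(mcfg$decoder$vocab)
  lang_field <- if (config$language == "TR") "report_tr" else "report_en"
  lapply(cohort, function(p) {
    stack <- build_slice_stack(p$volume, p$slice_indices,
      size = mcfg$encoder$image_size, patient_id = p$patient_id,
      label = p$label
    )
    stack <- scale_stack(stack)
    fr <- filter_report(p[[lang_field]], "parenchyma", config$language)
    sample <- tokenize_report(paste(fr$sentences, collapse = " "), tok,
      max_len = mcfg$decoder$max_positions, language = config$language
    )
    list(
      patient_id = p$patient_id, label_name = p$label,
      label = match(p$label, CLASS_LEVELS),
      pixels = stack$pixels, token_ids = sample$token_ids,
      reference_text = sample$text
    )
  })
}

#' Run pipeline stages
#'
#' Stages: `fixtures` (generate and write the synthetic cohort),
#' `preprocess` (stacks + tokenized filtered reports + stratified split),
#' `train` (joint optimisation, checkpoints), `evaluate` (test-split
#' classification and caption metrics), `explain` (Grad-CAM saliency
#' validation on malignant test patients).  Each stage writes its outputs
#' under the run directory and appends a JSONL log line; missing upstream
#' artifacts abort with the name of the stage that produces them.
#'
#' @param config a [run_config()].
#' @param stages ordered subset of
#'   `c("fixtures", "preprocess", "train", "evaluate", "explain")`.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("fixtures", "preprocess", "train",
                                    "evaluate", "explain")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$run_dir, recursive = TRUE, showWarnings = FALSE)
  mcfg <- model_config(config$profile)

  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    if (stage == "fixtures") {
      spec <- cohort_spec(
        n_per_class = config$cohort$n_per_class,
        depth = config$cohort$depth, rows = config$cohort$rows,
        cols = config$cohort$cols, noise_sd = config$cohort$noise_sd,
        seed = config$seed
      )
      cohort <- generate_cohort(spec)
      write_cohort(cohort, file.path(config$run_dir, "fixtures"))
      log_stage(config, stage, t0, list(n_patients = length(cohort)))
    } else if (stage == "preprocess") {
      fx <- require_artifact(file.path(config$run_dir, "fixtures", "manifest.csv"),
                             "fixtures", stage)
      cohort <- read_cohort(file.path(config$run_dir, "fixtures"))
      samples <- prepare_samples(cohort, config, mcfg)
      manifest <- cohort_manifest(cohort)
      split <- stratified_split(manifest[, c("patient_id", "label")],
                                fractions = config$fractions,
                                seed = config$seed)
      saveRDS(samples, file.path(config$run_dir, "samples.rds"))
      utils::write.csv(split, file.path(config$run_dir, "split.csv"),
                       row.names = FALSE)
      log_stage(config, stage, t0, list(
        n_samples = length(samples),
        inputs = unname(tools::md5sum(fx))
      ))
    } else if (stage == "train") {
      sp <- require_artifact(file.path(config$run_dir, "samples.rds"),
                             "preprocess", stage)
      samples <- readRDS(sp)
      split <- utils::read.csv(file.path(config$run_dir, "split.csv"))
      by_id <- stats::setNames(split$split, split$patient_id)
      tr <- samples[vapply(samples, function(s) by_id[[s$patient_id]] == "train",
                           logical(1))]
      va <- samples[vapply(samples, function(s) by_id[[s$patient_id]] == "val",
                           logical(1))]
      model <- lungformer_model(mcfg, seed = config$seed)
      tc <- train_config(
        lambda_report = config$train$lambda_report,
        max_lr = config$train$max_lr,
        batch_size = config$train$batch_size,
        max_epochs = config$train$max_epochs,
        max_steps = config$train$max_steps,
        early_stop_patience = config$train$early_stop_patience,
        seed = config$seed
      )
      fit <- train_lungformer(model, tr, if (length(va)) va else NULL, tc,
        checkpoint_dir = file.path(config$run_dir, "checkpoints")
      )
      utils::write.csv(fit$log, file.path(config$run_dir, "train_log.csv"),
                       row.names = FALSE)
      saveRDS(list(params = fit$model$params, profile = config$profile,
                   language = config$language),
              file.path(config$run_dir, "checkpoints", "model.rds"))
      log_stage(config, stage, t0, list(
        steps = nrow(fit$log), final_loss = fit$log$loss_total[nrow(fit$log)]
      ))
    } else if (stage %in% c("evaluate", "explain")) {
      ck <- require_artifact(
        file.path(config$run_dir, "checkpoints", "model.rds"), "train", stage
      )
      saved <- readRDS(ck)
      model <- lungformer_model(model_config(saved$profile), seed = config$seed)
      model$params <- saved$params
      samples <- readRDS(require_artifact(
        file.path(config$run_dir, "samples.rds"), "preprocess", stage
      ))
      split <- utils::read.csv(file.path(config$run_dir, "split.csv"))
      by_id <- stats::setNames(split$split, split$patient_id)
      te <- samples[vapply(samples, function(s) by_id[[s$patient_id]] == "test",
                           logical(1))]
      if (length(te) == 0) stop("test split is empty")

      if (stage == "evaluate") {
        tok <- report_tokenizer(mcfg$decoder$vocab)
        preds <- lapply(te, function(s) {
          fwd <- model_forward(model, s$pixels, keep_cache = FALSE)
          ids <- generate_report_ids(model$params$decoder, fwd$latent,
                                     mcfg$decoder)
          list(pred = fwd$prediction, text = tok$decode(ids), truth = s$label_name)
        })
        truth <- vapply(preds, `[[`, character(1), "truth")
        predicted <- vapply(preds, function(p) p$pred$predicted_class,
                            character(1))
        cm <- confusion_matrix(truth, predicted)
        mb <- classification_metrics(cm)
        cap <- caption_metrics(
          vapply(preds, `[[`, character(1), "text"),
          vapply(te, `[[`, character(1), "reference_text")
        )
        gen <- tibble::tibble(
          patient_id = vapply(te, `[[`, character(1), "patient_id"),
          language = config$language,
          text = vapply(preds, `[[`, character(1), "text")
        )
        writeLines(
          vapply(seq_len(nrow(gen)), function(i) {
            as.character(jsonlite::toJSON(as.list(gen[i, ]), auto_unbox = TRUE))
          }, character(1)),
          file.path(config$run_dir, "generated_reports.jsonl")
        )
        utils::write.csv(tidy(mb),
          file.path(config$run_dir, "metrics_per_class.csv"), row.names = FALSE)
        metrics <- c(as.list(glance(mb)), as.list(cap))
        jsonlite::write_json(metrics,
          file.path(config$run_dir, "metrics.json"), auto_unbox = TRUE,
          na = "null", digits = NA)
        log_stage(config, stage, t0, list(
          n_test = length(te), accuracy = mb$overall$accuracy
        ))
      } else {
        fx_dir <- file.path(config$run_dir, "fixtures")
        cohort <- read_cohort(fx_dir)
        names(cohort) <- vapply(cohort, `[[`, character(1), "patient_id")
        rows <- list()
        for (s in te) {
          pat <- cohort[[s$patient_id]]
          if (pat$label == "Normal") next
          stack <- list(pixels = s$pixels, size = mcfg$encoder$image_size,
                        patient_id = s$patient_id)
          rows[[length(rows) + 1L]] <-
            saliency_validate(model, pat, stack, target_class = s$label)
        }
        scores <- dplyr::bind_rows(rows)
        utils::write.csv(scores,
          file.path(config$run_dir, "saliency_scores.csv"), row.names = FALSE)
        utils::write.csv(saliency_summary(scores),
          file.path(config$run_dir, "saliency_summary.csv"), row.names = FALSE)
        log_stage(config, stage, t0, list(n_slices = nrow(scores)))
      }
    }
  }
  invisible(config$run_dir)
}
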