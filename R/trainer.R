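# Joint two-task optimisation: patient-level stratified splitting, the
# weighted classification + language-modeling objective, Adam with a
# one-cycle learning-rate schedule (30% warmup then cosine annealing), early
# stopping on validation loss, and checkpointing of the best parameters.

#' Training configuration
#'
#' @param lambda_report weight of the language-modeling loss in
#'   `L_total = L_cls + lambda * L_report` (published value 0.3).
#' @param max_lr one-cycle peak learning rate (published value 1e-4 for the
#'   base profile; tiny-profile smoke runs typically use 1e-3).
#' @param warmup_fraction fraction of total steps spent warming up (0.3).
#' @param div_factor,final_div_factor initial / final learning-rate divisors
#'   of the one-cycle schedule.
#' @param batch_size patients per optimisation step.
#' @param max_epochs epoch cap.
#' @param max_steps optional step cap (overrides epochs; used by smoke runs).
#' @param early_stop_patience non-improving validation epochs tolerated.
#' @param betas,eps,weight_decay Adam hyperparameters.
#' @param seed RNG seed for shuffling and dropout.
#' @export
train_config <- function(lambda_report = 0.3, max_lr = 1e-4,
                         warmup_fraction = 0.3, div_factor = 25,
                         final_div_factor = 1e4, batch_size = 16L,
                         max_epochs = 100L, max_steps = NULL,
                         early_stop_patience = 5L,
                         betas = c(0.9, 0.999), eps = 1e-8,
                         weight_decay = 0, seed = 1L) {
  if (lambda_report < 0) stop("lambda_report must be >= 0")
  if (warmup_fraction <= 0 || warmup_fraction >= 1) {
    stop("warmup_fraction must be in (0, 1)")
  }
  structure(
    list(
      lambda_report = lambda_report, max_lr = max_lr,
      warmup_fraction = warmup_fraction, div_factor = div_factor,
      final_div_factor = final_div_factor, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
      early_stop_patience = as.integer(early_stop_patience),
      betas = betas, eps = eps, weight_decay = weight_decay,
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Joint two-task loss
#' @param l_cls classification cross-entropy.
#' @param l_report language-modeling cross-entropy.
#' @param lambda report weight.
#' @return `l_cls + lambda * l_report`.
#' @export
joint_loss <- function(l_cls, l_report, lambda = 0.3) {
  stopifnot(is.finite(l_cls), is.finite(l_report))
  l_cls + lambda * l_report
}

#' Patient-level stratified train/validation/test split
#'
#' Within each class, `round(n * test)` patients (half-up) go to test,
#' `round(n * val)` to validation, and the remainder to train, assigned by a
#' seeded permutation.  With class counts 256/248/263 and fractions
#' 70/20/10 this yields the canonical 77-patient test set (26/25/26).
#'
#' @param data data frame with at least `patient_id` and `label` columns
#'   (one row per patient), or a bare vector of labels.
#' @param fractions length-3 numeric `(train, val, test)` summing to 1.
#' @param seed permutation seed.
#' @return tibble `(patient_id, label, split)` with
#'   `split in {train, val, test}`.
#' @export
stratified_split <- function(data, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!is.data.frame(data)) {
    data <- tibble::tibble(
      patient_id = as.character(seq_along(data)), label = data
    )
  }
  round_half_up <- function(x) floor(x + 0.5)
  out <- with_seed(seed, {
    dplyr::bind_rows(lapply(split(data, data$label), function(cls) {
      n <- nrow(cls)
      if (n == 0L) {
        warning("a class contributes no patients")
        return(cls[0, ])
      }
      n_test <- round_half_up(n * fractions[3])
      n_val <- round_half_up(n * fractions[2])
      perm <- sample.int(n)
      split_lab <- rep("train", n)
      split_lab[perm[seq_len(n_test)]] <- "test"
      if (n_val > 0) split_lab[perm[n_test + seq_len(n_val)]] <- "val"
      dplyr::mutate(cls, split = split_lab)
    }))
  })
  tibble::as_tibble(out[match(data$patient_id, out$patient_id), ])
}

#' One-cycle learning rate at a given step
#'
#' Cosine warmup from `max_lr / div_factor` to `max_lr` over the first
#' `warmup_fraction` of steps, then cosine annealing down to
#' `max_lr / (div_factor * final_div_factor)`.  The peak sits exactly at
#' `warmup_fraction * total_steps`.
#'
#' @param step 1-based current step.
#' @param total_steps schedule horizon.
#' @param max_lr peak learning rate.
#' @param warmup_fraction warmup share.
#' @param div_factor,final_div_factor initial/final divisors.
#' @export
onecycle_lr <- function(step, total_steps, max_lr = 1e-4,
                        warmup_fraction = 0.3, div_factor = 25,
                        final_div_factor = 1e4) {
  initial <- max_lr / div_factor
  final <- initial / final_div_factor
  peak_step <- warmup_fraction * total_steps
  if (step <= peak_step) {
    frac <- step / peak_step
    initial + (max_lr - initial) * (1 - cos(pi * frac)) / 2
  } else {
    frac <- (step - peak_step) / (total_steps - peak_step)
    final + (max_lr - final) * (1 + cos(pi * frac)) / 2
  }
}

## ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = nl_zeros_like(params), v = nl_zeros_like(params), t = 0L)
}

adam_update_rec <- function(p, g, m, v, lr, b1, b2, eps, bc1, bc2, wd) {
  if (is.list(p)) {
    for (k in seq_along(p)) {
      if (is.null(g[[k]])) next
      res <- adam_update_rec(p[[k]], g[[k]], m[[k]], v[[k]],
                             lr, b1, b2, eps, bc1, bc2, wd)
      p[[k]] <- res$p; m[[k]] <- res$m; v[[k]] <- res$v
    }
    return(list(p = p, m = m, v = v))
  }
  if (wd > 0) g <- g + wd * p
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / bc1
  vh <- v / bc2
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - betas[1]^state$t
  bc2 <- 1 - betas[2]^state$t
  res <- adam_update_rec(params, grads, state$m, state$v, lr,
                         betas[1], betas[2], eps, bc1, bc2, weight_decay)
  state$m <- res$m
  state$v <- res$v
  list(params = res$p, state = state)
}

## ---- early stopping ---------------------------------------------------------

#' Epoch at which early stopping halts training
#'
#' Training stops after `patience` consecutive epochs without improving the
#' best validation loss; with a monotonically worsening sequence this is
#' epoch `patience + 1`.
#' @param val_losses per-epoch validation losses observed so far.
#' @param patience tolerated non-improving epochs.
#' @return the stopping epoch, or `NA` if training would continue.
#' @export
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf
  bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(e)
    }
  }
  NA_integer_
}

## ---- training loop ----------------------------------------------------------

sample_loss_fwd <- function(model, s, lambda, training) {
  fwd <- model_forward(model, s$pixels,
    label = s$label, token_ids = s$token_ids, training = training
  )
  l_rep <- if (is.na(fwd$loss_report)) 0 else fwd$loss_report
  list(fwd = fwd, total = fwd$loss_cls + lambda * l_rep,
       cls = fwd$loss_cls, rep = l_rep)
}

#' Train the joint classification + report model
#'
#' @param model a [lungformer_model()].
#' @param train_samples list of samples, each
#'   `list(pixels, label, token_ids)` with standardised pixels (see
#'   [scale_stack()]), 1-based label, 0-based token ids (or `NULL` for
#'   classification-only training).
#' @param val_samples optional validation samples (enables early stopping and
#'   best-checkpoint selection on validation total loss).
#' @param config a [train_config()].
#' @param checkpoint_dir optional directory for `best.rds` / `last.rds`.
#' @return object of class `lungformer_fit`: `model` (best parameters),
#'   `log` (step-level tibble), `val_log`, `best_epoch`.
#' @export
train_lungformer <- function(model, train_samples, val_samples = NULL,
                             config = train_config(),
                             checkpoint_dir = NULL) {
  if (length(train_samples) == 0L) stop("training split is empty")
  n <- length(train_samples)
  steps_per_epoch <- max(1L, ceiling(n / config$batch_size))
  total_steps <- if (!is.null(config$max_steps)) {
    config$max_steps
  } else {
    steps_per_epoch * config$max_epochs
  }

  state <- adam_init(model$params)
  log <- list()
  val_log <- list()
  best_val <- Inf
  best_params <- model$params
  best_epoch <- NA_integer_
  bad <- 0L
  step <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(steps_per_epoch)) {
        idx <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
        step <- step + 1L
        grads <- NULL
        tot <- cls <- rep <- 0
        for (i in idx) {
          r <- sample_loss_fwd(model, train_samples[[i]],
                               config$lambda_report, training = TRUE)
          g <- model_backward(model, r$fwd, lambda = config$lambda_report)
          grads <- nl_add(grads, g)
          tot <- tot + r$total; cls <- cls + r$cls; rep <- rep + r$rep
        }
        grads <- nl_scale(grads, 1 / length(idx))
        lr <- onecycle_lr(step, total_steps, config$max_lr,
                          config$warmup_fraction, config$div_factor,
                          config$final_div_factor)
        upd <- adam_step(model$params, grads, state, lr,
                         config$betas, config$eps, config$weight_decay)
        model$params <- upd$params
        state <- upd$state
        log[[step]] <- tibble::tibble(
          step = step, epoch = epoch,
          loss_total = tot / length(idx), loss_cls = cls / length(idx),
          loss_report = rep / length(idx), lr = lr
        )
        if (!is.null(config$max_steps) && step >= config$max_steps) break
      }
      if (!is.null(config$max_steps) && step >= config$max_steps) break

      if (!is.null(val_samples) && length(val_samples) > 0) {
        vl <- mean(vapply(val_samples, function(s) {
          sample_loss_fwd(model, s, config$lambda_report, training = FALSE)$total
        }, numeric(1)))
        val_log[[epoch]] <- tibble::tibble(epoch = epoch, val_loss = vl)
        if (vl < best_val) {
          best_val <- vl
          best_params <- model$params
          best_epoch <- epoch
          bad <- 0L
          if (!is.null(checkpoint_dir)) {
            dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
            saveRDS(best_params, file.path(checkpoint_dir, "best.rds"))
          }
        } else {
          bad <- bad + 1L
          if (bad >= config$early_stop_patience) break
        }
      }
    }
  })

  if (is.null(val_samples)) {
    best_params <- model$params
  }
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(model$params, file.path(checkpoint_dir, "last.rds"))
    saveRDS(best_params, file.path(checkpoint_dir, "best.rds"))
  }
  model$params <- best_params
  structure(
    list(
      model = model,
      log = dplyr::bind_rows(log),
      val_log = dplyr::bind_rows(val_log),
      best_epoch = best_epoch,
      config = config
    ),
    class = "lungformer_fit"
  )
}

#' Overfit the decoder on one fixed (context, report) pair
#'
#' Language-model-only optimisation used as a learning smoke test: with a
#' fixed visual context and a single report, a few hundred Adam steps should
#' collapse the language-modeling loss.
#'
#' @param decoder_params parameters from [decoder_init()].
#' @param context fixed (n_context x D) context matrix.
#' @param token_ids 0-based report token ids.
#' @param config a [decoder_config()].
#' @param steps optimisation steps.
#' @param lr Adam learning rate.
#' @return list(params, losses) with the per-step loss trace.
#' @export
overfit_decoder <- function(decoder_params, context, token_ids, config,
                            steps = 300L, lr = 1e-3) {
  state <- adam_init(decoder_params)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    fwd <- decode_teacher_forced(decoder_params, token_ids, context, config,
      training = FALSE
    )
    losses[s] <- fwd$loss
    bk <- decoder_bwd(decoder_params, fwd, config)
    upd <- adam_step(decoder_params, bk$grads, state, lr)
    decoder_params <- upd$params
    state <- upd$state
  }
  list(params = decoder_params, losses = losses)
}

## ---- broom-style accessors ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Step-level training log of a fit
#' @param x a `lungformer_fit`.
#' @param ... unused.
#' @export
tidy.lungformer_fit <- function(x, ...) x$log

#' One-row summary of a fit
#' @param x a `lungformer_fit`.
#' @param ... unused.
#' @export
glance.lungformer_fit <- function(x, ...) {
  tibble::tibble(
    steps = nrow(x$log),
    initial_loss = x$log$loss_total[1],
    final_loss = x$log$loss_total[nrow(x$log)],
    best_epoch = x$best_epoch,
    best_val_loss = if (nrow(x$val_log)) min(x$val_log$val_loss) else NA_real_
  )
}

#' Loss-curve plot of a fit
#' @param object a `lungformer_fit`.
#' @param ... unused.
#' @export
autoplot.lungformer_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$log[, c("step", "loss_total", "loss_cls", "loss_report")],
    -"step", names_to = "loss", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "optimisation step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
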