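# ---------------------------------------------------------------------------
# Training, evaluation and ablation harness.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published recipe: mini-batch 8, AdamW at 1e-4 with
#' cosine annealing over 200 epochs, 512x512 inputs, boundary-weighted
#' IoU+BCE loss, model selection on mean validation Dice.
#'
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate.
#' @param epochs Training epochs; also the cosine annealing period.
#' @param optimizer Optimizer name; only `"adamw"` is provided.
#' @param schedule Learning-rate policy; only `"cosine"` is provided.
#' @param resize Training resolution (h, w), divisible by 32.
#' @param loss Loss name (`"iou+bce"` weighted combination by default; see
#'   [alt_losses()] for the comparison family).
#' @param seed Integer seed controlling init, shuffling and augmentation.
#' @param ablation Component switches from [ablation_config()].
#' @param select_metric Validation metric used to keep the best weights.
#' @param weight_decay AdamW decoupled weight decay.
#' @param augment Apply the augmentation policy during training.
#' @param aug_p Per-transform probability.
#' @param rot_range Rotation half-range (degrees).
#' @param noise_sd Augmentation noise sd.
#' @param bw_kernel,bw_omega Boundary-weight window and amplitude.
#' @param max_steps Optional hard cap on optimizer steps (the cosine period
#'   then spans steps instead of epochs); used by the overfitting harness.
#' @param eval_every Validate every this many epochs (always on the last).
#' @param stop_at Optional early-stopping threshold: training ends once the
#'   selection metric reaches this value on the validation set.
#' @return Config list (class `slhardnet_config`).
#' @export
train_config <- function(batch_size = 8L, lr = 1e-4, epochs = 200L,
                         optimizer = "adamw", schedule = "cosine",
                         resize = c(512L, 512L), loss = "iou+bce",
                         seed = 1L, ablation = ablation_config(),
                         select_metric = "DIC", weight_decay = 1e-2,
                         augment = TRUE, aug_p = 0.5, rot_range = 90,
                         noise_sd = 10 / 255, bw_kernel = 31L, bw_omega = 5,
                         max_steps = NULL, eval_every = 1L, stop_at = NULL) {
  if (!identical(optimizer, "adamw")) stop("unsupported optimizer: ", optimizer)
  if (!identical(schedule, "cosine")) stop("unsupported schedule: ", schedule)
  valid_losses <- c("iou+bce", "iou", "bce", "dice", "dice+bce")
  if (!loss %in% valid_losses) {
    stop("unknown loss '", loss, "'; available: ",
         paste(valid_losses, collapse = ", "))
  }
  cfg <- list(batch_size = as.integer(batch_size), lr = lr,
              epochs = as.integer(epochs), optimizer = optimizer,
              schedule = schedule, resize = as.integer(resize), loss = loss,
              seed = as.integer(seed), ablation = ablation,
              select_metric = select_metric, weight_decay = weight_decay,
              augment = augment, aug_p = aug_p, rot_range = rot_range,
              noise_sd = noise_sd, bw_kernel = as.integer(bw_kernel),
              bw_omega = bw_omega, max_steps = max_steps,
              eval_every = as.integer(eval_every), stop_at = stop_at)
  class(cfg) <- c("slhardnet_config", "list")
  cfg
}

stack_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, dim = c(d[1], d[2], 3L, n))
  g <- array(0, dim = c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    g[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, gt = g)
}

predict_batch_probs <- function(model, x) {
  out <- model_forward(model, x, train = FALSE)
  1 / (1 + exp(-out$main_logits$v))
}

eval_model_metrics <- function(model, dataset, batch_size = 4L,
                               threshold = 0.5) {
  preds <- list(); gts <- list(); ids <- character()
  i <- 1L
  while (i <= length(dataset)) {
    idx <- i:min(i + batch_size - 1L, length(dataset))
    b <- stack_batch(dataset[idx])
    pr <- predict_batch_probs(model, b$x)
    for (j in seq_along(idx)) {
      preds[[length(preds) + 1L]] <- (pr[, , 1, j] >= threshold) * 1
      gts[[length(gts) + 1L]] <- dataset[[idx[j]]]$mask
      ids <- c(ids, dataset[[idx[j]]]$id)
    }
    i <- i + batch_size
  }
  metric_table(preds, gts, ids)
}

#' Train the segmentation network
#'
#' Runs AdamW with per-epoch cosine annealing, computes validation metrics
#' after every epoch, keeps the weights with the best validation Dice and
#' reloads them at the end.
#'
#' @param cfg Configuration from [train_config()].
#' @param dataset Nonempty list of training samples (all one size, divisible
#'   by 32).
#' @param val_dataset Validation samples; defaults to the training set.
#' @param out_dir Optional run directory for checkpoint, log CSV and
#'   manifest.
#' @param verbose Print one line per epoch.
#' @return Fit object (class `slhardnet_fit`) with the model, config,
#'   per-epoch log tibble and best validation metrics.
#' @export
train <- function(cfg, dataset, val_dataset = NULL, out_dir = NULL,
                  verbose = FALSE) {
  if (length(dataset) == 0L) stop("training dataset is empty")
  val_dataset <- val_dataset %||% dataset
  set.seed(cfg$seed)
  model <- model_new(cfg$ablation)
  params <- collect_params(model)
  opt <- adamw_new(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  n <- length(dataset)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$max_steps %||% (cfg$epochs * steps_per_epoch)
  log_rows <- list()
  best <- list(metric = -Inf, state = NULL, epoch = NA_integer_)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    nb <- 0L
    lr_epoch <- cosine_lr(cfg$lr, epoch - 1L, cfg$epochs)
    for (bi in seq_len(steps_per_epoch)) {
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) break
      idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      samples <- dataset[idx]
      if (cfg$augment) {
        samples <- lapply(seq_along(samples), function(j) {
          augment(samples[[j]],
                  seed = (cfg$seed + 7919L * epoch + 104729L * idx[j]) %%
                    .Machine$integer.max,
                  p = cfg$aug_p, rot_range = cfg$rot_range,
                  noise_sd = cfg$noise_sd)
        })
      }
      b <- stack_batch(samples)
      lr_now <- if (is.null(cfg$max_steps)) lr_epoch
                else cosine_lr(cfg$lr, step, cfg$max_steps)
      ag_tape_start()
      out <- model_forward(model, b$x, train = TRUE)
      loss <- total_loss(out, b$gt, cfg$bw_kernel, cfg$bw_omega, cfg$loss)
      ag_backward(loss)
      ag_tape_end()
      adamw_step(opt, lr = lr_now)
      ep_loss <- ep_loss + loss$v
      nb <- nb + 1L
      step <- step + 1L
    }
    finished <- (!is.null(cfg$max_steps) && step >= cfg$max_steps) ||
      epoch == cfg$epochs
    do_eval <- finished || (epoch %% cfg$eval_every == 0L)
    dic <- NA_real_; jac <- NA_real_
    if (do_eval) {
      ev <- eval_model_metrics(model, val_dataset)
      dic <- ev$summary$DIC[1]
      jac <- ev$summary$JAC[1]
      sel <- ev$summary[[cfg$select_metric]][1]
      if (sel > best$metric) {
        best <- list(metric = sel, state = state_dict(model), epoch = epoch)
      }
      if (!is.null(cfg$stop_at) && sel >= cfg$stop_at) finished <- TRUE
    }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = if (is.null(cfg$max_steps)) lr_epoch else lr_now,
      train_loss = ep_loss / max(nb, 1L), val_DIC = dic, val_JAC = jac)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val DIC %.4f",
                      epoch, log_rows[[epoch]]$lr,
                      log_rows[[epoch]]$train_loss, dic))
    }
    if (finished) break
  }
  if (!is.null(best$state)) load_state_dict(model, best$state)
  fit <- structure(list(model = model, config = cfg,
                        log = do.call(rbind, log_rows),
                        best_metric = best$metric, best_epoch = best$epoch),
                   class = "slhardnet_fit")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))
    utils::write.csv(fit$log, file.path(out_dir, "log.csv"),
                     row.names = FALSE)
    write_manifest(cfg, out_dir)
  }
  fit
}

write_manifest <- function(cfg, out_dir) {
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("slhardnet")),
                   r_version = R.version.string,
                   git_hash = "<unversioned>")
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(NULL)
}

#' Save a checkpoint (weights + full config + seed record)
#' @param fit Fit object or model.
#' @param path Output file.
#' @export
save_checkpoint <- function(fit, path) {
  if (inherits(fit, "slhardnet_fit")) {
    saveRDS(list(state = state_dict(fit$model), config = fit$config,
                 seed = fit$config$seed, log = fit$log), path)
  } else {
    saveRDS(list(state = state_dict(fit), config = NULL, seed = NA), path)
  }
  invisible(path)
}

#' Load a checkpoint into a freshly built model
#' @param path Checkpoint file from [save_checkpoint()].
#' @return Fit object with the restored model and config.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config %||% train_config()
  model <- model_new(cfg$ablation)
  load_state_dict(model, ck$state)
  structure(list(model = model, config = cfg, log = ck$log,
                 best_metric = NA_real_, best_epoch = NA_integer_),
            class = "slhardnet_fit")
}

#' Evaluate a model on a dataset
#'
#' @param fit Fit object, or a raw model.
#' @param dataset List of samples.
#' @param threshold Binarization threshold.
#' @param pooled Also report pooled-count metrics.
#' @param csv Optional path for the per-image + summary CSV.
#' @return Evaluation object (class `slhardnet_eval`) with `per_image` and
#'   `summary` tibbles.
#' @export
evaluate <- function(fit, dataset, threshold = 0.5, pooled = FALSE,
                     csv = NULL) {
  model <- if (inherits(fit, "slhardnet_fit")) fit$model else fit
  preds <- list(); gts <- list(); ids <- character()
  i <- 1L
  while (i <= length(dataset)) {
    idx <- i:min(i + 3L, length(dataset))
    b <- stack_batch(dataset[idx])
    pr <- predict_batch_probs(model, b$x)
    for (j in seq_along(idx)) {
      preds[[length(preds) + 1L]] <- (pr[, , 1, j] >= threshold) * 1
      gts[[length(gts) + 1L]] <- dataset[[idx[j]]]$mask
      ids <- c(ids, dataset[[idx[j]]]$id)
    }
    i <- i + 4L
  }
  mt <- metric_table(preds, gts, ids, pooled = pooled)
  out <- structure(list(per_image = mt$per_image, summary = mt$summary,
                        threshold = threshold), class = "slhardnet_eval")
  if (!is.null(csv)) {
    utils::write.csv(rbind(mt$per_image, mt$summary), csv, row.names = FALSE)
  }
  out
}

#' Ablation comparison
#'
#' Trains the four component variants (baseline, +decoder, +attention, full)
#' under one seed and data budget and reports their validation metrics and
#' parameter counts.
#'
#' @param cfg Base configuration; the ablation field is overridden per
#'   variant.
#' @param dataset Training samples.
#' @param val_dataset Validation samples; defaults to the training set.
#' @return Tibble with one row per variant.
#' @export
ablate <- function(cfg, dataset, val_dataset = NULL) {
  variants <- list(
    baseline = ablation_config(FALSE, FALSE, FALSE),
    `+CFM` = ablation_config(TRUE, FALSE, FALSE),
    `+CFM+SCAM` = ablation_config(TRUE, TRUE, FALSE),
    full = ablation_config(TRUE, TRUE, TRUE))
  rows <- lapply(names(variants), function(v) {
    cfg_v <- cfg
    cfg_v$ablation <- variants[[v]]
    fit <- train(cfg_v, dataset, val_dataset)
    ev <- evaluate(fit, val_dataset %||% dataset)
    cbind(tibble::tibble(variant = v, n_params = n_params(fit$model)),
          ev$summary[1, c("DIC", "JAC", "ACC", "SEN", "SPE")])
  })
  do.call(rbind, rows)
}
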