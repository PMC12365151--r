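## Training: Adam with weight decay, per-epoch exponential learning-rate
## decay, stratified k-fold cross-validation, flip augmentation on training
## samples only, and per-fold clinical-encoder fitting (standardization
## statistics never see the validation split).

#' Training configuration
#'
#' Defaults follow the reference CMMFNet optimization recipe (Adam, learning rate
#' 1e-4, weight decay 1e-3, betas (0.9, 0.99), per-epoch exponential decay
#' with factor 0.99, batch size 24, focal gamma 0.25) except for the epoch
#' budget, which defaults to a desk-scale 30 instead of 500.
#'
#' @param lr Initial learning rate.
#' @param weight_decay L2 weight decay added to gradients.
#' @param betas Adam momentum coefficients.
#' @param scheduler_gamma Per-epoch exponential decay factor.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param flip_prob Per-axis flip-augmentation probability (training only).
#' @param focal_gamma Focal-loss focusing parameter.
#' @param early_stop_acc Stop a fold early once validation accuracy (in
#'   `[0, 1]`) reaches this value; `NULL` disables.
#' @param seed Seed covering initialization, shuffling and augmentation.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-3,
                         betas = c(0.9, 0.99), scheduler_gamma = 0.99,
                         epochs = 30L, batch_size = 24L, flip_prob = 0.5,
                         focal_gamma = 0.25, early_stop_acc = NULL,
                         seed = 1L) {
  if (lr <= 0 || weight_decay < 0) stop("train_config(): bad rates")
  if (scheduler_gamma <= 0 || scheduler_gamma >= 1) {
    stop("train_config(): scheduler_gamma must lie in (0, 1)")
  }
  if (any(betas <= 0 | betas >= 1)) stop("train_config(): bad betas")
  structure(list(lr = lr, weight_decay = weight_decay, betas = betas,
                 scheduler_gamma = scheduler_gamma,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 flip_prob = flip_prob, focal_gamma = focal_gamma,
                 early_stop_acc = early_stop_acc, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#' @param tc A [train_config()].
#' @param epoch Number of completed epochs (0 = initial rate).
#' @return `lr * scheduler_gamma^epoch`.
#' @export
lr_at_epoch <- function(tc, epoch) tc$lr * tc$scheduler_gamma^epoch

## --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_update_rec <- function(p, g, m, v, lr, b1, b2, eps, wd, c1, c2) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      if (is.null(p[[i]])) next
      res <- adam_update_rec(p[[i]], g[[i]], m[[i]], v[[i]],
                             lr, b1, b2, eps, wd, c1, c2)
      p[[i]] <- res$p; m[[i]] <- res$m; v[[i]] <- res$v
    }
    list(p = p, m = m, v = v)
  } else {
    g <- g + wd * p
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    list(p = p, m = m, v = v)
  }
}

adam_step <- function(params, grads, state, lr, betas, weight_decay,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  res <- adam_update_rec(params, grads, state$m, state$v, lr,
                         betas[1], betas[2], eps, weight_decay,
                         1 - betas[1]^state$t, 1 - betas[2]^state$t)
  state$m <- res$m
  state$v <- res$v
  list(params = res$p, state = state)
}

## --- folds -----------------------------------------------------------------

#' Stratified k-fold partition
#'
#' Shuffles each class and deals its members round-robin over the folds, so
#' per-fold class counts differ from exact proportionality by less than one
#' sample. Errors if any class has fewer than `k` members.
#'
#' @param labels 0-based class labels.
#' @param k Number of folds.
#' @param seed Seed for the per-class shuffles.
#' @return List of `k` disjoint 1-based index vectors covering all samples.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("stratified_folds(): class ",
         names(counts)[which(counts < k)[1]], " has fewer than ", k,
         " members")
  }
  set.seed(seed)
  folds <- vector("list", k)
  for (cls in sort(unique(labels))) {
    idx <- sample(which(labels == cls))
    slot <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[slot == f])
  }
  lapply(folds, sort)
}

## --- sample preparation ----------------------------------------------------

#' Preprocess generated phantom cases into model-ready samples
#'
#' Applies [preprocess_case()] to each case and keeps the raw clinical
#' record (the clinical vector is encoded per training fold).
#'
#' @param cases List of [sample_case()] results (or equivalent lists with
#'   `volume`, `bbox`, `ehr`, `label`).
#' @param crop_small,crop_large Crop shapes.
#' @param target_spacing_mm Resampling target.
#' @return List of samples with `roi_small`, `roi_large`, `bbox_small`,
#'   `bbox_large`, `ehr`, `label`.
#' @export
preprocess_cases <- function(cases, crop_small = c(32, 32, 32),
                             crop_large = c(128, 128, 32),
                             target_spacing_mm = c(1, 1, 1)) {
  lapply(cases, function(cs) {
    pp <- preprocess_case(cs$volume, cs$bbox, crop_small, crop_large,
                          target_spacing_mm)
    list(roi_small = pp$roi_small, roi_large = pp$roi_large,
         bbox_small = pp$bbox_small, bbox_large = pp$bbox_large,
         ehr = cs$ehr, label = cs$label)
  })
}

flip_sample <- function(s, axes) {
  for (ax in axes) {
    fs <- flip_with_bbox(s$roi_small, s$bbox_small, ax)
    s$roi_small <- fs$grid; s$bbox_small <- fs$bbox
    fl <- flip_with_bbox(s$roi_large, s$bbox_large, ax)
    s$roi_large <- fl$grid; s$bbox_large <- fl$bbox
  }
  s
}

encode_samples <- function(samples, encoder) {
  lapply(samples, function(s) {
    s$ehr_vec <- encode_ehr(s$ehr, encoder)
    s
  })
}

## --- fold training ---------------------------------------------------------

#' Train the model on one fold
#'
#' Fits the clinical encoder on the training split, initializes the model,
#' and runs Adam with per-epoch exponential learning-rate decay. Flip
#' augmentation (each axis independently with `flip_prob`) is applied to
#' training batches only; augmentation never touches labels or clinical
#' vectors. The checkpoint with the best validation accuracy is kept.
#'
#' @param samples Preprocessed samples (see [preprocess_cases()]).
#' @param train_idx,val_idx Disjoint 1-based index vectors.
#' @param config A [cmmf_config()]; its `ehr_len` is set from the fitted
#'   clinical encoder.
#' @param tc A [train_config()].
#' @param ehr_schema List of [ehr_field()] descriptors for the clinical
#'   record.
#' @return List with `model` (best checkpoint), `history` (per-epoch data
#'   frame of loss-bundle means and validation accuracy), `val_probs`,
#'   `val_pred`, `val_true`, `best_epoch`, `encoder`.
#' @export
train_fold <- function(samples, train_idx, val_idx, config, tc, ehr_schema) {
  if (length(intersect(train_idx, val_idx)) > 0) {
    stop("train_fold(): train and validation indices overlap")
  }
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  uses_clinical <- "clinical" %in% config$modalities

  if (uses_clinical) {
    train_records <- do.call(rbind, lapply(samples[train_idx], function(s) {
      as.data.frame(s$ehr, stringsAsFactors = FALSE)
    }))
    encoder <- fit_ehr_encoder(train_records, ehr_schema)
    config$ehr_len <- encoder$length
    samples <- encode_samples(samples, encoder)
  } else {
    encoder <- NULL
  }

  counts <- tabulate(labels[train_idx] + 1L, nbins = config$n_classes)
  if (any(counts == 0)) stop("train_fold(): a class is absent from training")
  alpha_t <- class_alpha_weights(counts)

  model <- cmmf_model(config, seed = tc$seed)
  state <- adam_init(model$params)
  set.seed(tc$seed + 1L)

  val_samples <- samples[val_idx]
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  hist_rows <- vector("list", tc$epochs)

  for (epoch in seq_len(tc$epochs)) {
    lr <- lr_at_epoch(tc, epoch - 1L)
    order_idx <- sample(train_idx)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / tc$batch_size))
    bundles <- list()
    for (bi in seq_along(batches)) {
      batch <- lapply(samples[batches[[bi]]], function(s) {
        axes <- which(runif(3) < tc$flip_prob) - 1L
        if (length(axes) > 0) flip_sample(s, axes) else s
      })
      step <- model_loss(model, batch, alpha_t, tc$focal_gamma)
      upd <- adam_step(model$params, step$grads, state, lr, tc$betas,
                       tc$weight_decay)
      model$params <- upd$params
      state <- upd$state
      bundles[[bi]] <- step$bundle
    }
    pv <- predict_cmmf(model, val_samples, tc$batch_size)
    val_acc <- mean(pv$pred == labels[val_idx])
    mean_of <- function(f) mean(vapply(bundles, `[[`, numeric(1), f))
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      L_SC = mean_of("L_SC"), L_LC = mean_of("L_LC"),
      L_focal = mean_of("L_focal"), omega = mean_of("omega"),
      L_total = mean_of("L_total"), val_accuracy = val_acc)
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, params = model$params, epoch = epoch)
    }
    if (!is.null(tc$early_stop_acc) && val_acc >= tc$early_stop_acc) break
  }

  model$params <- best$params
  pv <- predict_cmmf(model, val_samples, tc$batch_size)
  list(model = model,
       history = do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                                  logical(1))]),
       val_probs = pv$probs, val_pred = pv$pred,
       val_true = labels[val_idx], val_idx = val_idx,
       best_epoch = best$epoch, encoder = encoder)
}

#' Stratified k-fold cross-validated training and evaluation
#'
#' Trains `k` independently initialized models, each fold serving once as
#' the validation set, and reports pooled-prediction metrics plus per-fold
#' reports with their mean and standard deviation.
#'
#' @param samples Preprocessed samples (see [preprocess_cases()]).
#' @param config A [cmmf_config()].
#' @param tc A [train_config()].
#' @param ehr_schema Clinical field descriptors.
#' @param k Number of folds.
#' @return A `cmmf_cv` list: `pooled` ([evaluate_predictions()] over all
#'   validation predictions), `folds` (per-fold reports), `summary`
#'   (mean/sd of the fold metrics), `fold_results`.
#' @export
cross_validate <- function(samples, config, tc, ehr_schema, k = 5L) {
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  folds <- stratified_folds(labels, k, seed = tc$seed)
  all_idx <- sort(unlist(folds))
  if (!identical(all_idx, seq_along(samples))) {
    stop("cross_validate(): folds do not partition the dataset")
  }
  results <- vector("list", k)
  for (f in seq_len(k)) {
    val_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(samples), val_idx)
    tc_f <- tc
    tc_f$seed <- tc$seed + f
    results[[f]] <- train_fold(samples, train_idx, val_idx, config, tc_f,
                               ehr_schema)
  }
  pooled_true <- unlist(lapply(results, `[[`, "val_true"))
  pooled_pred <- unlist(lapply(results, `[[`, "val_pred"))
  pooled_probs <- do.call(rbind, lapply(results, `[[`, "val_probs"))
  pooled <- evaluate_predictions(pooled_true, pooled_pred, pooled_probs,
                                 config$n_classes)
  fold_reports <- lapply(results, function(r) {
    evaluate_predictions(r$val_true, r$val_pred, r$val_probs,
                         config$n_classes)
  })
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  fold_mat <- t(vapply(fold_reports, function(r) {
    unlist(r[metric_names])
  }, numeric(length(metric_names))))
  structure(list(
    pooled = pooled, folds = fold_reports,
    summary = data.frame(metric = metric_names,
                         mean = colMeans(fold_mat),
                         sd = apply(fold_mat, 2, sd)),
    fold_results = results), class = "cmmf_cv")
}

#' @export
print.cmmf_cv <- function(x, ...) {
  cat("Pooled validation metrics over", length(x$folds), "folds:\n")
  print(x$pooled)
  cat("Per-fold mean (sd):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %7.3f (%.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
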