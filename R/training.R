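#' Self-supervised pretraining
#'
#' Trains the masked autoencoder on a fixed-length event set by latent
#' reconstruction: for every event in every epoch a fresh random mask plan is
#' drawn (seeded stream), the encoder processes visible and masked subsequences
#' separately, the decoder predicts the encoder's representation of the masked
#' content, and the mean-squared latent loss is minimized with Adam. Labels are
#' never read — the label field is stripped before the loop.
#'
#' @param events A fixed-length [event_set] (see [preprocess_events()]).
#' @param mcfg A [model_config].
#' @param tcfg A [train_config]; `epochs_pretrain`, `batch_size`, `lr`,
#'   `mask_ratio` and `seed` are used.
#' @param verbose Print per-epoch loss.
#' @return A checkpoint of class `mae_checkpoint`: weights (projection,
#'   positional table, mask token, encoder, decoder), configs, the
#'   preprocessing contract (`fixed_length`, `w`), and a per-epoch `log`
#'   tibble (epoch, loss, lr, seconds).
#' @export
pretrain <- function(events, mcfg, tcfg, verbose = FALSE) {
  stopifnot(inherits(events, "event_set"), inherits(mcfg, "model_config"),
            inherits(tcfg, "train_config"))
  # self-supervised: strip labels so the loop cannot read them
  unlabeled <- event_set(lapply(events$events, function(e)
    event_record(e$id, e$trace, label = "", source = e$source,
                 duration_points = e$duration_points)),
    fixed_length = events$fixed_length)
  sb <- segment_batch(unlabeled, mcfg$w)
  n <- sb$B; L <- sb$L
  if (L < 2L)
    stopf("pretrain: events yield %d subsequence(s); at least 2 are required", L)
  model <- mae_model(mcfg, n_positions = L, seed = tcfg$seed)
  w <- model$weights
  opt <- adam_init(w)
  log <- vector("list", tcfg$epochs_pretrain)
  set.seed(mix_seed(tcfg$seed, 7L))
  for (epoch in seq_len(tcfg$epochs_pretrain)) {
    t0 <- proc.time()[["elapsed"]]
    order_idx <- sample.int(n)
    plans <- lapply(seq_len(n), function(i)
      make_mask(L, tcfg$mask_ratio, seed = mix_seed(tcfg$seed, epoch, i)))
    losses <- c(); sizes <- c()
    for (start in seq(1L, n, by = tcfg$batch_size)) {
      idx <- order_idx[start:min(start + tcfg$batch_size - 1L, n)]
      rows <- unlist(lapply(idx, function(b) ((b - 1L) * L + 1L):(b * L)),
                     use.names = FALSE)
      st <- pretrain_step(w, sb$seg[rows, , drop = FALSE], length(idx), L,
                          plans[idx], mcfg, train = TRUE)
      upd <- adam_step(w, st$grads, opt, lr = tcfg$lr)
      w <- upd$w; opt <- upd$state
      losses <- c(losses, st$loss); sizes <- c(sizes, length(idx))
    }
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = sum(losses * sizes) / sum(sizes), lr = tcfg$lr,
      seconds = proc.time()[["elapsed"]] - t0)
    if (verbose) message(sprintf("pretrain epoch %d: loss %.6f", epoch,
                                 log[[epoch]]$loss))
  }
  structure(list(weights = w, mcfg = mcfg, ccfg = NULL, tcfg = tcfg,
                 preprocess = list(fixed_length = events$fixed_length, w = mcfg$w),
                 n_positions = L, stage = "pretrain", class_names = NULL,
                 log = do.call(rbind, log)),
            class = "mae_checkpoint")
}

#' Supervised fine-tuning (or training from scratch)
#'
#' Optimizes cross-entropy over pooled full-event embeddings with AdamW and a
#' cosine learning-rate schedule decaying to `lr * lr_floor_fraction` by the
#' final epoch. With `init` a pretraining checkpoint, the input projection,
#' positional table and encoder are loaded from it; with `init = NULL` the whole
#' model is freshly initialized — the supervised-only "scratch" baseline that
#' shares every other setting of the fine-tuning recipe.
#'
#' @param events A labeled fixed-length [event_set]; every event must carry a
#'   non-empty label.
#' @param mcfg A [model_config] (must match `init` when given).
#' @param tcfg A [train_config]; `epochs_finetune`, `batch_size`, `lr`,
#'   `weight_decay`, `lr_floor_fraction`, `schedule_finetune`, `seed` are used.
#' @param init Optional `mae_checkpoint` from [pretrain()].
#' @param ccfg Optional [classifier_config]; defaults to
#'   `classifier_config(M = <number of classes>)`.
#' @param freeze_encoder If `TRUE`, only the classifier head is updated.
#' @param verbose Print per-epoch loss.
#' @return An `mae_checkpoint` with stage `"finetune"`, including `class_names`.
#' @export
finetune <- function(events, mcfg, tcfg, init = NULL, ccfg = NULL,
                     freeze_encoder = FALSE, verbose = FALSE) {
  stopifnot(inherits(events, "event_set"), inherits(mcfg, "model_config"),
            inherits(tcfg, "train_config"))
  labels <- event_labels(events)
  if (any(!nzchar(labels)))
    stopf("finetune: all events must be labeled (event '%s' is not)",
          event_ids(events)[which(!nzchar(labels))[1L]])
  class_names <- events$class_names
  M <- length(class_names)
  if (is.null(ccfg)) ccfg <- classifier_config(M = M)
  if (ccfg$M != M) stopf("finetune: ccfg$M = %d but %d classes present", ccfg$M, M)
  y <- match(labels, class_names)
  sb <- segment_batch(events, mcfg$w)
  n <- sb$B; L <- sb$L
  if (!is.null(init)) {
    stopifnot(inherits(init, "mae_checkpoint"))
    if (!identical(init$preprocess$fixed_length, events$fixed_length) ||
        init$preprocess$w != mcfg$w || init$mcfg$d != mcfg$d ||
        init$n_positions != L)
      stopf("finetune: checkpoint is incompatible with these events/config (F, w, d, L must match)")
  }
  model <- mae_model(mcfg, n_positions = L, ccfg = ccfg,
                     seed = mix_seed(tcfg$seed, 13L))
  w <- model$weights
  if (!is.null(init)) {
    w$proj <- init$weights$proj
    w$pos <- init$weights$pos
    w$enc <- init$weights$enc
  }
  opt_names <- if (freeze_encoder) "clf" else c("proj", "pos", "enc", "clf")
  opt <- adam_init(w[opt_names])
  log <- vector("list", tcfg$epochs_finetune)
  set.seed(mix_seed(tcfg$seed, 29L))
  for (epoch in seq_len(tcfg$epochs_finetune)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- if (tcfg$schedule_finetune == "cosine_to_floor")
      cosine_lr(epoch, tcfg$epochs_finetune, tcfg$lr, tcfg$lr_floor_fraction)
    else tcfg$lr
    order_idx <- sample.int(n)
    losses <- c(); sizes <- c()
    for (start in seq(1L, n, by = tcfg$batch_size)) {
      idx <- order_idx[start:min(start + tcfg$batch_size - 1L, n)]
      rows <- unlist(lapply(idx, function(b) ((b - 1L) * L + 1L):(b * L)),
                     use.names = FALSE)
      st <- finetune_step(w, sb$seg[rows, , drop = FALSE], length(idx), L,
                          y[idx], mcfg, ccfg, train = TRUE,
                          freeze_encoder = freeze_encoder)
      g <- st$grads[opt_names]
      upd <- adam_step(w[opt_names], g, opt, lr = lr,
                       decoupled_wd = tcfg$weight_decay)
      w[opt_names] <- upd$w; opt <- upd$state
      losses <- c(losses, st$loss); sizes <- c(sizes, length(idx))
    }
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = sum(losses * sizes) / sum(sizes), lr = lr,
      seconds = proc.time()[["elapsed"]] - t0)
    if (verbose) message(sprintf("finetune epoch %d: loss %.6f (lr %.2e)", epoch,
                                 log[[epoch]]$loss, lr))
  }
  structure(list(weights = w, mcfg = mcfg, ccfg = ccfg, tcfg = tcfg,
                 preprocess = list(fixed_length = events$fixed_length, w = mcfg$w),
                 n_positions = L, stage = "finetune", class_names = class_names,
                 log = do.call(rbind, log)),
            class = "mae_checkpoint")
}

# Rebuild an mae_model view over checkpoint weights (evaluation use).
checkpoint_model <- function(ckpt) {
  structure(list(weights = ckpt$weights, mcfg = ckpt$mcfg, ccfg = ckpt$ccfg,
                 L = ckpt$n_positions, seed = NA_integer_),
            class = "mae_model")
}

#' Predict class probabilities for events
#'
#' Runs the fine-tuned model in evaluation mode: full-event encoding, global
#' average pooling, classifier head, softmax. Rows sum to 1; the predicted
#' label is the argmax class.
#'
#' @param events A fixed-length [event_set] matching the checkpoint's
#'   preprocessing contract.
#' @param ckpt An `mae_checkpoint` with stage `"finetune"`.
#' @return A tibble with columns `id`, `true_label`, `pred_label`, then one
#'   probability column `p_<class>` per class.
#' @export
predict_events <- function(events, ckpt) {
  stopifnot(inherits(events, "event_set"), inherits(ckpt, "mae_checkpoint"))
  if (ckpt$stage != "finetune")
    stopf("predict_events: checkpoint has no classifier (stage '%s')", ckpt$stage)
  if (!identical(events$fixed_length, ckpt$preprocess$fixed_length))
    stopf("predict_events: events have fixed_length %s but checkpoint expects %s",
          format(events$fixed_length), format(ckpt$preprocess$fixed_length))
  model <- checkpoint_model(ckpt)
  sb <- segment_batch(events, ckpt$mcfg$w)
  z <- embed_event(model, sb)
  probs <- softmax_rows(classify(model, z))
  colnames(probs) <- paste0("p_", ckpt$class_names)
  pred <- ckpt$class_names[max.col(probs, ties.method = "first")]
  out <- tibble::tibble(id = sb$ids, true_label = sb$labels, pred_label = pred)
  cbind(out, tibble::as_tibble(probs))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is written as an RDS archive of weights and configs plus a
#' JSON sidecar (`<path>.json`) recording the architecture, training settings
#' and preprocessing contract, so a fine-tuning run can verify compatibility
#' without loading the weights.
#'
#' @param ckpt An `mae_checkpoint`.
#' @param path Destination file (conventionally `.rds`).
#' @return `path` (`save_checkpoint`) or the checkpoint (`load_checkpoint`).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "mae_checkpoint"))
  saveRDS(ckpt, path)
  sidecar <- list(stage = ckpt$stage,
                  mcfg = unclass(ckpt$mcfg),
                  ccfg = if (!is.null(ckpt$ccfg)) unclass(ckpt$ccfg),
                  tcfg = unclass(ckpt$tcfg),
                  preprocess = ckpt$preprocess,
                  n_positions = ckpt$n_positions,
                  class_names = ckpt$class_names,
                  n_parameters = length(tree_flatten(ckpt$weights)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "mae_checkpoint"))
    stopf("load_checkpoint: '%s' is not an mae_checkpoint", path)
  ckpt
}
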