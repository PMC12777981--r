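#' Cross-entropy of a predicted distribution
#'
#' With a one-hot true label the cross-entropy sum collapses to the true-class
#' term, `-log p_true`. Probabilities are clamped to `>= 1e-12` before the log.
#'
#' @param probs Numeric vector summing to 1 over the classes.
#' @param true_class Integer class index in `1:length(probs)`.
#' @return A scalar loss.
#' @export
cross_entropy <- function(probs, true_class) {
  if (!is_count(true_class) || true_class > length(probs))
    stopf("cross_entropy: invalid class index %s", format(true_class))
  -log(max(probs[[true_class]], 1e-12))
}

#' Classification metrics from predicted and true labels
#'
#' Builds the confusion matrix (rows = true, columns = predicted) and reports
#' accuracy, precision, recall and F1. Macro averaging (the default) takes the
#' unweighted mean of per-class precision/recall over all classes in the label
#' universe — classes absent from truth and predictions contribute 0 and are
#' counted — and the headline F1 is the harmonic mean of macro precision and
#' macro recall (per-class F1 values are also emitted). Micro averaging reduces
#' to accuracy for single-label classification.
#'
#' @param preds,truth Character vectors of equal positive length.
#' @param averaging `"macro"` or `"micro"`.
#' @param class_names Optional label universe (order fixes the confusion-matrix
#'   layout); defaults to the sorted union of labels present.
#' @return A `metric_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1`, `averaging`, `confusion`, `per_class` (tibble), `n`.
#' @export
compute_metrics <- function(preds, truth, averaging = c("macro", "micro"),
                            class_names = NULL) {
  averaging <- match.arg(averaging)
  if (!length(truth) || length(preds) != length(truth))
    stopf("compute_metrics: 'preds' and 'truth' must be equal-length and non-empty")
  if (is.null(class_names)) class_names <- sort(unique(c(truth, preds)))
  if (!all(c(preds, truth) %in% class_names))
    stopf("compute_metrics: labels outside 'class_names'")
  tf <- factor(truth, levels = class_names)
  pf <- factor(preds, levels = class_names)
  confusion <- table(true = tf, predicted = pf)
  n <- length(truth)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  prec_c <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec_c <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  accuracy <- sum(tp) / n
  if (averaging == "macro") {
    precision <- mean(prec_c)
    recall <- mean(rec_c)
  } else {
    precision <- recall <- accuracy
  }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, averaging = averaging,
                 confusion = unclass(confusion),
                 per_class = tibble::tibble(class = class_names,
                                            precision = as.numeric(prec_c),
                                            recall = as.numeric(rec_c),
                                            f1 = as.numeric(f1_c)),
                 n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n = %d (%s): accuracy %.4f, precision %.4f, recall %.4f, F1 %.4f\n",
              x$n, x$averaging, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Assign events to k folds
#'
#' Deterministic given `seed`. Under stratification every class is shuffled and
#' dealt round-robin, so per-class fold sizes differ by at most 1; each class
#' must then have at least `k` members.
#'
#' @param events An [event_set].
#' @param k Number of folds, >= 2.
#' @param seed Integer seed.
#' @param stratified Stratify by label (default `TRUE`).
#' @return A `fold_assignment`: named integer vector (`id -> fold` in `1:k`)
#'   with attributes `k`, `seed`, `stratified`.
#' @export
kfold <- function(events, k = 5L, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(events, "event_set"))
  if (!is_count(k) || k < 2L) stopf("kfold: k must be an integer >= 2")
  ids <- event_ids(events)
  labels <- event_labels(events)
  fold <- integer(length(ids))
  if (stratified) {
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      if (length(members) < k)
        stopf("kfold: class '%s' has %d events, fewer than k = %d",
              cl, length(members), k)
      perm <- with_seed(mix_seed(seed, match(cl, unique(labels))),
                        sample(members))
      fold[perm] <- rep_len(seq_len(k), length(perm))
    }
  } else {
    perm <- with_seed(seed, sample(seq_along(ids)))
    fold[perm] <- rep_len(seq_len(k), length(perm))
  }
  structure(stats::setNames(fold, ids), k = as.integer(k),
            seed = as.integer(seed), stratified = stratified,
            class = "fold_assignment")
}

# One train/evaluate round shared by the experiment runners.
# Returns a metric_report on the test events.
train_and_eval <- function(train_set, test_set, mcfg, tcfg, ccfg = NULL,
                           init = NULL, pretrain_first = FALSE) {
  if (pretrain_first && is.null(init)) init <- pretrain(train_set, mcfg, tcfg)
  ckpt <- finetune(train_set, mcfg, tcfg, init = init, ccfg = ccfg)
  preds <- predict_events(test_set, ckpt)
  report <- compute_metrics(preds$pred_label, preds$true_label,
                            class_names = ckpt$class_names)
  attr(report, "pretrain_log") <- if (!is.null(init)) init$log
  attr(report, "finetune_log") <- ckpt$log
  report
}

#' k-fold cross-validated training and evaluation
#'
#' For each fold: pretrain on the training partition (unless
#' `variant = "scratch"`), fine-tune, and evaluate on the held-out fold.
#' Pretraining only ever sees training-partition events, never the held-out
#' fold. Reports per-fold metrics and their mean and standard deviation.
#'
#' @param events A labeled fixed-length [event_set].
#' @param k Number of folds.
#' @param mcfg,tcfg,ccfg Model, training and (optional) classifier configs.
#' @param variant `"pretrained"` (self-supervised pretraining then fine-tuning)
#'   or `"scratch"` (supervised-only baseline, identical recipe otherwise).
#' @param seed Fold-assignment seed; per-fold training seeds are derived from
#'   `tcfg$seed`.
#' @param stratified Stratify the folds by label.
#' @return List with `folds` (tibble: fold, n, accuracy, precision, recall,
#'   f1), `mean`, `sd` (named numeric), and `reports` (per-fold
#'   `metric_report`s).
#' @export
run_cv <- function(events, k = 5L, mcfg, tcfg, ccfg = NULL,
                   variant = c("pretrained", "scratch"), seed = 1L,
                   stratified = TRUE) {
  variant <- match.arg(variant)
  assignment <- kfold(events, k, seed = seed, stratified = stratified)
  reports <- vector("list", k)
  rows <- vector("list", k)
  for (fold in seq_len(k)) {
    test_idx <- which(assignment == fold)
    train_idx <- which(assignment != fold)
    tcfg_fold <- tcfg
    tcfg_fold$seed <- mix_seed(tcfg$seed, fold)
    rep_f <- train_and_eval(subset_events(events, train_idx),
                            subset_events(events, test_idx),
                            mcfg, tcfg_fold, ccfg,
                            pretrain_first = (variant == "pretrained"))
    reports[[fold]] <- rep_f
    rows[[fold]] <- tibble::tibble(fold = fold, n = rep_f$n,
                                   accuracy = rep_f$accuracy,
                                   precision = rep_f$precision,
                                   recall = rep_f$recall, f1 = rep_f$f1)
  }
  folds <- do.call(rbind, rows)
  metrics <- c("accuracy", "precision", "recall", "f1")
  list(folds = folds,
       mean = vapply(metrics, function(m) mean(folds[[m]]), 0),
       sd = vapply(metrics, function(m) stats::sd(folds[[m]]), 0),
       reports = reports)
}

# Stratified subsample of a fraction of an event_set (by label), seeded.
# Errors if any class would vanish.
stratified_subsample <- function(set, fraction, seed) {
  labels <- event_labels(set)
  keep <- integer(0)
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    n_keep <- round(fraction * length(members))
    if (n_keep < 1L)
      stopf("subsample: fraction %.3f leaves class '%s' empty", fraction, cl)
    keep <- c(keep, with_seed(mix_seed(seed, match(cl, unique(labels))),
                              members[sample.int(length(members), n_keep)]))
  }
  subset_events(set, sort(keep))
}

#' Data-scarcity experiment
#'
#' Measures how classification degrades as the labeled training set shrinks,
#' and whether self-supervised pretraining compensates. The events are split
#' once into a training and a fixed test partition (stratified, seeded); the
#' same test set is retained in every condition. For each seed, the encoder is
#' pretrained once on the full (unlabeled) training partition; for each
#' fraction, a stratified subsample of the labeled training events is drawn and
#' each variant is fine-tuned on it — `"pretrained"` starting from the
#' pretrained encoder, `"scratch"` from random initialization — then evaluated
#' on the test partition.
#'
#' @param events A labeled fixed-length [event_set].
#' @param fractions Fractions of the training partition to keep, in (0, 1].
#' @param variants Subset of `c("pretrained", "scratch")`.
#' @param seeds Integer vector of training seeds (one full repeat each).
#' @param mcfg,tcfg,ccfg Configs as in [run_cv()].
#' @param test_fraction Fraction of events held out as the fixed test set.
#' @param split_seed Seed of the train/test split.
#' @return Tidy tibble: `fraction`, `variant`, `seed`, `fold` (always 1, one
#'   fixed split), `n_train`, `accuracy`, `f1`.
#' @export
scarcity_experiment <- function(events, fractions = c(0.1, 0.25, 0.5, 0.75, 1.0),
                                variants = c("pretrained", "scratch"),
                                seeds = 1:3, mcfg, tcfg, ccfg = NULL,
                                test_fraction = 1/3, split_seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  variants <- match.arg(variants, c("pretrained", "scratch"), several.ok = TRUE)
  labels <- event_labels(events)
  test_idx <- sort(unlist(lapply(unique(labels), function(cl) {
    members <- which(labels == cl)
    with_seed(mix_seed(split_seed, match(cl, unique(labels))),
              members[sample.int(length(members),
                                 max(1L, round(test_fraction * length(members))))])
  })))
  test_set <- subset_events(events, test_idx)
  train_set <- subset_events(events, setdiff(seq_along(labels), test_idx))
  rows <- list()
  for (s in seeds) {
    tcfg_s <- tcfg
    tcfg_s$seed <- mix_seed(tcfg$seed, s)
    enc <- if ("pretrained" %in% variants) pretrain(train_set, mcfg, tcfg_s)
           else NULL
    for (fr in fractions) {
      sub <- if (fr < 1) stratified_subsample(train_set, fr, mix_seed(s, round(1000 * fr)))
             else train_set
      for (v in variants) {
        rep_v <- train_and_eval(sub, test_set, mcfg, tcfg_s, ccfg,
                                init = if (v == "pretrained") enc else NULL)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fraction = fr, variant = v, seed = s, fold = 1L,
          n_train = length(sub), accuracy = rep_v$accuracy, f1 = rep_v$f1)
      }
    }
  }
  do.call(rbind, rows)
}

#' Mask-ratio sweep
#'
#' Full pretrain + fine-tune run per (ratio, seed) on a fixed stratified
#' holdout split, recording held-out accuracy — the protocol for locating the
#' mask-ratio optimum of the pretext task.
#'
#' @param events A labeled fixed-length [event_set].
#' @param ratios Mask ratios in (0, 1).
#' @param seeds Integer vector of training seeds.
#' @param mcfg,tcfg,ccfg Configs as in [run_cv()].
#' @param test_fraction,split_seed Holdout-split controls.
#' @return Tidy tibble: `ratio`, `seed`, `accuracy`, `f1`.
#' @export
mask_ratio_sweep <- function(events, ratios = c(0.15, 0.3, 0.45, 0.6, 0.75, 0.9),
                             seeds = 1:2, mcfg, tcfg, ccfg = NULL,
                             test_fraction = 1/3, split_seed = 1L) {
  stopifnot(all(ratios > 0), all(ratios < 1))
  labels <- event_labels(events)
  test_idx <- sort(unlist(lapply(unique(labels), function(cl) {
    members <- which(labels == cl)
    with_seed(mix_seed(split_seed, match(cl, unique(labels))),
              members[sample.int(length(members),
                                 max(1L, round(test_fraction * length(members))))])
  })))
  test_set <- subset_events(events, test_idx)
  train_set <- subset_events(events, setdiff(seq_along(labels), test_idx))
  rows <- list()
  for (r in ratios) {
    for (s in seeds) {
      tcfg_rs <- tcfg
      tcfg_rs$seed <- mix_seed(tcfg$seed, s, round(1000 * r))
      tcfg_rs$mask_ratio <- r
      rep_rs <- train_and_eval(train_set, test_set, mcfg, tcfg_rs, ccfg,
                               pretrain_first = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ratio = r, seed = s, accuracy = rep_rs$accuracy, f1 = rep_rs$f1)
    }
  }
  do.call(rbind, rows)
}

#' Export event embeddings
#'
#' Writes (or returns) the pooled encoder embedding `z` of every event, for
#' downstream projection (t-SNE/UMAP) and inspection of representation quality
#' across training stages.
#'
#' @param events A fixed-length [event_set].
#' @param ckpt An `mae_checkpoint`; ignored when `stage = "random_init"`.
#' @param stage Provenance tag recorded in the output: `"random_init"` (fresh
#'   seeded weights), `"pretrained"`, `"scratch"` or `"finetuned"`.
#' @param path Optional TSV destination; header comment lines record stage and
#'   seed.
#' @param mcfg Required for `stage = "random_init"`.
#' @param seed Weight seed for `stage = "random_init"`.
#' @return Tibble: `id`, `label`, `z1..zd` (invisibly when `path` is given).
#' @export
export_embeddings <- function(events, ckpt = NULL,
                              stage = c("finetuned", "pretrained", "scratch",
                                        "random_init"),
                              path = NULL, mcfg = NULL, seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(inherits(events, "event_set"))
  if (stage == "random_init") {
    if (is.null(mcfg)) stopf("export_embeddings: random_init requires mcfg")
    sb <- segment_batch(events, mcfg$w)
    model <- mae_model(mcfg, n_positions = sb$L, seed = seed)
  } else {
    stopifnot(inherits(ckpt, "mae_checkpoint"))
    model <- checkpoint_model(ckpt)
    sb <- segment_batch(events, ckpt$mcfg$w)
    seed <- ckpt$tcfg$seed
  }
  z <- embed_event(model, sb)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  out <- cbind(tibble::tibble(id = sb$ids, label = sb$labels),
               tibble::as_tibble(z))
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# stage=%s seed=%d d=%d", stage, seed, ncol(z)), con)
    utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
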