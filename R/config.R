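#' Model configuration for the attention autoencoder
#'
#' Collects every architectural hyperparameter of the masked autoencoder in one
#' validated object. The defaults are the reference settings used throughout the
#' package: per-position embedding dimension `d = 64`, per-head key/value
#' dimensions `d_k = d_v = 64`, 8 attention layers in both the encoder and the
#' decoder, 4 heads per layer, feedforward dropout `p1 = 0.2`, feedforward
#' hidden width `4 * d`, and subsequence (token) length `w = 12` sampling
#' points — sized to the average per-amino-acid signal span of an ultrathin
#' solid-state pore read.
#'
#' @param d Integer, embedding dimension of each projected subsequence.
#' @param d_k,d_v Integers, per-head key and value dimensions.
#' @param n_layers Integer, attention layers in the encoder and in the decoder.
#' @param h Integer, attention heads per layer.
#' @param p1 Dropout rate inside each feedforward sublayer (training only).
#' @param ffn_dim Integer, hidden width of the feedforward sublayer.
#' @param w Integer, subsequence length in sampling points.
#' @param backbone `"attention"` for multi-head self-attention mixing layers,
#'   `"cnn"` for the ablation variant in which every attention sublayer is
#'   replaced by a same-width kernel-3 1-D convolution block (feedforward
#'   sublayers kept), keeping depth and dimensions comparable.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d = 64L, d_k = 64L, d_v = 64L, n_layers = 8L, h = 4L,
                         p1 = 0.2, ffn_dim = 4L * d, w = 12L,
                         backbone = c("attention", "cnn")) {
  backbone <- match.arg(backbone)
  for (nm in c("d", "d_k", "d_v", "n_layers", "h", "ffn_dim", "w")) {
    v <- get(nm)
    if (!is_count(v)) stopf("model_config: '%s' must be a positive integer", nm)
  }
  if (!is.numeric(p1) || length(p1) != 1L || p1 < 0 || p1 >= 1)
    stopf("model_config: 'p1' must be in [0, 1)")
  structure(list(d = as.integer(d), d_k = as.integer(d_k), d_v = as.integer(d_v),
                 n_layers = as.integer(n_layers), h = as.integer(h), p1 = p1,
                 ffn_dim = as.integer(ffn_dim), w = as.integer(w),
                 backbone = backbone),
            class = "model_config")
}

#' Classifier-head configuration
#'
#' The fine-tuning head maps the pooled event embedding `z` (length `d`) through
#' one hidden layer of width `d_c` (default 256) with dropout `p2 = 0.2` to `M`
#' class logits.
#'
#' @param M Integer, number of classes (>= 2).
#' @param d_c Integer, hidden width of the first classifier layer.
#' @param p2 Dropout rate between the two classifier layers (training only).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(M, d_c = 256L, p2 = 0.2) {
  if (!is_count(M) || M < 2) stopf("classifier_config: 'M' must be an integer >= 2")
  if (!is_count(d_c)) stopf("classifier_config: 'd_c' must be a positive integer")
  if (!is.numeric(p2) || length(p2) != 1L || p2 < 0 || p2 >= 1)
    stopf("classifier_config: 'p2' must be in [0, 1)")
  structure(list(M = as.integer(M), d_c = as.integer(d_c), p2 = p2),
            class = "classifier_config")
}

#' Training configuration
#'
#' Optimizer and schedule settings for both training stages. Defaults follow the
#' reference recipe: 300 pretraining epochs with Adam at learning rate `1e-3`
#' and batch size 128; 300 fine-tuning epochs with AdamW (weight decay `1e-4`)
#' under cosine annealing that decays the learning rate to
#' `lr * lr_floor_fraction` (1 % of the initial rate) by the final epoch; mask
#' ratio `r = 0.6` during pretraining.
#'
#' @param epochs_pretrain,epochs_finetune Integers, epochs per stage.
#' @param batch_size Integer, events per gradient step.
#' @param lr Initial learning rate (both stages).
#' @param weight_decay AdamW decoupled weight-decay coefficient (fine-tune only).
#' @param lr_floor_fraction Final learning rate as a fraction of `lr` under the
#'   cosine schedule.
#' @param optimizer_pretrain,optimizer_finetune Optimizer names; only
#'   `"adam"` / `"adamw"` are available.
#' @param schedule_finetune `"cosine_to_floor"` or `"none"`.
#' @param seed Integer seed controlling weight initialization, data shuffling,
#'   per-epoch mask plans and dropout.
#' @param mask_ratio Fraction `r` of subsequences masked during pretraining.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs_pretrain = 300L, epochs_finetune = 300L,
                         batch_size = 128L, lr = 1e-3, weight_decay = 1e-4,
                         lr_floor_fraction = 0.01,
                         optimizer_pretrain = "adam",
                         optimizer_finetune = "adamw",
                         schedule_finetune = c("cosine_to_floor", "none"),
                         seed = 1L, mask_ratio = 0.6) {
  schedule_finetune <- match.arg(schedule_finetune)
  optimizer_pretrain <- match.arg(optimizer_pretrain, "adam")
  optimizer_finetune <- match.arg(optimizer_finetune, "adamw")
  for (nm in c("epochs_pretrain", "epochs_finetune", "batch_size")) {
    if (!is_count(get(nm))) stopf("train_config: '%s' must be a positive integer", nm)
  }
  if (!is.numeric(lr) || lr <= 0) stopf("train_config: 'lr' must be positive")
  if (!is.numeric(weight_decay) || weight_decay < 0)
    stopf("train_config: 'weight_decay' must be >= 0")
  if (!is.numeric(lr_floor_fraction) || lr_floor_fraction <= 0 || lr_floor_fraction > 1)
    stopf("train_config: 'lr_floor_fraction' must be in (0, 1]")
  if (!is.numeric(mask_ratio) || mask_ratio <= 0 || mask_ratio >= 1)
    stopf("train_config: 'mask_ratio' must be in (0, 1)")
  structure(list(epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 lr_floor_fraction = lr_floor_fraction,
                 optimizer_pretrain = optimizer_pretrain,
                 optimizer_finetune = optimizer_finetune,
                 schedule_finetune = schedule_finetune,
                 seed = as.integer(seed), mask_ratio = mask_ratio),
            class = "train_config")
}

#' Cosine annealing learning-rate schedule
#'
#' Learning rate for `epoch` (1-based) of `n_epochs`, decaying from `lr` at the
#' first epoch to `lr * floor_fraction` at the final epoch:
#' `lr_t = lr_min + (lr - lr_min) * (1 + cos(pi * (t - 1) / (E - 1))) / 2`.
#' Both endpoints are exact; with a single epoch the rate is `lr`.
#'
#' @param epoch Integer in `1:n_epochs`.
#' @param n_epochs Total epochs.
#' @param lr Initial learning rate.
#' @param floor_fraction Final rate as a fraction of `lr`.
#' @return The learning rate, a scalar.
#' @export
cosine_lr <- function(epoch, n_epochs, lr, floor_fraction = 0.01) {
  stopifnot(epoch >= 1, epoch <= n_epochs)
  if (n_epochs == 1L) return(lr)
  lr_min <- lr * floor_fraction
  lr_min + (lr - lr_min) * (1 + cos(pi * (epoch - 1) / (n_epochs - 1))) / 2
}
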