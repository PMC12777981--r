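#' Build an asymmetric attention autoencoder
#'
#' Constructs the full model: a shared affine input projection mapping each
#' length-`w` subsequence to `d` dimensions, a learned positional-embedding
#' table (one table shared by encoder and decoder), a learned mask-token
#' vector, `n_layers` mixing+feedforward blocks for the encoder and for the
#' decoder (post-norm residual blocks, GELU feedforward), and — when `ccfg` is
#' given — a two-layer classifier head on the pooled event embedding.
#'
#' The autoencoder is asymmetric in how it is used, not in width: during
#' pretraining the encoder sees the visible and the masked subsequences as two
#' separate sequences, while the decoder processes all `L` positions in
#' parallel (visible positions carrying encoder outputs, masked positions a
#' shared mask token plus their positional embedding).
#'
#' @param mcfg A [model_config].
#' @param n_positions Number of subsequence positions `L` the model is built
#'   for (positional table size).
#' @param ccfg Optional [classifier_config] for the fine-tuning head.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mae_model` with elements `weights`, `mcfg`,
#'   `ccfg`, `L`.
#' @export
mae_model <- function(mcfg, n_positions, ccfg = NULL, seed = 1L) {
  stopifnot(inherits(mcfg, "model_config"))
  if (!is_count(n_positions) || n_positions < 2L)
    stopf("mae_model: n_positions must be an integer >= 2")
  weights <- with_seed(seed, {
    w <- list(
      proj = list(W = xavier(mcfg$w, mcfg$d), b = rep(0, mcfg$d)),
      pos = rmat(n_positions, mcfg$d, 0.02),
      mask_token = stats::rnorm(mcfg$d, sd = 0.02),
      enc = stack_init(mcfg),
      dec = stack_init(mcfg))
    if (!is.null(ccfg)) w$clf <- clf_init(mcfg$d, ccfg)
    w
  })
  structure(list(weights = weights, mcfg = mcfg, ccfg = ccfg,
                 L = as.integer(n_positions), seed = as.integer(seed)),
            class = "mae_model")
}

#' Number of trainable parameters
#' @param model An `mae_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) length(tree_flatten(model$weights))

# Positional indices for a full event-major batch: 1..L repeated B times.
full_positions <- function(B, L) rep(seq_len(L), B)

# Row indices in the (B*L)-row batch matrix selected by per-event index lists.
# idx_list: list of B integer vectors (same length each).
gather_rows <- function(idx_list, L) {
  B <- length(idx_list)
  unlist(lapply(seq_len(B), function(b) (b - 1L) * L + idx_list[[b]]),
         use.names = FALSE)
}

latent_batch <- function(values, B, Ltok, positions, stage) {
  structure(list(values = values, B = as.integer(B), Ltok = as.integer(Ltok),
                 positions = positions, stage = stage),
            class = "latent_batch")
}

# Normalize a plan argument into a list of B mask_plan objects.
plans_for_batch <- function(plan, B) {
  if (inherits(plan, "mask_plan")) return(rep(list(plan), B))
  if (is.list(plan) && length(plan) == B &&
      all(vapply(plan, inherits, TRUE, "mask_plan"))) return(plan)
  stopf("expected one mask_plan or a list of %d mask_plans", B)
}

#' Project segmented events into the latent space
#'
#' Applies the shared affine map to every length-`w` subsequence and adds the
#' learned positional embedding of its index. All events in the batch must
#' share `(L, w)`.
#'
#' @param model An `mae_model`.
#' @param segments A list of `segmented_event`s, a single `segmented_event`, or
#'   a batch from the internal segmenter.
#' @return A `latent_batch` with stage `"projected"`, values `(B * L) x d`.
#' @export
project <- function(model, segments) {
  stopifnot(inherits(model, "mae_model"))
  if (inherits(segments, "segmented_event")) segments <- list(segments)
  if (is.list(segments) && !is.null(segments$seg)) {
    seg <- segments$seg; B <- segments$B; L <- segments$L
  } else {
    Ls <- vapply(segments, `[[`, 0L, "L")
    ws <- vapply(segments, `[[`, 0L, "w")
    if (length(unique(Ls)) != 1L || length(unique(ws)) != 1L)
      stopf("project: ragged batch — events disagree on (L, w)")
    B <- length(segments); L <- Ls[1L]
    seg <- do.call(rbind, lapply(segments, `[[`, "subsequences"))
  }
  if (ncol(seg) != model$mcfg$w)
    stopf("project: subsequence length %d but model expects w = %d",
          ncol(seg), model$mcfg$w)
  if (L != model$L)
    stopf("project: batch has L = %d but model was built for L = %d", L, model$L)
  pos_idx <- full_positions(B, L)
  X <- add_rowvec(seg %*% model$weights$proj$W, model$weights$proj$b) +
    model$weights$pos[pos_idx, , drop = FALSE]
  latent_batch(X, B, L, matrix(pos_idx, nrow = B, byrow = TRUE), "projected")
}

#' Run the encoder over projected latents
#'
#' Applies `n_layers` blocks of (multi-head self-attention over the selected
#' positions, then feedforward), with residual connections and layer
#' normalization, in evaluation mode (dropout off; deterministic). `mode`
#' selects which positions take part: the full event, only the visible
#' positions of a mask plan, or only the masked positions (the branch whose
#' output serves as the reconstruction target).
#'
#' @param model An `mae_model`.
#' @param latents A `latent_batch` with stage `"projected"`.
#' @param mode `"full"`, `"visible_only"` or `"masked_only"`.
#' @param plan A `mask_plan` (or list of per-event plans); required unless
#'   `mode = "full"`.
#' @return A `latent_batch` with stage `"encoded"`; only the selected columns
#'   are present, carrying their original position indices.
#' @export
encode <- function(model, latents, mode = c("full", "visible_only", "masked_only"),
                   plan = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(latents, "latent_batch"))
  if (latents$stage != "projected")
    stopf("encode: latents must be at stage 'projected'")
  B <- latents$B; L <- latents$Ltok
  if (mode == "full") {
    idx_list <- rep(list(seq_len(L)), B)
  } else {
    if (is.null(plan)) stopf("encode: mode '%s' requires a mask plan", mode)
    plans <- plans_for_batch(plan, B)
    field <- if (mode == "visible_only") "visible_idx" else "masked_idx"
    idx_list <- lapply(plans, `[[`, field)
  }
  Ltok <- length(idx_list[[1L]])
  rows <- gather_rows(idx_list, L)
  x <- latents$values[rows, , drop = FALSE]
  y <- stack_fwd(x, model$weights$enc, B, Ltok, model$mcfg, train = FALSE)$y
  latent_batch(y, B, Ltok,
               matrix(unlist(idx_list), nrow = B, byrow = TRUE), "encoded")
}

#' Assemble the decoder input from encoded visible positions
#'
#' Returns an `L`-position batch in which visible columns carry the encoder
#' outputs and masked columns carry the shared learned mask-token vector plus
#' the positional embedding of their original index.
#'
#' @param model An `mae_model`.
#' @param encoded_visible `latent_batch` from
#'   `encode(..., mode = "visible_only")`, covering exactly the plan's visible
#'   positions.
#' @param plan The same `mask_plan` (or per-event list).
#' @return A `latent_batch` with stage `"decoder_input"` and all `L` positions.
#' @export
build_decoder_input <- function(model, encoded_visible, plan) {
  stopifnot(inherits(encoded_visible, "latent_batch"))
  if (encoded_visible$stage != "encoded")
    stopf("build_decoder_input: expected an encoded latent_batch")
  B <- encoded_visible$B; L <- model$L
  plans <- plans_for_batch(plan, B)
  for (b in seq_len(B)) {
    if (!identical(as.integer(encoded_visible$positions[b, ]),
                   as.integer(plans[[b]]$visible_idx)))
      stopf("build_decoder_input: encoded positions do not match plan (event %d)", b)
  }
  d <- model$mcfg$d
  x <- matrix(0, B * L, d)
  vis_rows <- gather_rows(lapply(plans, `[[`, "visible_idx"), L)
  mask_rows <- gather_rows(lapply(plans, `[[`, "masked_idx"), L)
  mask_pos <- unlist(lapply(plans, `[[`, "masked_idx"), use.names = FALSE)
  x[vis_rows, ] <- encoded_visible$values
  x[mask_rows, ] <- matrix(model$weights$mask_token, length(mask_rows), d,
                           byrow = TRUE) +
    model$weights$pos[mask_pos, , drop = FALSE]
  latent_batch(x, B, L, matrix(full_positions(B, L), nrow = B, byrow = TRUE),
               "decoder_input")
}

#' Run the decoder over the full assembled input
#'
#' Applies the decoder's `n_layers` blocks over all `L` positions in parallel
#' (evaluation mode). Columns at the plan's masked positions are the predictive
#' representations compared against the encoder targets during pretraining.
#'
#' @param model An `mae_model`.
#' @param decoder_input `latent_batch` from [build_decoder_input()].
#' @return A `latent_batch` with stage `"decoded"`, all `L` positions.
#' @export
decode <- function(model, decoder_input) {
  stopifnot(inherits(decoder_input, "latent_batch"))
  if (decoder_input$stage != "decoder_input")
    stopf("decode: expected a decoder_input latent_batch")
  B <- decoder_input$B; L <- decoder_input$Ltok
  y <- stack_fwd(decoder_input$values, model$weights$dec, B, L, model$mcfg,
                 train = FALSE)$y
  latent_batch(y, B, L, decoder_input$positions, "decoded")
}

#' Mark encoder outputs at masked positions as the reconstruction target
#'
#' The target branch is gradient-isolated: during training no signal flows into
#' the encoder through the targets (without this, the trivial collapse — both
#' branches constant — minimizes the latent reconstruction loss). Values are
#' returned unchanged.
#'
#' @param latents_masked `latent_batch` from
#'   `encode(..., mode = "masked_only")`.
#' @return The same `latent_batch` with attribute `grad_isolated = TRUE`.
#' @export
pretrain_targets <- function(latents_masked) {
  stopifnot(inherits(latents_masked, "latent_batch"))
  attr(latents_masked, "grad_isolated") <- TRUE
  latents_masked
}

#' Latent-space mean-squared reconstruction loss
#'
#' Mean of squared element-wise differences between the decoder's predictive
#' representations and the encoder targets, over all masked positions and all
#' `d` dimensions (and over the batch).
#'
#' @param Fm `latent_batch` of decoder outputs at masked positions.
#' @param Hm `latent_batch` of gradient-isolated encoder targets, same shape.
#' @return A scalar loss.
#' @export
mse_latent_loss <- function(Fm, Hm) {
  a <- if (inherits(Fm, "latent_batch")) Fm$values else as.matrix(Fm)
  b <- if (inherits(Hm, "latent_batch")) Hm$values else as.matrix(Hm)
  if (!identical(dim(a), dim(b))) stopf("mse_latent_loss: shape mismatch")
  mean((a - b)^2)
}

#' Select the masked-position columns of a decoded batch
#'
#' @param decoded `latent_batch` with stage `"decoded"` (all `L` positions).
#' @param plan The `mask_plan` (or per-event list) used for the event.
#' @return A `latent_batch` holding only the masked columns.
#' @export
masked_columns <- function(decoded, plan) {
  stopifnot(inherits(decoded, "latent_batch"))
  B <- decoded$B; L <- decoded$Ltok
  plans <- plans_for_batch(plan, B)
  rows <- gather_rows(lapply(plans, `[[`, "masked_idx"), L)
  latent_batch(decoded$values[rows, , drop = FALSE], B,
               length(plans[[1L]]$masked_idx),
               matrix(unlist(lapply(plans, `[[`, "masked_idx")), nrow = B,
                      byrow = TRUE), decoded$stage)
}

#' Pooled event embedding
#'
#' Fine-tuning path: the full-event encoder output `H` (`L x d` per event) is
#' reduced by global average pooling to a single `d`-vector `z` per event.
#'
#' @param model An `mae_model`.
#' @param segments Segmented event batch (as for [project()]).
#' @return A `B x d` matrix of event embeddings.
#' @export
embed_event <- function(model, segments) {
  H <- encode(model, project(model, segments), mode = "full")
  pool_rows(H$values, H$B, H$Ltok)
}

pool_rows <- function(x, B, L) {
  z <- matrix(0, B, ncol(x))
  for (b in seq_len(B)) z[b, ] <- colMeans(x[((b - 1L) * L + 1L):(b * L), ,
                                             drop = FALSE])
  z
}

#' Classifier head on pooled embeddings
#'
#' Two-layer map `d -> d_c -> M` with ReLU nonlinearity (dropout `p2` between
#' the layers is active only during training; this evaluation-mode call is
#' deterministic). The outputs are unnormalized logits; apply [softmax_rows()]
#' for class probabilities.
#'
#' @param model An `mae_model` built with a [classifier_config].
#' @param z `B x d` matrix of pooled embeddings.
#' @return `B x M` matrix of logits.
#' @export
classify <- function(model, z) {
  stopifnot(inherits(model, "mae_model"))
  if (is.null(model$weights$clf))
    stopf("classify: model has no classifier head (supply ccfg to mae_model)")
  clf_fwd(as.matrix(z), model$weights$clf, model$ccfg, train = FALSE)$logits
}

#' Row-wise softmax
#'
#' Converts logits to a probability distribution per row:
#' `p_c = exp(y_c) / sum_j exp(y_j)` (computed with the max-subtraction trick).
#'
#' @param logits Numeric matrix.
#' @return Matrix of the same shape; rows sum to 1.
#' @export
softmax_rows <- function(logits) row_softmax(as.matrix(logits))

# ---- training-step internals ---------------------------------------------------
# These run the same forward maps as the public operations but keep caches and
# return analytic gradients. `weights` is model$weights.

# Pretraining step: latent reconstruction of masked subsequences.
# seg: (B*L) x w, plans: list of B mask_plan. Returns loss and gradient tree
# over proj/pos/mask_token/enc/dec.
pretrain_step <- function(weights, seg, B, L, plans, mcfg, train = TRUE) {
  d <- mcfg$d
  pos_idx <- full_positions(B, L)
  X <- add_rowvec(seg %*% weights$proj$W, weights$proj$b) +
    weights$pos[pos_idx, , drop = FALSE]

  vis_list <- lapply(plans, `[[`, "visible_idx")
  mask_list <- lapply(plans, `[[`, "masked_idx")
  Lv <- length(vis_list[[1L]]); Lm <- length(mask_list[[1L]])
  vis_rows <- gather_rows(vis_list, L)
  mask_rows <- gather_rows(mask_list, L)
  mask_pos <- unlist(mask_list, use.names = FALSE)

  enc_v <- stack_fwd(X[vis_rows, , drop = FALSE], weights$enc, B, Lv, mcfg, train)
  # Target branch: encoder over masked subsequences, gradient-isolated, so no
  # caches are kept and nothing is backpropagated through it. Dropout stays off
  # in the target branch to keep the regression target stable.
  Hm <- stack_fwd(X[mask_rows, , drop = FALSE], weights$enc, B, Lm, mcfg,
                  train = FALSE)$y

  dec_in <- matrix(0, B * L, d)
  dec_in[vis_rows, ] <- enc_v$y
  dec_in[mask_rows, ] <- matrix(weights$mask_token, length(mask_rows), d,
                                byrow = TRUE) +
    weights$pos[mask_pos, , drop = FALSE]
  dec <- stack_fwd(dec_in, weights$dec, B, L, mcfg, train)
  Fm <- dec$y[mask_rows, , drop = FALSE]
  loss <- mean((Fm - Hm)^2)

  # backward
  dF_full <- matrix(0, B * L, d)
  dF_full[mask_rows, ] <- 2 * (Fm - Hm) / length(Fm)
  dec_b <- stack_bwd(dF_full, dec, weights$dec, B, L, mcfg)
  ddec_in <- dec_b$dx
  d_mask_token <- colSums(ddec_in[mask_rows, , drop = FALSE])
  dpos <- matrix(0, nrow(weights$pos), d)
  mp <- rowsum(ddec_in[mask_rows, , drop = FALSE], group = mask_pos)
  dpos[as.integer(rownames(mp)), ] <- dpos[as.integer(rownames(mp)), ] + mp

  enc_b <- stack_bwd(ddec_in[vis_rows, , drop = FALSE], enc_v, weights$enc,
                     B, Lv, mcfg)
  dXv <- enc_b$dx
  vp <- rowsum(dXv, group = unlist(vis_list, use.names = FALSE))
  dpos[as.integer(rownames(vp)), ] <- dpos[as.integer(rownames(vp)), ] + vp
  dW <- crossprod(seg[vis_rows, , drop = FALSE], dXv)
  db <- colSums(dXv)

  grads <- list(proj = list(W = dW, b = db), pos = dpos,
                mask_token = d_mask_token, enc = enc_b$dp, dec = dec_b$dp)
  list(loss = loss, grads = grads)
}

# Fine-tuning step: cross-entropy on pooled full-event embeddings.
# y: integer class in 1..M per event. Returns loss, gradients over
# proj/pos/enc/clf, and the probability matrix.
finetune_step <- function(weights, seg, B, L, y, mcfg, ccfg, train = TRUE,
                          freeze_encoder = FALSE) {
  pos_idx <- full_positions(B, L)
  X <- add_rowvec(seg %*% weights$proj$W, weights$proj$b) +
    weights$pos[pos_idx, , drop = FALSE]
  enc <- stack_fwd(X, weights$enc, B, L, mcfg, train)
  z <- pool_rows(enc$y, B, L)
  cl <- clf_fwd(z, weights$clf, ccfg, train)
  p <- row_softmax(cl$logits)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))

  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B
  cb <- clf_bwd(dlogits, cl, weights$clf)
  grads <- list(clf = cb$dp)
  if (!freeze_encoder) {
    dH <- cb$dz[rep(seq_len(B), each = L), , drop = FALSE] / L
    eb <- stack_bwd(dH, enc, weights$enc, B, L, mcfg)
    dX <- eb$dx
    dpos_tab <- rowsum(dX, group = pos_idx)
    grads$enc <- eb$dp
    grads$pos <- dpos_tab[order(as.integer(rownames(dpos_tab))), , drop = FALSE]
    grads$proj <- list(W = crossprod(seg, dX), b = colSums(dX))
  }
  list(loss = loss, grads = grads, probs = p)
}
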