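pm <- asNamespace("poremae")

test_that("projection is affine with additive positional embeddings", {
  mcfg <- tiny_mcfg()
  L <- 5L
  model <- mae_model(mcfg, n_positions = L, seed = 2)
  seg <- withr::with_seed(1, lapply(1:3, function(i)
    segment_trace(rnorm(L * mcfg$w), mcfg$w)))
  lb <- project(model, seg)
  expect_identical(dim(lb$values), c(3L * L, mcfg$d))
  expect_identical(lb$stage, "projected")

  # zero weights, bias and positional table -> all-zero latents
  z <- model
  z$weights$proj$W[] <- 0; z$weights$proj$b[] <- 0; z$weights$pos[] <- 0
  expect_true(all(project(z, seg)$values == 0))

  # identical subsequences at two positions differ exactly by the positional rows
  rep_seg <- segment_trace(rep(1:3, L), mcfg$w)  # identical rows
  out <- project(model, rep_seg)$values
  expect_equal(out[2, ] - out[1, ],
               model$weights$pos[2, ] - model$weights$pos[1, ], tolerance = 1e-12)

  # ragged batches are rejected
  bad <- list(segment_trace(rnorm(15), 3), segment_trace(rnorm(18), 3))
  expect_error(project(model, bad), "ragged")
})

test_that("encoder modes select the plan's positions and keep their indices", {
  mcfg <- tiny_mcfg()
  L <- 42L
  model <- mae_model(mcfg, n_positions = L, seed = 3)
  seg <- withr::with_seed(2, segment_trace(rnorm(L * mcfg$w), mcfg$w))
  lb <- project(model, seg)
  plan <- make_mask(L, 0.6, seed = 5)

  full <- encode(model, lb, "full")
  expect_identical(full$Ltok, L)
  vis <- encode(model, lb, "visible_only", plan)
  expect_identical(vis$Ltok, 17L)
  expect_identical(as.integer(vis$positions[1, ]), plan$visible_idx)
  msk <- encode(model, lb, "masked_only", plan)
  expect_identical(msk$Ltok, 25L)
  expect_error(encode(model, lb, "visible_only"), "requires a mask plan")
})

test_that("self-attention stacks are permutation-equivariant with zeroed positions", {
  mcfg <- tiny_mcfg()
  L <- 7L
  model <- mae_model(mcfg, n_positions = L, seed = 4)
  model$weights$pos[] <- 0
  x <- withr::with_seed(3, matrix(rnorm(L * mcfg$w), L, mcfg$w))
  perm <- withr::with_seed(4, sample(L))
  out1 <- encode(model, project(model, segment_trace(as.vector(t(x)), mcfg$w)),
                 "full")$values
  out2 <- encode(model, project(model, segment_trace(as.vector(t(x[perm, ])),
                                                     mcfg$w)), "full")$values
  expect_lt(max(abs(out2 - out1[perm, ])), 1e-5)
})

test_that("decoder input places mask tokens and encoder outputs correctly", {
  mcfg <- tiny_mcfg()
  L <- 5L
  model <- mae_model(mcfg, n_positions = L, seed = 6)
  seg <- withr::with_seed(5, segment_trace(rnorm(L * mcfg$w), mcfg$w))
  lb <- project(model, seg)
  plan <- structure(list(masked_idx = c(2L, 4L), visible_idx = c(1L, 3L, 5L),
                         r = 0.4, seed = 0L, L = L), class = "mask_plan")
  enc_v <- encode(model, lb, "visible_only", plan)
  dec_in <- build_decoder_input(model, enc_v, plan)
  expect_identical(dec_in$Ltok, L)
  expect_equal(dec_in$values[c(1, 3, 5), ], enc_v$values, tolerance = 1e-15)
  for (i in c(2L, 4L))
    expect_equal(dec_in$values[i, ],
                 model$weights$mask_token + model$weights$pos[i, ],
                 tolerance = 1e-15)

  # decode keeps all L positions and d dims; eval mode is deterministic
  dec <- decode(model, dec_in)
  expect_identical(dim(dec$values), c(L, mcfg$d))
  expect_identical(decode(model, dec_in)$values, dec$values)

  # mismatched plan is rejected
  plan2 <- make_mask(L, 0.6, seed = 1)
  if (!identical(plan2$visible_idx, plan$visible_idx))
    expect_error(build_decoder_input(model, enc_v, plan2), "do not match")

  # mask-token rows are plan-independent: positions masked under both plans
  # carry identical (mask_token + positional) rows, while visible rows differ
  # because the encoder's attention context differs between plans
  enc_v2 <- encode(model, lb, "visible_only", plan2)
  dec_in2 <- build_decoder_input(model, enc_v2, plan2)
  both_masked <- intersect(plan$masked_idx, plan2$masked_idx)
  expect_gt(length(both_masked), 0L)
  expect_equal(dec_in$values[both_masked, ], dec_in2$values[both_masked, ],
               tolerance = 1e-12)
})

test_that("latent MSE matches a brute-force oracle and closed forms", {
  expect_identical(mse_latent_loss(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(mse_latent_loss(matrix(c(1, 0, 0, 1), 2), matrix(0, 2, 2)), 0.5)
  for (i in 1:100) {
    nd <- withr::with_seed(i, sample(1:6, 2))
    a <- withr::with_seed(i + 1, matrix(rnorm(nd[1] * nd[2]), nd[1]))
    b <- withr::with_seed(i + 2, matrix(rnorm(nd[1] * nd[2]), nd[1]))
    brute <- 0
    for (r in seq_len(nd[1])) for (c in seq_len(nd[2]))
      brute <- brute + (a[r, c] - b[r, c])^2
    expect_equal(mse_latent_loss(a, b), brute / (nd[1] * nd[2]),
                 tolerance = 1e-10)
  }
  expect_error(mse_latent_loss(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("pooled embeddings equal the per-dimension mean over positions", {
  mcfg <- tiny_mcfg()
  L <- 6L
  model <- mae_model(mcfg, n_positions = L, seed = 8)
  seg <- withr::with_seed(6, lapply(1:2, function(i)
    segment_trace(rnorm(L * mcfg$w), mcfg$w)))
  z <- embed_event(model, seg)
  expect_identical(dim(z), c(2L, mcfg$d))
  H <- encode(model, project(model, seg), "full")
  for (b in 1:2) {
    rows <- ((b - 1) * L + 1):(b * L)
    brute <- colSums(H$values[rows, ]) / L
    expect_equal(z[b, ], brute, tolerance = 1e-10)
  }
  # symmetry: pooling rows u and -u gives zero
  expect_equal(pm$pool_rows(rbind(1:4, -(1:4)), 1L, 2L), matrix(0, 1, 4))
})

test_that("classifier head is linear at zero weights and shapes to M classes", {
  mcfg <- tiny_mcfg()
  ccfg <- classifier_config(M = 8L, d_c = 16L)
  model <- mae_model(mcfg, n_positions = 4L, ccfg = ccfg, seed = 9)
  z <- withr::with_seed(7, matrix(rnorm(3 * mcfg$d), 3))
  logits <- classify(model, z)
  expect_identical(dim(logits), c(3L, 8L))
  z0 <- model
  z0$weights$clf <- tree_map0 <- rapply(model$weights$clf, function(x) x * 0,
                                        how = "replace")
  expect_true(all(classify(z0, z) == 0))
  expect_identical(classifier_config(M = 3)$d_c, 256L)
})

test_that("pretrain-step gradients match finite differences with an isolated target", {
  mcfg <- tiny_mcfg()
  L <- 5L; B <- 2L
  seg <- withr::with_seed(11, matrix(rnorm(B * L * mcfg$w), B * L, mcfg$w))
  model <- mae_model(mcfg, n_positions = L, seed = 12)
  w <- model$weights
  plans <- list(make_mask(L, 0.6, 21), make_mask(L, 0.6, 22))
  st <- pm$pretrain_step(w, seg, B, L, plans, mcfg, train = FALSE)
  expect_true(is.finite(st$loss))

  # forward pass with the target representation frozen (isolation semantics)
  msk <- lapply(plans, `[[`, "masked_idx")
  vis <- lapply(plans, `[[`, "visible_idx")
  mr <- pm$gather_rows(msk, L); vr <- pm$gather_rows(vis, L)
  pos_idx <- pm$full_positions(B, L)
  X0 <- pm$add_rowvec(seg %*% w$proj$W, w$proj$b) + w$pos[pos_idx, ]
  Hm0 <- pm$stack_fwd(X0[mr, ], w$enc, B, length(msk[[1]]), mcfg, FALSE)$y
  loss_fixed_target <- function(wv) {
    w2 <- pm$tree_unflatten(w, wv)
    X <- pm$add_rowvec(seg %*% w2$proj$W, w2$proj$b) + w2$pos[pos_idx, ]
    ev <- pm$stack_fwd(X[vr, ], w2$enc, B, length(vis[[1]]), mcfg, FALSE)
    dec_in <- matrix(0, B * L, mcfg$d)
    dec_in[vr, ] <- ev$y
    dec_in[mr, ] <- matrix(w2$mask_token, length(mr), mcfg$d, byrow = TRUE) +
      w2$pos[unlist(msk), ]
    Fm <- pm$stack_fwd(dec_in, w2$dec, B, L, mcfg, FALSE)$y[mr, ]
    mean((Fm - Hm0)^2)
  }
  wv <- pm$tree_flatten(w)
  ga <- pm$tree_flatten(st$grads)
  idx <- withr::with_seed(13, sort(sample(length(wv), 60)))
  gn <- numeric_gradient(loss_fixed_target, wv, idx)
  expect_lt(max(abs(gn - ga[idx])), 1e-6)

  # without isolation the finite-difference gradient (target recomputed) differs
  loss_live_target <- function(wv) {
    w2 <- pm$tree_unflatten(w, wv)
    pm$pretrain_step(w2, seg, B, L, plans, mcfg, train = FALSE)$loss
  }
  gn_live <- numeric_gradient(loss_live_target, wv, idx)
  expect_gt(max(abs(gn_live - ga[idx])), 1e-3)
})

test_that("finetune-step gradients match finite differences", {
  mcfg <- tiny_mcfg()
  ccfg <- classifier_config(M = 3L, d_c = 7L, p2 = 0)
  L <- 5L; B <- 2L
  seg <- withr::with_seed(14, matrix(rnorm(B * L * mcfg$w), B * L, mcfg$w))
  model <- mae_model(mcfg, n_positions = L, ccfg = ccfg, seed = 15)
  w <- model$weights
  y <- c(1L, 3L)
  st <- pm$finetune_step(w, seg, B, L, y, mcfg, ccfg, train = FALSE)
  ord <- c("proj", "pos", "enc", "clf")
  wv <- pm$tree_flatten(w[ord])
  ga <- pm$tree_flatten(st$grads[ord])
  f <- function(v) {
    wfull <- w; wfull[ord] <- pm$tree_unflatten(w[ord], v)
    pm$finetune_step(wfull, seg, B, L, y, mcfg, ccfg, train = FALSE)$loss
  }
  idx <- withr::with_seed(16, sort(sample(length(wv), 60)))
  expect_lt(max(abs(numeric_gradient(f, wv, idx) - ga[idx])), 1e-6)
})

test_that("cnn-backbone gradients are exact and signatures are drop-in", {
  mcfg <- tiny_mcfg(backbone = "cnn")
  L <- 5L; B <- 2L
  seg <- withr::with_seed(17, matrix(rnorm(B * L * mcfg$w), B * L, mcfg$w))
  model <- mae_model(mcfg, n_positions = L, seed = 18)
  w <- model$weights
  plans <- list(make_mask(L, 0.6, 31), make_mask(L, 0.6, 32))
  st <- pm$pretrain_step(w, seg, B, L, plans, mcfg, train = FALSE)
  msk <- lapply(plans, `[[`, "masked_idx"); vis <- lapply(plans, `[[`, "visible_idx")
  mr <- pm$gather_rows(msk, L); vr <- pm$gather_rows(vis, L)
  pos_idx <- pm$full_positions(B, L)
  X0 <- pm$add_rowvec(seg %*% w$proj$W, w$proj$b) + w$pos[pos_idx, ]
  Hm0 <- pm$stack_fwd(X0[mr, ], w$enc, B, length(msk[[1]]), mcfg, FALSE)$y
  f <- function(wv) {
    w2 <- pm$tree_unflatten(w, wv)
    X <- pm$add_rowvec(seg %*% w2$proj$W, w2$proj$b) + w2$pos[pos_idx, ]
    ev <- pm$stack_fwd(X[vr, ], w2$enc, B, length(vis[[1]]), mcfg, FALSE)
    dec_in <- matrix(0, B * L, mcfg$d)
    dec_in[vr, ] <- ev$y
    dec_in[mr, ] <- matrix(w2$mask_token, length(mr), mcfg$d, byrow = TRUE) +
      w2$pos[unlist(msk), ]
    mean((pm$stack_fwd(dec_in, w2$dec, B, L, mcfg, FALSE)$y[mr, ] - Hm0)^2)
  }
  wv <- pm$tree_flatten(w)
  ga <- pm$tree_flatten(st$grads)
  idx <- withr::with_seed(19, sort(sample(length(wv), 50)))
  expect_lt(max(abs(numeric_gradient(f, wv, idx) - ga[idx])), 1e-6)
  # identical public surface
  lb <- project(model, segment_trace(rnorm(L * mcfg$w), mcfg$w))
  expect_identical(encode(model, lb, "full")$Ltok, L)
})

test_that("evaluation-mode forward maps are bitwise deterministic and counted", {
  mcfg <- tiny_mcfg()
  model <- mae_model(mcfg, n_positions = 6L, seed = 20)
  seg <- withr::with_seed(20, segment_trace(rnorm(18), 3))
  a <- encode(model, project(model, seg), "full")$values
  b <- encode(model, project(model, seg), "full")$values
  expect_identical(a, b)
  # parameter count is a pure function of the architecture
  expect_identical(n_parameters(mae_model(mcfg, 6L, seed = 1)),
                   n_parameters(mae_model(mcfg, 6L, seed = 99)))
  d <- 64L
  default_model <- mae_model(model_config(), n_positions = 42L,
                             ccfg = classifier_config(M = 8L), seed = 1)
  expect_identical(n_parameters(default_model),
                   n_parameters(mae_model(model_config(), 42L,
                                          classifier_config(M = 8L), seed = 2)))
})
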