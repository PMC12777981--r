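# Internal neural-network primitives: forward passes with caches and matching
# analytic backward passes, written on plain matrices so the whole model trains
# through BLAS. Batches are row-stacked, event-major: a batch of B events with
# Ltok positions each is an (B * Ltok) x d matrix whose rows
# (b-1)*Ltok + 1 .. b*Ltok belong to event b.
#
# Gradient correctness is pinned by finite-difference checks in the test suite;
# any change here must keep those green.

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

xavier <- function(nr, nc) rmat(nr, nc, sqrt(2 / (nr + nc)))

# x + v broadcast across rows, via column-major recycling (faster than sweep)
add_rowvec <- function(x, v) x + rep(v, rep.int(nrow(x), length(v)))
mul_rowvec <- function(x, v) x * rep(v, rep.int(nrow(x), length(v)))

row_softmax <- function(S) {
  # subtracting the global max is enough for numerical stability here
  E <- exp(S - max(S))
  E / rowSums(E)
}

# ---- elementwise ---------------------------------------------------------------
# GELU in its tanh form, 0.5*x*(1 + tanh(sqrt(2/pi)*(x + 0.044715*x^3))),
# evaluated in the compiled kernel (src/kernels.cpp).

gelu_fwd <- function(x) cpp_gelu_fwd(x)$y

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  cpp_dropout(x, p)
}
dropout_bwd <- function(dy, cache) if (is.null(cache$mask)) dy else dy * cache$mask

# ---- layer norm ----------------------------------------------------------------

ln_init <- function(d) list(g = rep(1, d), b = rep(0, d))

ln_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  y <- add_rowvec(mul_rowvec(xhat, p$g), p$b)
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  dxhat <- mul_rowvec(dy, p$g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dp = list(g = colSums(dy * xhat), b = colSums(dy)))
}

# ---- multi-head self-attention -------------------------------------------------

attn_init <- function(cfg) {
  d <- cfg$d; hk <- cfg$h * cfg$d_k; hv <- cfg$h * cfg$d_v
  # residual output projection scaled down with depth (stabilizes deep stacks)
  list(Wq = xavier(d, hk), Wk = xavier(d, hk), Wv = xavier(d, hv),
       Wo = xavier(hv, d) / sqrt(2 * cfg$n_layers), bo = rep(0, d))
}

attn_fwd <- function(x, p, B, L, cfg) {
  Q <- x %*% p$Wq; K <- x %*% p$Wk; V <- x %*% p$Wv
  kf <- cpp_attn_fwd(Q, K, V, B, L, cfg$h, cfg$d_k, cfg$d_v)
  y <- add_rowvec(kf$O %*% p$Wo, p$bo)
  list(y = y, x = x, Q = Q, K = K, V = V, O = kf$O, A = kf$A)
}

attn_bwd <- function(dy, cache, p, B, L, cfg) {
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- tcrossprod(dy, p$Wo)
  kb <- cpp_attn_bwd(dO, cache$Q, cache$K, cache$V, cache$A, B, L,
                     cfg$h, cfg$d_k, cfg$d_v)
  dx <- tcrossprod(kb$dQ, p$Wq) + tcrossprod(kb$dK, p$Wk) +
    tcrossprod(kb$dV, p$Wv)
  list(dx = dx,
       dp = list(Wq = crossprod(cache$x, kb$dQ), Wk = crossprod(cache$x, kb$dK),
                 Wv = crossprod(cache$x, kb$dV), Wo = dWo, bo = dbo))
}

# ---- kernel-3 1-D convolution over positions (CNN-backbone ablation) -----------

conv_init <- function(cfg) {
  d <- cfg$d
  list(Wl = xavier(d, d), Wc = xavier(d, d), Wr = xavier(d, d), b = rep(0, d))
}

# Shift rows by one position within each event block, zero at block boundaries.
shift_blocks <- function(x, B, L, by) {
  y <- matrix(0, nrow(x), ncol(x))
  if (L == 1L) return(y)
  keep <- seq_len(L - 1L)
  for (b in seq_len(B)) {
    off <- (b - 1L) * L
    if (by == 1L) y[off + keep + 1L, ] <- x[off + keep, , drop = FALSE]
    else          y[off + keep, ] <- x[off + keep + 1L, , drop = FALSE]
  }
  y
}

conv_fwd <- function(x, p, B, L, cfg) {
  xm1 <- shift_blocks(x, B, L, 1L)   # previous position
  xp1 <- shift_blocks(x, B, L, -1L)  # next position
  a <- add_rowvec(xm1 %*% p$Wl + x %*% p$Wc + xp1 %*% p$Wr, p$b)
  g <- cpp_gelu_fwd(a)
  list(y = g$y, x = x, xm1 = xm1, xp1 = xp1, a = a, t = g$t)
}

conv_bwd <- function(dy, cache, p, B, L, cfg) {
  da <- cpp_gelu_grad(dy, cache$a, cache$t)
  dx <- tcrossprod(da, p$Wc) +
    shift_blocks(tcrossprod(da, p$Wl), B, L, -1L) +
    shift_blocks(tcrossprod(da, p$Wr), B, L, 1L)
  list(dx = dx,
       dp = list(Wl = crossprod(cache$xm1, da), Wc = crossprod(cache$x, da),
                 Wr = crossprod(cache$xp1, da), b = colSums(da)))
}

# ---- feedforward sublayer ------------------------------------------------------

ffn_init <- function(cfg) {
  list(W1 = xavier(cfg$d, cfg$ffn_dim), b1 = rep(0, cfg$ffn_dim),
       W2 = xavier(cfg$ffn_dim, cfg$d) / sqrt(2 * cfg$n_layers),
       b2 = rep(0, cfg$d))
}

ffn_fwd <- function(x, p, cfg, train) {
  a1 <- add_rowvec(x %*% p$W1, p$b1)
  g <- cpp_gelu_fwd(a1)
  dr <- dropout_fwd(g$y, cfg$p1, train)
  y <- add_rowvec(dr$y %*% p$W2, p$b2)
  list(y = y, x = x, a1 = a1, t = g$t, dr = dr)
}

ffn_bwd <- function(dy, cache, p) {
  dW2 <- crossprod(cache$dr$y, dy)
  db2 <- colSums(dy)
  dg <- dropout_bwd(tcrossprod(dy, p$W2), cache$dr)
  da1 <- cpp_gelu_grad(dg, cache$a1, cache$t)
  list(dx = tcrossprod(da1, p$W1),
       dp = list(W1 = crossprod(cache$x, da1), b1 = colSums(da1),
                 W2 = dW2, b2 = db2))
}

# ---- one transformer block (pre-norm residual) ---------------------------------
# Pre-norm: x + Mix(LN(x)), then x + FFN(LN(x)); a final LayerNorm closes each
# stack. Pre-norm keeps gradients well-scaled without a warmup schedule, which
# matters for small-batch CPU training.

block_init <- function(cfg) {
  mix <- if (cfg$backbone == "attention") attn_init(cfg) else conv_init(cfg)
  list(mix = mix, ln1 = ln_init(cfg$d), ffn = ffn_init(cfg), ln2 = ln_init(cfg$d))
}

block_fwd <- function(x, p, B, L, cfg, train) {
  n1c <- ln_fwd(x, p$ln1)
  mixc <- if (cfg$backbone == "attention") attn_fwd(n1c$y, p$mix, B, L, cfg)
          else conv_fwd(n1c$y, p$mix, B, L, cfg)
  r1 <- x + mixc$y
  n2c <- ln_fwd(r1, p$ln2)
  ffnc <- ffn_fwd(n2c$y, p$ffn, cfg, train)
  list(y = r1 + ffnc$y, mixc = mixc, n1c = n1c, n2c = n2c, ffnc = ffnc)
}

block_bwd <- function(dy, cache, p, B, L, cfg) {
  fb <- ffn_bwd(dy, cache$ffnc, p$ffn)
  l2 <- ln_bwd(fb$dx, cache$n2c, p$ln2)
  dr1 <- dy + l2$dx
  mb <- if (cfg$backbone == "attention") attn_bwd(dr1, cache$mixc, p$mix, B, L, cfg)
        else conv_bwd(dr1, cache$mixc, p$mix, B, L, cfg)
  l1 <- ln_bwd(mb$dx, cache$n1c, p$ln1)
  list(dx = dr1 + l1$dx,
       dp = list(mix = mb$dp, ln1 = l1$dp, ffn = fb$dp, ln2 = l2$dp))
}

# ---- a stack of blocks (encoder or decoder) ------------------------------------

stack_init <- function(cfg) {
  list(blocks = lapply(seq_len(cfg$n_layers), function(i) block_init(cfg)),
       ln_f = ln_init(cfg$d))
}

stack_fwd <- function(x, stack, B, L, cfg, train) {
  layers <- stack$blocks
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    caches[[i]] <- block_fwd(x, layers[[i]], B, L, cfg, train)
    x <- caches[[i]]$y
  }
  fin <- ln_fwd(x, stack$ln_f)
  list(y = fin$y, caches = caches, fin = fin)
}

stack_bwd <- function(dy, stack_cache, stack, B, L, cfg) {
  layers <- stack$blocks
  lf <- ln_bwd(dy, stack_cache$fin, stack$ln_f)
  dy <- lf$dx
  dp <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bb <- block_bwd(dy, stack_cache$caches[[i]], layers[[i]], B, L, cfg)
    dy <- bb$dx
    dp[[i]] <- bb$dp
  }
  list(dx = dy, dp = list(blocks = dp, ln_f = lf$dp))
}

# ---- classifier head -----------------------------------------------------------

clf_init <- function(d, ccfg) {
  list(W1 = xavier(d, ccfg$d_c), b1 = rep(0, ccfg$d_c),
       W2 = xavier(ccfg$d_c, ccfg$M), b2 = rep(0, ccfg$M))
}

relu_fwd <- function(x) pmax(x, 0)

clf_fwd <- function(z, p, ccfg, train) {
  a1 <- add_rowvec(z %*% p$W1, p$b1)
  hz <- relu_fwd(a1)
  dr <- dropout_fwd(hz, ccfg$p2, train)
  logits <- add_rowvec(dr$y %*% p$W2, p$b2)
  list(logits = logits, z = z, a1 = a1, dr = dr)
}

clf_bwd <- function(dlogits, cache, p) {
  dW2 <- crossprod(cache$dr$y, dlogits)
  db2 <- colSums(dlogits)
  dh <- dropout_bwd(tcrossprod(dlogits, p$W2), cache$dr)
  da1 <- dh * (cache$a1 > 0)
  list(dz = tcrossprod(da1, p$W1),
       dp = list(W1 = crossprod(cache$z, da1), b1 = colSums(da1),
                 W2 = dW2, b2 = db2))
}

# ---- optimizers ----------------------------------------------------------------

adam_init <- function(w) list(m = tree_zeros_like(w), v = tree_zeros_like(w), t = 0L)

# Adam / AdamW step. `decoupled_wd > 0` applies AdamW-style decoupled weight
# decay (multiplicative shrink by lr * wd before the moment update is added).
adam_step <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      decoupled_wd = 0) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(wi, gi, mi, vi) {
    if (is.list(wi)) {
      out_w <- wi; out_m <- mi; out_v <- vi
      for (k in seq_along(wi)) {
        r <- rec(wi[[k]], gi[[k]], mi[[k]], vi[[k]])
        out_w[[k]] <- r$w; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(w = out_w, m = out_m, v = out_v))
    }
    m2 <- beta1 * mi + (1 - beta1) * gi
    v2 <- beta2 * vi + (1 - beta2) * gi * gi
    upd <- (m2 / bc1) / (sqrt(v2 / bc2) + eps)
    w2 <- wi - lr * upd
    if (decoupled_wd > 0) w2 <- w2 - lr * decoupled_wd * wi
    list(w = w2, m = m2, v = v2)
  }
  r <- rec(w, g, state$m, state$v)
  list(w = r$w, state = list(m = r$m, v = r$v, t = t))
}
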