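# Fused composite operations with hand-written backward passes.  These are
# algebraically identical to chains of the primitive ops but collapse each
# hot block into a single tape node, which matters for the interpreter-bound
# training loop.  Each has a primitive-op twin exercised by the tests.

# Edge-restricted channel-wise attention (one GT layer, all heads at once).
# Inputs: Q, K, V, Ep nodes (n x d_p / ne x d_p), edge index (ii = target,
# jj = source), scale = 1/sqrt(d_k).  Output: rbind(msg (n rows), W (ne
# rows)); callers slice the two blocks.
ag_edge_attention <- function(Q, K, V, Ep, ii, jj, n, scale, tape) {
  Qv <- Q$value; Kv <- K$value; Vv <- V$value; Ev <- Ep$value
  out <- cpp_edge_attn_forward(Qv, Kv, Vv, Ev, ii, jj, n, scale)
  ne <- length(ii)
  W <- out[n + seq_len(ne), , drop = FALSE]
  .ag_new(tape, out, list(Q, K, V, Ep), function(g) {
    gs <- cpp_edge_attn_backward(g[seq_len(n), , drop = FALSE],
                                 g[n + seq_len(ne), , drop = FALSE],
                                 W, Qv, Kv, Vv, Ev, ii, jj, n, scale)
    list(gs$gQ, gs$gK, gs$gV, gs$gE)
  })
}

# Dense multi-head scaled dot-product attention over one graph's rows.
# Heads are contiguous column blocks of width d_ki; Q, K, V are n x d_fe
# nodes (already projected).  Output: n x d_fe.
ag_dense_mha <- function(Q, K, V, h_ki, tape) {
  Qv <- Q$value; Kv <- K$value; Vv <- V$value
  n <- nrow(Qv)
  d_fe <- ncol(Qv)
  d_ki <- d_fe %/% h_ki
  scale <- 1 / sqrt(d_ki)
  A <- vector("list", h_ki)
  out <- matrix(0, n, d_fe)
  for (k in seq_len(h_ki)) {
    cols <- (d_ki * (k - 1L) + 1L):(d_ki * k)
    S <- tcrossprod(Qv[, cols, drop = FALSE], Kv[, cols, drop = FALSE]) * scale
    mx <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
    E <- exp(S - mx)
    A[[k]] <- E / rowSums(E)
    out[, cols] <- A[[k]] %*% Vv[, cols, drop = FALSE]
  }
  .ag_new(tape, out, list(Q, K, V), function(g) {
    gQ <- matrix(0, n, d_fe); gK <- gQ; gV <- gQ
    for (k in seq_len(h_ki)) {
      cols <- (d_ki * (k - 1L) + 1L):(d_ki * k)
      gk <- g[, cols, drop = FALSE]
      Ak <- A[[k]]
      gV[, cols] <- crossprod(Ak, gk)
      gA <- tcrossprod(gk, Vv[, cols, drop = FALSE])
      gS <- Ak * (gA - rowSums(Ak * gA)) * scale
      gQ[, cols] <- gS %*% Kv[, cols, drop = FALSE]
      gK[, cols] <- crossprod(gS, Qv[, cols, drop = FALSE])
    }
    list(gQ, gK, gV)
  })
}

# Inner-product graph-autoencoder reconstruction loss for one graph slice:
# mean((Abar - sigmoid(H H^T))^2) over all n^2 entries.  `idx` selects the
# graph's rows from the batch node tensor.
ag_gae_recon <- function(H, idx, Abar, tape) {
  Hv <- H$value[idx, , drop = FALSE]
  n2 <- length(Abar)
  S <- tcrossprod(Hv)
  P <- 1 / (1 + exp(-S))
  D <- P - Abar
  .ag_new(tape, matrix(mean(D * D), 1L, 1L), list(H), function(g) {
    gS <- (2 * g[1L] / n2) * D * P * (1 - P)
    gH <- (gS + t(gS)) %*% Hv
    out <- matrix(0, nrow(H$value), ncol(H$value))
    out[idx, ] <- gH
    list(out)
  })
}

# fused two-layer MLP: act_out(act_hidden(x W1 + b1) W2 + b2).
# Activations: "none", "relu", "sigmoid", "silu".
ag_mlp2 <- function(x, W1, b1, W2, b2, tape,
                    act_hidden = "relu", act_out = "none") {
  xv <- x$value
  n <- nrow(xv)
  a1 <- xv %*% W1$value + rep(b1$value, each = n)
  h <- .act_fwd(a1, act_hidden)
  a2 <- h$y %*% W2$value + rep(b2$value, each = n)
  o <- .act_fwd(a2, act_out)
  .ag_new(tape, o$y, list(x, W1, b1, W2, b2), function(g) {
    ga2 <- g * o$d
    gh <- ga2 %*% t(W2$value)
    ga1 <- gh * h$d
    list(ga1 %*% t(W1$value), crossprod(xv, ga1),
         matrix(colSums(ga1), 1L), crossprod(h$y, ga2),
         matrix(colSums(ga2), 1L))
  })
}

# activation forward + pointwise derivative (w.r.t. pre-activation)
.act_fwd <- function(a, act) {
  switch(act,
    none = list(y = a, d = 1),
    relu = {
      m <- a > 0
      list(y = a * m, d = m)
    },
    sigmoid = {
      s <- 1 / (1 + exp(-a))
      list(y = s, d = s * (1 - s))
    },
    silu = {
      s <- 1 / (1 + exp(-a))
      list(y = a * s, d = s * (1 + a * (1 - s)))
    },
    stop("unknown activation ", act)
  )
}

# fused residual feed-forward: x + act2(act1(xn W1) W2); xn is the
# (normalized) input node, x the residual stream.
ag_ffn_residual <- function(x, xn, W1, W2, tape,
                            act_hidden = "silu", act_out = "none") {
  xnv <- xn$value
  h <- .act_fwd(xnv %*% W1$value, act_hidden)
  o <- .act_fwd(h$y %*% W2$value, act_out)
  .ag_new(tape, x$value + o$y, list(x, xn, W1, W2), function(g) {
    ga2 <- g * o$d
    ga1 <- (ga2 %*% t(W2$value)) * h$d
    list(g, ga1 %*% t(W1$value), crossprod(xnv, ga1), crossprod(h$y, ga2))
  })
}

# fused self-attention pooling readout over a merged batch: gate the kept
# rows of H by tanh(score), then concatenate per-graph mean and max.
# `keep` indexes kept rows (ascending), gk their graph ids.
ag_pool_readout <- function(H, scores, keep, gk, n_graphs, tape) {
  Hv <- H$value
  d <- ncol(Hv)
  Hk <- Hv[keep, , drop = FALSE]
  gate <- tanh(as.vector(scores$value)[keep])
  Hg <- Hk * gate
  cnt <- tabulate(gk, nbins = n_graphs)
  cnt[cnt == 0L] <- 1L
  mean_part <- .seg_sum(Hg, gk, n_graphs) / cnt
  arg <- .seg_argmax(Hg, gk, n_graphs)
  hit <- arg > 0L
  cols <- col(arg)[hit]
  max_part <- matrix(0, n_graphs, d)
  max_part[hit] <- Hg[cbind(as.vector(arg[hit]), cols)]
  .ag_new(tape, cbind(mean_part, max_part), list(H, scores), function(g) {
    gmean <- g[, seq_len(d), drop = FALSE]
    gmax <- g[, d + seq_len(d), drop = FALSE]
    dHg <- (gmean / cnt)[gk, , drop = FALSE]
    dHg[cbind(as.vector(arg[hit]), cols)] <-
      dHg[cbind(as.vector(arg[hit]), cols)] + gmax[hit]
    dgate <- rowSums(dHg * Hk)
    dHk <- dHg * gate
    gH <- matrix(0, nrow(Hv), d)
    gH[keep, ] <- dHk
    gs <- matrix(0, nrow(Hv), 1L)
    gs[keep, 1L] <- dgate * (1 - gate^2)
    list(gH, gs)
  })
}
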