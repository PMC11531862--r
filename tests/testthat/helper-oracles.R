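# Naive/brute-force reference implementations and small fixture builders.
# These stay deliberately loop-based and independent of the package's
# vectorized code paths.

# eval-mode batch norm with fresh running stats (mean 0, var 1)
.bn_eval <- function(X, g, b, eps = 1e-5) {
  sweep(sweep(X / sqrt(1 + eps), 2L, as.vector(g), `*`), 2L, as.vector(b), `+`)
}

.silu_ref <- function(x) x / (1 + exp(-x))

# per-node / per-head / per-channel loop implementation of one graph
# transformer layer (eval-mode batch norm)
naive_gt_layer <- function(H, E, edge_index, p, h_d) {
  n <- nrow(H); d_p <- ncol(H); d_k <- d_p / h_d
  Hn <- .bn_eval(H, p$g_h1, p$b_h1)
  Q <- Hn %*% p$W_Q; K <- Hn %*% p$W_K; V <- Hn %*% p$W_V
  if (nrow(edge_index) > 0L) {
    En <- .bn_eval(E, p$g_e1, p$b_e1)
    Ep <- En %*% p$W_E
    msg <- matrix(0, n, d_p)
    Wcat <- matrix(0, nrow(edge_index), d_p)
    for (i in seq_len(n)) {
      eids <- which(edge_index[, 1] == i)
      if (length(eids) == 0L) next
      js <- edge_index[eids, 2]
      for (k in seq_len(h_d)) {
        for (ch in seq_len(d_k)) {
          col <- (k - 1L) * d_k + ch
          s <- Q[i, col] * K[js, col] / sqrt(d_k) * Ep[eids, col]
          w <- exp(s - max(s)); w <- w / sum(w)
          Wcat[eids, col] <- w
          msg[i, col] <- sum(w * V[js, col])
        }
      }
    }
    Hbar <- H + msg %*% p$W_h0
    Ebar <- E + Wcat %*% p$W_e0
    En2 <- .bn_eval(Ebar, p$g_e2, p$b_e2)
    Eout <- Ebar + .silu_ref(En2 %*% p$W_e1) %*% p$W_e2
  } else {
    Hbar <- H
    Eout <- E
  }
  Hn2 <- .bn_eval(Hbar, p$g_h2, p$b_h2)
  Hout <- Hbar + .silu_ref(Hn2 %*% p$W_h1) %*% p$W_h2
  list(H = Hout, E = Eout)
}

# dense-matrix graph-convolution reference
naive_gae_encode <- function(H, edge_index, W, slope = 0.01) {
  n <- nrow(H)
  A <- matrix(0, n, n)
  if (nrow(edge_index) > 0L) {
    A[edge_index] <- 1
    A <- 1 * ((A + t(A)) > 0)
  }
  diag(A) <- 1
  D <- diag(1 / sqrt(rowSums(A)), n)
  Z <- D %*% A %*% D %*% H %*% W
  ifelse(Z > 0, Z, slope * Z)
}

# double-loop reconstruction loss reference
naive_gae_recon <- function(H, edge_index) {
  n <- nrow(H)
  A <- matrix(0, n, n)
  if (nrow(edge_index) > 0L) {
    A[edge_index] <- 1
    A <- 1 * ((A + t(A)) > 0)
  }
  diag(A) <- 1
  acc <- 0
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      ahat <- 1 / (1 + exp(-sum(H[u, ] * H[v, ])))
      acc <- acc + (A[u, v] - ahat)^2
    }
  }
  acc / n^2
}

# triple-loop dense multi-head cross-attention reference
naive_cross_attend <- function(Hbp, Hmf, Hcc, params, h_ki) {
  n <- nrow(Hbp); d_fe <- ncol(Hbp); d_ki <- d_fe / h_ki
  lapply(params$groups, function(gw) {
    Q <- Hbp %*% gw$Wq; K <- Hmf %*% gw$Wk; V <- Hcc %*% gw$Wv
    out <- matrix(0, n, d_fe)
    for (k in seq_len(h_ki)) {
      cols <- (k - 1L) * d_ki + seq_len(d_ki)
      for (q in seq_len(n)) {
        s <- vapply(seq_len(n),
                    function(j) sum(Q[q, cols] * K[j, cols]), 1) / sqrt(d_ki)
        w <- exp(s - max(s)); w <- w / sum(w)
        out[q, cols] <- colSums(w * V[, cols, drop = FALSE])
      }
    }
    out
  })
}

# brute-force multi-label metrics by pair enumeration / explicit ranking
brute_metrics <- function(scores, labels, threshold = 0.5) {
  N <- nrow(scores); C <- ncol(scores)
  per_label <- function(f) {
    vals <- c()
    for (j in seq_len(C)) {
      s <- sum(labels[, j])
      if (s == 0 || s == N) next
      vals <- c(vals, f(scores[, j], labels[, j]))
    }
    mean(vals)
  }
  auroc1 <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  ap1 <- function(s, y) {
    ord <- order(-s)
    hits <- 0; acc <- 0
    for (r in seq_along(ord)) {
      if (y[ord[r]] == 1) {
        hits <- hits + 1
        acc <- acc + hits / r
      }
    }
    acc / sum(y)
  }
  rl_vals <- oe_vals <- c()
  for (i in seq_len(N)) {
    pos <- which(labels[i, ] == 1); neg <- which(labels[i, ] == 0)
    if (length(pos)) {
      oe_vals <- c(oe_vals, as.numeric(labels[i, which.max(scores[i, ])] == 0))
    }
    if (length(pos) && length(neg)) {
      bad <- 0
      for (a in pos) for (b in neg) {
        bad <- bad + (scores[i, a] < scores[i, b]) +
          0.5 * (scores[i, a] == scores[i, b])
      }
      rl_vals <- c(rl_vals, bad / (length(pos) * length(neg)))
    }
  }
  list(ap = per_label(ap1), auroc = per_label(auroc1),
       hloss = mean((scores >= threshold) != labels),
       rl = mean(rl_vals), oerror = mean(oe_vals))
}

# random symmetric edge set over n nodes (both directions, sorted)
rand_edges <- function(n, p = 0.4) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  if (nrow(keep) == 0L && n >= 2L) keep <- matrix(c(1L, 2L), 1L)
  ei <- rbind(keep, keep[, 2:1, drop = FALSE])
  colnames(ei) <- c("i", "j")
  ei[order(ei[, 1], ei[, 2]), , drop = FALSE]
}

# small model/simulation configs used across tests
tiny_model_config <- function(lr = 3e-3, seed = 11L, ...) {
  model_config(d_h = 6L, d_e = 42L, d_p = 8L, h_d = 2L, n_layers = 2L,
               d_fe = 8L, d_F = 8L, h_ki = 2L, M_bp = 8L, M_cc = 5L,
               M_mf = 5L, C = 4L, lr = lr, batch_size = 4L, seed = seed, ...)
}

tiny_sim_config <- function(n_proteins = 8L, seed = 21L, ...) {
  sim_config(n_proteins = n_proteins, len_range = c(10L, 16L), d_h = 6L,
             catalogue = default_motif_catalogue(k = 5L), seed = seed, ...)
}

tiny_dataset <- function(n_proteins = 8L, seed = 21L, cfg = tiny_model_config()) {
  prepare_dataset(generate_records(tiny_sim_config(n_proteins, seed)),
                  config = cfg)
}

single_labels <- function(ds, i) {
  lapply(ds$labels, function(m) m[i, ])
}

# central finite-difference gradient of f with respect to entry (r, c) of
# the matrix at `path` (character vector) inside a nested parameter list
fd_grad_entry <- function(f, params, path, r, c, h = 1e-5) {
  bump <- function(delta) {
    p <- params
    loc <- paste0("p", paste(sprintf("[['%s']]", path), collapse = ""))
    m <- eval(parse(text = loc))
    m[r, c] <- m[r, c] + delta
    eval(parse(text = paste0(loc, " <- m")))
    p
  }
  (f(bump(h)) - f(bump(-h))) / (2 * h)
}
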