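# Reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a node: an environment holding a numeric
# matrix `value`, the accumulated `grad`, its `parents`, and a backward
# closure `bw(g)` returning one gradient (or NULL) per parent.  Nodes are
# registered on a tape in creation order; creation order is a valid
# topological order, so the backward sweep is a single reverse loop.
# Scalars are 1x1 matrices throughout.

ag_tape <- function(train = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$train <- isTRUE(train)
  tp
}

.ag_new <- function(tape, value, parents = list(), bw = NULL) {
  if (!is.matrix(value)) value <- as.matrix(value)
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

# Leaf holding data that never needs a gradient.
ag_const <- function(tape, x) .ag_new(tape, x)

# Leaf holding a trainable parameter; grad is collected after ag_backward.
ag_param <- function(tape, x) {
  nd <- .ag_new(tape, x)
  nd$is_param <- TRUE
  nd
}

ag_value <- function(node) node$value

ag_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- ps[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(tape)
}

.ag_check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop("non-finite values encountered in ", what, call. = FALSE)
  }
  invisible(x)
}

## ---- arithmetic ------------------------------------------------------------

ag_add <- function(a, b, tape) {
  .ag_new(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b, tape) {
  .ag_new(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b, tape) {
  av <- a$value; bv <- b$value
  .ag_new(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s, tape) {
  .ag_new(tape, a$value * s, list(a), function(g) list(g * s))
}

# x %*% W
ag_matmul <- function(x, w, tape) {
  xv <- x$value; wv <- w$value
  .ag_new(tape, xv %*% wv, list(x, w),
          function(g) list(g %*% t(wv), crossprod(xv, g)))
}

# x %*% t(y)
ag_matmul_t <- function(x, y, tape) {
  xv <- x$value; yv <- y$value
  .ag_new(tape, tcrossprod(xv, yv), list(x, y),
          function(g) list(g %*% yv, crossprod(g, xv)))
}

# affine map with a 1 x d bias row broadcast over rows
ag_linear <- function(x, w, b, tape) {
  xv <- x$value; wv <- w$value
  val <- xv %*% wv
  val <- val + rep(b$value, each = nrow(val))
  .ag_new(tape, val, list(x, w, b), function(g) {
    list(g %*% t(wv), crossprod(xv, g), matrix(colSums(g), 1L))
  })
}

# multiply every column of x by the column vector v (n x 1)
ag_colmul <- function(x, v, tape) {
  xv <- x$value; vv <- as.vector(v$value)
  .ag_new(tape, xv * vv, list(x, v), function(g) {
    list(g * vv, matrix(rowSums(g * xv), ncol = 1L))
  })
}

# constant (sparse or dense) matrix A times node x
ag_spmm <- function(A, x, tape) {
  val <- as.matrix(A %*% x$value)
  .ag_new(tape, val, list(x), function(g) list(as.matrix(Matrix::crossprod(A, g))))
}

## ---- activations -----------------------------------------------------------

ag_relu <- function(x, tape) {
  m <- x$value > 0
  .ag_new(tape, x$value * m, list(x), function(g) list(g * m))
}

ag_leaky_relu <- function(x, tape, slope = 0.01) {
  m <- ifelse(x$value > 0, 1, slope)
  .ag_new(tape, x$value * m, list(x), function(g) list(g * m))
}

ag_silu <- function(x, tape) {
  s <- 1 / (1 + exp(-x$value))
  val <- x$value * s
  d <- s * (1 + x$value * (1 - s))
  .ag_new(tape, val, list(x), function(g) list(g * d))
}

ag_sigmoid <- function(x, tape) {
  s <- 1 / (1 + exp(-x$value))
  .ag_new(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(x, tape) {
  tv <- tanh(x$value)
  .ag_new(tape, tv, list(x), function(g) list(g * (1 - tv^2)))
}

## ---- indexing / shaping ----------------------------------------------------

ag_rows <- function(x, idx, tape) {
  xv <- x$value
  nr <- nrow(xv)
  .ag_new(tape, xv[idx, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, nr, ncol(xv))
    if (!is.unsorted(idx, strictly = TRUE)) {
      out[idx, ] <- g            # unique sorted indices: direct scatter
    } else {
      rs <- rowsum(g, group = idx, reorder = TRUE)
      out[as.integer(rownames(rs)), ] <- rs
    }
    list(out)
  })
}

ag_cbind <- function(nodes, tape) {
  vals <- lapply(nodes, ag_value)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  .ag_new(tape, do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ag_rbind <- function(nodes, tape) {
  vals <- lapply(nodes, ag_value)
  hs <- vapply(vals, nrow, 1L)
  ends <- cumsum(hs)
  starts <- ends - hs + 1L
  .ag_new(tape, do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

ag_mean_list <- function(nodes, tape) {
  k <- length(nodes)
  val <- Reduce(`+`, lapply(nodes, ag_value)) / k
  .ag_new(tape, val, nodes, function(g) rep(list(g / k), k))
}

ag_sum_list <- function(nodes, tape) {
  val <- Reduce(`+`, lapply(nodes, ag_value))
  .ag_new(tape, val, nodes, function(g) rep(list(g), length(nodes)))
}

## ---- segment operations (grouped rows) ------------------------------------

# sum rows of x by group id (1..n_out); groups absent from `groups` get zeros
.seg_sum <- function(x, groups, n_out) {
  out <- matrix(0, n_out, ncol(x))
  rs <- rowsum(x, group = groups, reorder = TRUE)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

ag_scatter_sum <- function(x, groups, n_out, tape) {
  .ag_new(tape, .seg_sum(x$value, groups, n_out), list(x),
          function(g) list(g[groups, , drop = FALSE]))
}

ag_segment_mean <- function(x, groups, n_out, tape) {
  cnt <- tabulate(groups, nbins = n_out)
  cnt[cnt == 0L] <- 1L
  .ag_new(tape, .seg_sum(x$value, groups, n_out) / cnt, list(x),
          function(g) list((g / cnt)[groups, , drop = FALSE]))
}

# per-(group, column) argmax; ties resolve to the lowest row index
.seg_argmax <- function(x, groups, n_out) {
  cpp_seg_argmax(x, as.integer(groups), as.integer(n_out))
}

ag_segment_max <- function(x, groups, n_out, tape) {
  xv <- x$value
  d <- ncol(xv)
  arg <- .seg_argmax(xv, groups, n_out)
  hit <- arg > 0L
  val <- matrix(0, n_out, d)
  cols <- col(arg)[hit]
  val[hit] <- xv[cbind(as.vector(arg[hit]), cols)]
  .ag_new(tape, val, list(x), function(g) {
    out <- matrix(0, nrow(xv), d)
    out[cbind(as.vector(arg[hit]), cols)] <- g[hit]
    list(out)
  })
}

# column-wise max per segment, used for softmax shifting
.seg_max <- function(x, groups, n_out) {
  out <- matrix(-Inf, n_out, ncol(x))
  arg <- .seg_argmax(x, groups, n_out)
  hit <- arg > 0L
  out[hit] <- x[cbind(as.vector(arg[hit]), col(arg)[hit])]
  out
}

# softmax over rows sharing a group id, independently per column.
# Shifted by the per-(group, column) max for stability.
ag_segment_softmax <- function(x, groups, n_out, tape) {
  xv <- x$value
  m <- .seg_max(xv, groups, n_out)
  e <- exp(xv - m[groups, , drop = FALSE])
  denom <- .seg_sum(e, groups, n_out)
  y <- e / denom[groups, , drop = FALSE]
  .ag_new(tape, y, list(x), function(g) {
    s <- .seg_sum(y * g, groups, n_out)
    list(y * (g - s[groups, , drop = FALSE]))
  })
}

# ordinary row-wise softmax (dense attention)
ag_softmax_rows <- function(x, tape) {
  xv <- x$value
  m <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - m)
  y <- e / rowSums(e)
  .ag_new(tape, y, list(x), function(g) list(y * (g - rowSums(y * g))))
}

## ---- normalization ---------------------------------------------------------

# Batch normalization over the rows currently on the tape (one column = one
# channel).  `state` is an environment with running mean/var vectors `rm`,
# `rv` and momentum; updated in place in training mode, read in eval mode.
ag_batchnorm <- function(x, gamma, beta, state, tape, eps = 1e-5) {
  xv <- x$value
  gv <- as.vector(gamma$value)
  bv <- as.vector(beta$value)
  n <- nrow(xv)
  bycol <- function(v) rep(v, each = n)
  if (tape$train) {
    mu <- colMeans(xv)
    xc <- xv - bycol(mu)
    va <- colMeans(xc * xc)
    mom <- state$momentum
    state$rm <- (1 - mom) * state$rm + mom * mu
    state$rv <- (1 - mom) * state$rv + mom * va
    inv <- 1 / sqrt(va + eps)
    xhat <- xc * bycol(inv)
    val <- xhat * bycol(gv) + bycol(bv)
    .ag_new(tape, val, list(x, gamma, beta), function(g) {
      dx <- g - bycol(colMeans(g)) - xhat * bycol(colMeans(g * xhat))
      dx <- dx * bycol(gv * inv)
      list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
    })
  } else {
    inv <- 1 / sqrt(state$rv + eps)
    xhat <- (xv - bycol(state$rm)) * bycol(inv)
    val <- xhat * bycol(gv) + bycol(bv)
    .ag_new(tape, val, list(x, gamma, beta), function(g) {
      list(g * bycol(gv * inv),
           matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
    })
  }
}

bn_state <- function(d, momentum = 0.1) {
  st <- new.env(parent = emptyenv())
  st$rm <- numeric(d)
  st$rv <- rep(1, d)
  st$momentum <- momentum
  st
}

## ---- reductions & losses ---------------------------------------------------

ag_mean_all <- function(x, tape) {
  n <- length(x$value)
  .ag_new(tape, matrix(mean(x$value), 1L, 1L), list(x),
          function(g) list(matrix(g[1L] / n, nrow(x$value), ncol(x$value))))
}

ag_sum_all <- function(x, tape) {
  .ag_new(tape, matrix(sum(x$value), 1L, 1L), list(x),
          function(g) list(matrix(g[1L], nrow(x$value), ncol(x$value))))
}

# mean squared error against a constant target
ag_mse <- function(pred, target, tape) {
  pv <- pred$value
  n <- length(pv)
  diff <- pv - target
  .ag_new(tape, matrix(mean(diff * diff), 1L, 1L), list(pred),
          function(g) list(2 * g[1L] * diff / n))
}

# binary cross-entropy of probabilities against {0,1} targets, with
# clamping of predictions to [eps, 1-eps]
ag_bce <- function(pred, target, tape, eps = 1e-7) {
  pv <- pmin(pmax(pred$value, eps), 1 - eps)
  free <- (pred$value > eps) & (pred$value < 1 - eps)
  n <- length(pv)
  val <- mean(-target * log(pv) - (1 - target) * log(1 - pv))
  .ag_new(tape, matrix(val, 1L, 1L), list(pred), function(g) {
    d <- (-target / pv + (1 - target) / (1 - pv)) / n
    list(g[1L] * d * free)
  })
}

## ---- parameter plumbing ----------------------------------------------------

# wrap a nested list of matrices into parameter nodes with the same shape
ag_wrap_params <- function(tape, params) {
  if (is.list(params)) return(lapply(params, function(p) ag_wrap_params(tape, p)))
  ag_param(tape, params)
}

# recover gradients from a wrapped structure (zeros where untouched)
ag_collect_grads <- function(wrapped) {
  if (is.list(wrapped)) return(lapply(wrapped, ag_collect_grads))
  if (is.null(wrapped$grad)) {
    matrix(0, nrow(wrapped$value), ncol(wrapped$value))
  } else {
    wrapped$grad
  }
}
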