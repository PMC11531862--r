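# Parameter initialization and the Adam optimizer.

# Glorot-style uniform initialization: U(-sqrt(6/(fan_in+fan_out)), +).
# Variance-preserving for the affine sublayers that dominate this
# architecture; gain-2 (Kaiming) scaling compounds across the stacked
# affine maps and saturates the sigmoid heads at initialization.
init_weight <- function(d_in, d_out) {
  bound <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -bound, bound), d_in, d_out)
}

init_bias <- function(d) matrix(0, 1L, d)

# flatten a nested list of matrices to a flat named list (stable order)
flatten_params <- function(params, prefix = "") {
  if (!is.list(params)) {
    out <- list(params)
    names(out) <- prefix
    return(out)
  }
  nms <- names(params)
  out <- list()
  for (k in seq_along(params)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nms[k]) else nms[k]
    out <- c(out, flatten_params(params[[k]], key))
  }
  out
}

# apply a function elementwise over two identically shaped nested lists
map2_params <- function(a, b, f) {
  if (!is.list(a)) return(f(a, b))
  out <- a
  for (k in seq_along(a)) out[[k]] <- map2_params(a[[k]], b[[k]], f)
  out
}

map_params <- function(a, f) {
  if (!is.list(a)) return(f(a))
  out <- a
  for (k in seq_along(a)) out[[k]] <- map_params(a[[k]], f)
  out
}

# rebuild a nested list of matrices from a flat vector, using `skel` for
# shapes; inverse of unlist(..., use.names = FALSE)
relist_params <- function(v, skel) {
  pos <- 0L
  walk <- function(s) {
    if (!is.list(s)) {
      k <- length(s)
      out <- matrix(v[(pos + 1L):(pos + k)], nrow(s), ncol(s))
      pos <<- pos + k
      return(out)
    }
    lapply(s, walk)
  }
  out <- walk(skel)
  stopifnot(pos == length(v))
  out
}

# The optimizer works on the flattened parameter vector; the nested list is
# rebuilt once per step (the model forward needs matrices).
adam_state <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  n <- length(unlist(params, use.names = FALSE))
  list(m = numeric(n), v = numeric(n), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, opt, clip = Inf, weight_decay = 0) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  pv <- unlist(params, use.names = FALSE)
  gv <- unlist(grads, use.names = FALSE)
  if (is.finite(clip)) {
    gn <- sqrt(sum(gv * gv))
    if (gn > clip) gv <- gv * (clip / gn)
  }
  opt$m <- b1 * opt$m + (1 - b1) * gv
  opt$v <- b2 * opt$v + (1 - b2) * gv * gv
  step <- opt$lr * (opt$m / (1 - b1^opt$t)) /
    (sqrt(opt$v / (1 - b2^opt$t)) + opt$eps)
  if (weight_decay > 0) step <- step + opt$lr * weight_decay * pv
  list(params = relist_params(pv - step, params), opt = opt)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
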