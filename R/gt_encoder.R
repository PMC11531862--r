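# Edge-featured graph transformer encoder.
#
# Attention is restricted to contact-map neighbours.  Per head and edge
# (i, j), the score is the channel-wise product (Q_i * K_j) / sqrt(d_k) * E_ij;
# softmax is taken over j in N(i) independently per channel, so the
# concatenated attention weights have width d_p = h_d * d_k and can update
# the edge features through a d_p x d_p map.  Heads live in contiguous
# column blocks; because every operation is channel-wise, no explicit head
# reshaping is needed.

init_gt_layer_params <- function(d_p) {
  list(
    W_Q = init_weight(d_p, d_p), W_K = init_weight(d_p, d_p),
    W_V = init_weight(d_p, d_p), W_E = init_weight(d_p, d_p),
    W_h0 = init_weight(d_p, d_p), W_e0 = init_weight(d_p, d_p),
    W_h1 = init_weight(d_p, 2L * d_p), W_h2 = init_weight(2L * d_p, d_p),
    W_e1 = init_weight(d_p, 2L * d_p), W_e2 = init_weight(2L * d_p, d_p),
    g_h1 = matrix(1, 1L, d_p), b_h1 = matrix(0, 1L, d_p),
    g_e1 = matrix(1, 1L, d_p), b_e1 = matrix(0, 1L, d_p),
    g_h2 = matrix(1, 1L, d_p), b_h2 = matrix(0, 1L, d_p),
    g_e2 = matrix(1, 1L, d_p), b_e2 = matrix(0, 1L, d_p)
  )
}

#' Initialize graph-transformer parameters
#'
#' Weights use uniform Kaiming-style fan-in scaling; batch-norm scale/shift
#' start at 1/0.  Seed-controlled via the caller's RNG (see
#' [model_config()] / [init_model()] for the seeded entry point).
#'
#' @param d_h,d_e Input node / edge feature dimensions.
#' @param d_p Model width (must equal heads x per-head width).
#' @param n_layers Number of transformer layers.
#' @return Nested list of parameter matrices.
#' @export
init_gt_params <- function(d_h, d_e, d_p = 128L, n_layers = 2L) {
  list(
    proj = list(W_h = init_weight(d_h, d_p), b_h = init_bias(d_p),
                W_e = init_weight(d_e, d_p), b_e = init_bias(d_p)),
    layers = stats::setNames(
      lapply(seq_len(n_layers), function(l) init_gt_layer_params(d_p)),
      paste0("layer", seq_len(n_layers))
    )
  )
}

#' Fresh batch-norm running-statistics states for a transformer stack
#' @param d_p Model width.
#' @param n_layers Number of layers.
#' @param momentum Running-statistics momentum.
#' @return List (per layer) of lists of four state environments.
#' @export
gt_bn_states <- function(d_p, n_layers, momentum = 0.1) {
  lapply(seq_len(n_layers), function(l) {
    list(h1 = bn_state(d_p, momentum), e1 = bn_state(d_p, momentum),
         h2 = bn_state(d_p, momentum), e2 = bn_state(d_p, momentum))
  })
}

# tape-level input projection; pw = wrapped proj params
.gt_project_nodes <- function(tape, Xn, En, pw) {
  list(H = ag_linear(Xn, pw$W_h, pw$b_h, tape),
       E = ag_linear(En, pw$W_e, pw$b_e, tape))
}

# tape-level transformer layer; lw = wrapped layer params, st = bn states.
# skip_edge_update drops the edge-stream update (Ebar and its FFN) -- valid
# only for the final layer of a stack whose edge output is not consumed,
# since the node update is unaffected.
.gt_layer_nodes <- function(tape, H, E, edge_index, lw, st, h_d,
                            skip_edge_update = FALSE) {
  n <- nrow(ag_value(H))
  d_p <- ncol(ag_value(H))
  d_k <- d_p / h_d
  Hn <- ag_batchnorm(H, lw$g_h1, lw$b_h1, st$h1, tape)
  Q <- ag_matmul(Hn, lw$W_Q, tape)
  K <- ag_matmul(Hn, lw$W_K, tape)
  V <- ag_matmul(Hn, lw$W_V, tape)
  if (nrow(edge_index) > 0L) {
    En <- ag_batchnorm(E, lw$g_e1, lw$b_e1, st$e1, tape)
    Ep <- ag_matmul(En, lw$W_E, tape)
    ii <- edge_index[, 1L]
    jj <- edge_index[, 2L]
    att <- ag_edge_attention(Q, K, V, Ep, ii, jj, n, 1 / sqrt(d_k), tape)
    .ag_check_finite(ag_value(att), "gt attention")
    ne <- length(ii)
    msg <- ag_rows(att, seq_len(n), tape)
    Hbar <- ag_add(H, ag_matmul(msg, lw$W_h0, tape), tape)
    if (skip_edge_update) {
      E_next <- E
    } else {
      W <- ag_rows(att, n + seq_len(ne), tape)
      Ebar <- ag_add(E, ag_matmul(W, lw$W_e0, tape), tape)
      Ebn <- ag_batchnorm(Ebar, lw$g_e2, lw$b_e2, st$e2, tape)
      E_next <- ag_ffn_residual(Ebar, Ebn, lw$W_e1, lw$W_e2, tape)
    }
  } else {
    # no edges: the attention message is zero and edges pass through empty
    Hbar <- H
    E_next <- E
  }
  Hbn <- ag_batchnorm(Hbar, lw$g_h2, lw$b_h2, st$h2, tape)
  H_next <- ag_ffn_residual(Hbar, Hbn, lw$W_h1, lw$W_h2, tape)
  .ag_check_finite(ag_value(H_next), "gt layer output")
  list(H = H_next, E = E_next)
}

#' Project raw node/edge features into the transformer width
#'
#' @param node_feats n x d_h matrix.
#' @param edge_feats |E| x d_e matrix.
#' @param params `proj` element of [init_gt_params()] output.
#' @return list(H = n x d_p, E = |E| x d_p).
#' @export
project_inputs <- function(node_feats, edge_feats, params) {
  if (ncol(node_feats) != nrow(params$W_h) ||
      ncol(edge_feats) != nrow(params$W_e)) {
    stop("feature dimensions do not match projection weights", call. = FALSE)
  }
  tape <- ag_tape(train = FALSE)
  pw <- ag_wrap_params(tape, params)
  out <- .gt_project_nodes(tape, ag_const(tape, node_feats),
                           ag_const(tape, edge_feats), pw)
  list(H = ag_value(out$H), E = ag_value(out$E))
}

#' Apply one graph-transformer layer
#'
#' @param state list(H, E, edge_index) as produced by [project_inputs()]
#'   plus the graph's edge index.
#' @param params One element of the `layers` list from [init_gt_params()].
#' @param h_d Number of attention heads.
#' @param bn_states Optional list of four batch-norm state environments
#'   (h1, e1, h2, e2); fresh unit states are used when NULL.
#' @param train Use batch statistics (TRUE) or running statistics (FALSE).
#' @return list(H, E, edge_index) after the layer.
#' @export
gt_layer <- function(state, params, h_d = 4L, bn_states = NULL, train = FALSE) {
  d_p <- ncol(state$H)
  if (d_p %% h_d != 0L) stop("d_p must be divisible by h_d", call. = FALSE)
  if (is.null(bn_states)) {
    bn_states <- list(h1 = bn_state(d_p), e1 = bn_state(d_p),
                      h2 = bn_state(d_p), e2 = bn_state(d_p))
  }
  tape <- ag_tape(train = train)
  lw <- ag_wrap_params(tape, params)
  out <- .gt_layer_nodes(tape, ag_const(tape, state$H), ag_const(tape, state$E),
                         state$edge_index, lw, bn_states, h_d)
  list(H = ag_value(out$H), E = ag_value(out$E), edge_index = state$edge_index)
}

#' Encode a residue graph with the full transformer stack
#'
#' @param graph A `residue_graph`.
#' @param params Output of [init_gt_params()].
#' @param h_d Number of heads.
#' @param bn_states Optional per-layer batch-norm states (see
#'   [gt_bn_states()]); fresh states when NULL.
#' @param train Batch-statistics mode.
#' @return list(H = n x d_p, E = |E| x d_p, edge_index).
#' @export
gt_encode <- function(graph, params, h_d = 4L, bn_states = NULL,
                      train = FALSE) {
  n_layers <- length(params$layers)
  stopifnot(n_layers >= 1L)
  d_p <- ncol(params$proj$W_h)
  if (is.null(bn_states)) bn_states <- gt_bn_states(d_p, n_layers)
  tape <- ag_tape(train = train)
  pw <- ag_wrap_params(tape, params)
  st <- .gt_project_nodes(tape, ag_const(tape, graph$node_feats),
                          ag_const(tape, graph$edge_feats), pw$proj)
  for (l in seq_len(n_layers)) {
    st <- .gt_layer_nodes(tape, st$H, st$E, graph$edge_index,
                          pw$layers[[l]], bn_states[[l]], h_d)
  }
  list(H = ag_value(st$H), E = ag_value(st$E), edge_index = graph$edge_index)
}
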