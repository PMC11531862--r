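# Functional cross-attention: fuses the three ontology feature tensors into
# localization features.  Queries come from BP, keys from MF and values from
# CC (asymmetric by design).  Three independent attention groups run dense
# multi-head attention over the protein's own residues; their outputs are
# averaged, projected, and passed through a residual expand-then-contract
# feed-forward block.

#' Initialize functional cross-attention parameters
#'
#' @param d_fe Branch feature width.
#' @param d_F Fused feature width.
#' @param n_groups Number of attention groups (default 3).
#' @return Nested list: per-ontology nLinear transforms, per-group Q/K/V
#'   maps, output projection `Ot`, and FFN weights.
#' @export
init_fun_attention_params <- function(d_fe, d_F = d_fe, n_groups = 3L) {
  list(
    nlin = list(
      bp = .init_nlinear(d_fe), cc = .init_nlinear(d_fe),
      mf = .init_nlinear(d_fe)
    ),
    groups = stats::setNames(
      lapply(seq_len(n_groups), function(i) {
        list(Wq = init_weight(d_fe, d_fe), Wk = init_weight(d_fe, d_fe),
             Wv = init_weight(d_fe, d_fe))
      }),
      paste0("group", seq_len(n_groups))
    ),
    Ot = init_weight(d_fe, d_F),
    W_F1 = init_weight(d_F, 2L * d_F),
    W_F2 = init_weight(2L * d_F, d_F)
  )
}

.init_nlinear <- function(d) {
  list(W1 = init_weight(d, d), b1 = init_bias(d),
       W2 = init_weight(d, d), b2 = init_bias(d))
}

#' Nonlinear transformation layer (two-layer MLP)
#'
#' Affine, ReLU, affine -- applied row-wise.
#'
#' @param H n x d_fe matrix.
#' @param params list(W1, b1, W2, b2).
#' @return n x d_fe matrix.
#' @export
nlinear <- function(H, params) {
  if (ncol(H) != nrow(params$W1)) stop("shape mismatch in nlinear", call. = FALSE)
  tape <- ag_tape(train = FALSE)
  pw <- ag_wrap_params(tape, params)
  ag_value(.nlinear_nodes(tape, ag_const(tape, H), pw))
}

.nlinear_nodes <- function(tape, H, pw) {
  ag_mlp2(H, pw$W1, pw$b1, pw$W2, pw$b2, tape,
          act_hidden = "relu", act_out = "none")
}

# cross-attention over a merged batch: per graph, per group, dense MHA
# (fused kernel ag_dense_mha; heads are column blocks of width d_ki)
.cross_attend_nodes <- function(tape, Hbp, Hmf, Hcc, gw_list, graph_id,
                                n_graphs, h_ki) {
  outs <- vector("list", length(gw_list))
  for (i in seq_along(gw_list)) {
    gw <- gw_list[[i]]
    Q <- ag_matmul(Hbp, gw$Wq, tape)
    K <- ag_matmul(Hmf, gw$Wk, tape)
    V <- ag_matmul(Hcc, gw$Wv, tape)
    pieces <- vector("list", n_graphs)
    for (g in seq_len(n_graphs)) {
      idx <- which(graph_id == g)
      pieces[[g]] <- ag_dense_mha(ag_rows(Q, idx, tape),
                                  ag_rows(K, idx, tape),
                                  ag_rows(V, idx, tape), h_ki, tape)
    }
    outs[[i]] <- if (n_graphs == 1L) pieces[[1L]] else ag_rbind(pieces, tape)
  }
  outs
}

#' Functional cross-attention over one protein
#'
#' For each attention group, queries are projected from the BP features,
#' keys from MF, values from CC; scaled dot-product attention runs densely
#' over all residues of the protein and heads are concatenated back to
#' `d_fe`.
#'
#' @param H_bp,H_mf,H_cc n x d_fe feature matrices.
#' @param params Output of [init_fun_attention_params()].
#' @param h_ki Heads per group.
#' @return List of per-group n x d_fe matrices (length `n_groups`).
#' @export
cross_attend <- function(H_bp, H_mf, H_cc, params, h_ki = 4L) {
  n <- nrow(H_bp)
  if (n == 0L) stop("cross_attend requires at least one residue", call. = FALSE)
  stopifnot(nrow(H_mf) == n, nrow(H_cc) == n)
  tape <- ag_tape(train = FALSE)
  gw <- ag_wrap_params(tape, params$groups)
  outs <- .cross_attend_nodes(tape, ag_const(tape, H_bp), ag_const(tape, H_mf),
                              ag_const(tape, H_cc), gw, rep(1L, n), 1L, h_ki)
  lapply(outs, ag_value)
}

.fuse_nodes <- function(tape, outs, pw) {
  HF <- ag_relu(ag_matmul(ag_mean_list(outs, tape), pw$Ot, tape), tape)
  ag_ffn_residual(HF, HF, pw$W_F1, pw$W_F2, tape,
                  act_hidden = "relu", act_out = "relu")
}

#' Fuse cross-attention outputs into localization features
#'
#' Node-wise mean of the group outputs, projection by `Ot` with ReLU, then a
#' residual feed-forward block expanding to `2 d_F` and contracting back.
#'
#' @param H_list List of n x d_fe matrices (one per group).
#' @param params Output of [init_fun_attention_params()].
#' @return n x d_F matrix of localization features.
#' @export
fuse_functional <- function(H_list, params) {
  tape <- ag_tape(train = FALSE)
  pw <- ag_wrap_params(tape, params[c("Ot", "W_F1", "W_F2")])
  outs <- lapply(H_list, function(H) ag_const(tape, H))
  ag_value(.fuse_nodes(tape, outs, pw))
}

#' Initialize the localization head
#' @param d_F Fused width.
#' @param n_classes Number of localization classes.
#' @return list(pool, head) parameter lists.
#' @export
init_sl_head_params <- function(d_F, n_classes) {
  list(
    pool = list(Ws = init_weight(d_F, 1L)),
    head = list(Wm1 = init_weight(2L * d_F, d_F), bm1 = init_bias(d_F),
                Wm2 = init_weight(d_F, n_classes), bm2 = init_bias(n_classes))
  )
}

#' Localization score head
#'
#' Self-attention pooling of the fused features followed by a two-layer MLP
#' with sigmoid outputs.
#'
#' @param H_SL n x d_F fused features.
#' @param edge_index Edge matrix.
#' @param params Output of [init_sl_head_params()].
#' @param ratio Pooling ratio.
#' @return Score vector in (0,1)^C.
#' @export
localization_scores <- function(H_SL, edge_index, params, ratio = 0.5) {
  tape <- ag_tape(train = FALSE)
  pw <- ag_wrap_params(tape, params)
  Ahat <- normalized_adjacency(edge_index, nrow(H_SL))
  pooled <- .sat_pool_nodes(tape, Ahat, ag_const(tape, H_SL), pw$pool$Ws,
                            rep(1L, nrow(H_SL)), 1L, ratio)
  as.vector(ag_value(.score_head_nodes(tape, pooled$readout, pw$head)))
}
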