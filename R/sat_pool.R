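# Self-attention graph pooling (SAGPool-style): a one-layer graph
# convolution scores every node; the top ceil(r * n) nodes per graph are
# kept, their features gated by tanh(score), and the readout concatenates
# the mean and max over the kept nodes.  The raw scores double as the
# per-residue importance signal.

# tape-level pooling over a (possibly merged) batch.
# Ahat: normalized adjacency of the batch; H: node feature node; Ws: wrapped
# score weight (d x 1); graph_id: graph membership per node.
.sat_pool_nodes <- function(tape, Ahat, H, Ws, graph_id, n_graphs, ratio) {
  scores <- ag_spmm(Ahat, ag_matmul(H, Ws, tape), tape)   # n x 1 raw scores
  sv <- as.vector(ag_value(scores))
  keep <- .topk_per_graph(sv, graph_id, n_graphs, ratio)
  readout <- ag_pool_readout(H, scores, keep, graph_id[keep], n_graphs, tape)
  list(readout = readout, scores = scores, keep = keep)
}

# indices of the top ceil(r * n_g) nodes per graph, score-descending,
# ties broken toward the lower node index; returned in ascending index order
.topk_per_graph <- function(scores, graph_id, n_graphs, ratio) {
  stopifnot(ratio > 0, ratio <= 1)
  keep <- integer(0)
  for (g in seq_len(n_graphs)) {
    idx <- which(graph_id == g)
    k <- max(1L, ceiling(ratio * length(idx)))
    ord <- idx[order(-scores[idx], idx)]
    keep <- c(keep, sort(ord[seq_len(k)]))
  }
  keep
}

#' Self-attention pooling node scores
#'
#' One graph convolution (symmetric-normalized adjacency with self-loops)
#' projecting node features to a single channel; returned raw
#' (pre-activation).
#'
#' @param H n x d node features.
#' @param edge_index Edge matrix.
#' @param Ws d x 1 score projection weight.
#' @return Numeric n-vector of raw scores.
#' @export
sat_node_scores <- function(H, edge_index, Ws) {
  Ahat <- normalized_adjacency(edge_index, nrow(H))
  as.vector(as.matrix(Ahat %*% (H %*% Ws)))
}

#' Self-attention pooling readout
#'
#' Keeps the top `ceil(ratio * n)` nodes by score (ties toward the lower
#' residue index), gates kept features by `tanh(score)`, and concatenates
#' the mean and max over kept nodes.
#'
#' @param H n x d node features.
#' @param edge_index Edge matrix.
#' @param Ws d x 1 score projection weight.
#' @param ratio Pooling ratio in (0, 1].
#' @return list(vector = length 2d readout, scores = raw node scores,
#'   kept = kept node indices).
#' @export
sat_pool <- function(H, edge_index, Ws, ratio = 0.5) {
  tape <- ag_tape(train = FALSE)
  Ahat <- normalized_adjacency(edge_index, nrow(H))
  out <- .sat_pool_nodes(tape, Ahat, ag_const(tape, H), ag_param(tape, Ws),
                         rep(1L, nrow(H)), 1L, ratio)
  list(vector = as.vector(ag_value(out$readout)),
       scores = as.vector(ag_value(out$scores)),
       kept = out$keep)
}

#' Per-residue importance scores
#'
#' Min-max normalization of the raw pooling scores within one protein,
#' mapping them to the unit interval; constant scores map to 0.5 by
#' convention.
#'
#' @param scores Raw node scores (e.g. from [sat_node_scores()] or the
#'   localization pooling head of a trained model).
#' @return Numeric vector in the unit interval.
#' @export
residue_importance <- function(scores) {
  rng <- range(scores)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    return(rep(0.5, length(scores)))
  }
  (scores - rng[1]) / diff(rng)
}

#' Export residue importance scores as TSV
#'
#' @param importance Named list of importance vectors keyed by protein id.
#' @param path Output path (columns: protein_id, residue_index 1-based,
#'   importance).
#' @export
write_importance <- function(importance, path) {
  rows <- lapply(names(importance), function(pid) {
    data.frame(protein_id = pid,
               residue_index = seq_along(importance[[pid]]),
               importance = sprintf("%.6f", importance[[pid]]))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
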