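# Per-ontology (BP / CC / MF) branches: a two-layer linear projection, a
# one-layer graph-autoencoder (GCN encoder + inner-product decoder with an
# adjacency-reconstruction MSE), and a pooled MLP score head.

#' Initialize one ontology branch
#'
#' @param d_p Transformer output width.
#' @param d_fe Branch feature width (GAE output).
#' @param n_terms Vocabulary size of the ontology.
#' @return Nested list of parameter matrices (projection, GAE weight,
#'   pooling score weight, head MLP).
#' @export
init_branch_params <- function(d_p, d_fe, n_terms) {
  list(
    W1 = init_weight(d_p, d_fe), b1 = init_bias(d_fe),
    W2 = init_weight(d_fe, d_fe), b2 = init_bias(d_fe),
    Wf = init_weight(d_fe, d_fe),
    pool = list(Ws = init_weight(d_fe, 1L)),
    head = list(Wm1 = init_weight(2L * d_fe, d_fe), bm1 = init_bias(d_fe),
                Wm2 = init_weight(d_fe, n_terms), bm2 = init_bias(n_terms))
  )
}

#' Two stacked affine maps (branch projection)
#'
#' Applied exactly as specified -- two affine layers with no interleaved
#' activation (the composition is itself affine; kept as two parameterized
#' layers for fidelity to the architecture).
#'
#' @param H n x d_p matrix.
#' @param params Branch parameters (uses W1, b1, W2, b2).
#' @return n x d_fe matrix.
#' @export
branch_project <- function(H, params) {
  if (ncol(H) != nrow(params$W1)) stop("shape mismatch in branch_project",
                                       call. = FALSE)
  tape <- ag_tape(train = FALSE)
  pw <- ag_wrap_params(tape, params[c("W1", "b1", "W2", "b2")])
  out <- .branch_project_nodes(tape, ag_const(tape, H), pw)
  ag_value(out)
}

.branch_project_nodes <- function(tape, H, pw) {
  ag_mlp2(H, pw$W1, pw$b1, pw$W2, pw$b2, tape,
          act_hidden = "none", act_out = "none")
}

#' Symmetric-normalized adjacency with self-loops
#'
#' Returns D^(-1/2) (A + I) D^(-1/2) where A is the binary contact adjacency
#' and D the diagonal of row sums of A + I, as a sparse matrix.
#'
#' @param edge_index Directed edge matrix (both directions present).
#' @param n Number of nodes.
#' @return n x n sparse symmetric operator (`dgCMatrix`).
#' @export
normalized_adjacency <- function(edge_index, n) {
  stopifnot(n >= 1L)
  if (nrow(edge_index) > 0L) {
    A <- Matrix::sparseMatrix(i = edge_index[, 1L], j = edge_index[, 2L],
                              x = 1, dims = c(n, n))
    A <- methods::as(1 * ((A + Matrix::t(A)) > 0), "CsparseMatrix")
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  Abar <- A + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(Abar))
  Matrix::Diagonal(n, dinv) %*% Abar %*% Matrix::Diagonal(n, dinv)
}

# dense adjacency-with-self-loops, target of the reconstruction loss
.dense_abar <- function(edge_index, n) {
  A <- matrix(0, n, n)
  if (nrow(edge_index) > 0L) {
    A[edge_index] <- 1
    A <- 1 * ((A + t(A)) > 0)
  }
  diag(A) <- 1
  A
}

#' Graph-autoencoder encoder layer
#'
#' One graph convolution `LeakyReLU(D^(-1/2) Abar D^(-1/2) H W)` with
#' negative slope `slope`.
#'
#' @param H_mid n x d matrix (branch projection output).
#' @param edge_index Edge matrix.
#' @param W d x d_fe weight matrix (element `Wf` of branch params).
#' @param slope LeakyReLU negative slope.
#' @return n x d_fe matrix.
#' @export
gae_encode <- function(H_mid, edge_index, W, slope = 0.01) {
  if (ncol(H_mid) != nrow(W)) stop("shape mismatch in gae_encode", call. = FALSE)
  Ahat <- normalized_adjacency(edge_index, nrow(H_mid))
  tape <- ag_tape(train = FALSE)
  out <- .gae_encode_nodes(tape, Ahat, ag_const(tape, H_mid),
                           ag_param(tape, W), slope)
  ag_value(out)
}

.gae_encode_nodes <- function(tape, Ahat, H, Wf, slope = 0.01) {
  ag_leaky_relu(ag_spmm(Ahat, ag_matmul(H, Wf, tape), tape), tape, slope)
}

#' Adjacency reconstruction loss of a graph autoencoder
#'
#' The decoder is the inner product: `Ahat_uv = sigmoid(<H_u, H_v>)`.  The
#' loss is the mean squared error over all n^2 entries against the binary
#' adjacency with self-loops (the same Abar the encoder normalizes).
#'
#' @param H_fun n x d_fe encoded features.
#' @param edge_index Edge matrix.
#' @param n Number of nodes.
#' @return Nonnegative scalar.
#' @export
gae_reconstruction_loss <- function(H_fun, edge_index, n = nrow(H_fun)) {
  tape <- ag_tape(train = FALSE)
  out <- .gae_recon_nodes(tape, ag_const(tape, H_fun),
                          .dense_abar(edge_index, n))
  ag_value(out)[1L]
}

.gae_recon_nodes <- function(tape, H, Abar) {
  S <- ag_sigmoid(ag_matmul_t(H, H, tape), tape)
  ag_mse(S, Abar, tape)
}

# pooled 2-layer MLP head with sigmoid outputs; hw = wrapped head params
.score_head_nodes <- function(tape, pooled, hw) {
  ag_mlp2(pooled, hw$Wm1, hw$bm1, hw$Wm2, hw$bm2, tape,
          act_hidden = "relu", act_out = "sigmoid")
}

#' Ontology score head: self-attention pooling + MLP
#'
#' @param H_fun n x d_fe branch features.
#' @param edge_index Edge matrix.
#' @param params Branch parameters (uses `pool$Ws` and `head`).
#' @param ratio Pooling ratio in (0, 1].
#' @return Score vector in (0,1)^M for the branch vocabulary.
#' @export
function_scores <- function(H_fun, edge_index, params, ratio = 0.5) {
  tape <- ag_tape(train = FALSE)
  pw <- ag_wrap_params(tape, params[c("pool", "head")])
  Ahat <- normalized_adjacency(edge_index, nrow(H_fun))
  pooled <- .sat_pool_nodes(tape, Ahat, ag_const(tape, H_fun), pw$pool$Ws,
                            rep(1L, nrow(H_fun)), 1L, ratio)
  as.vector(ag_value(.score_head_nodes(tape, pooled$readout, pw$head)))
}
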