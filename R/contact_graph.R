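# Residue contact graphs: edges between alpha carbons within a distance
# threshold, geometric edge features, and node features from a pluggable
# per-residue embedding provider.

#' Build the residue contact map
#'
#' Edges connect every unordered residue pair whose Ca-Ca Euclidean distance
#' is at most `threshold` (inclusive); both directions are stored.  Isolated
#' nodes are permitted.
#'
#' @param coords n x 3 matrix of Ca positions (Angstroms).
#' @param threshold Contact distance threshold in Angstroms (default 4.5).
#' @return Integer matrix with columns `i`, `j` (1-based, i = target node of
#'   a message from j), sorted by i then j.
#' @export
build_contact_map <- function(coords, threshold = 4.5) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1L, ncol(coords) == 3L, threshold > 0)
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  n <- nrow(coords)
  if (n == 1L) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  }
  dm <- as.matrix(stats::dist(coords))
  hit <- which(dm <= threshold & row(dm) != col(dm), arr.ind = TRUE)
  ei <- cbind(i = unname(hit[, 1L]), j = unname(hit[, 2L]))
  ei[order(ei[, 1L], ei[, 2L]), , drop = FALSE]
}

# per-node k nearest neighbours (excluding self); distances are compared at
# 1e-8 A resolution with ties broken by residue index, so the ordering is
# stable under rigid motions that perturb exact ties in the last ulp;
# returns list(nbr = n x k index matrix (0 = padding), disp = n x 3k
# displacement matrix, dsum = n-vector of summed neighbour distances)
.knn_geometry <- function(coords, k = 5L) {
  n <- nrow(coords)
  nbr <- matrix(0L, n, k)
  disp <- matrix(0, n, 3L * k)
  dsum <- numeric(n)
  if (n > 1L) {
    dm <- as.matrix(stats::dist(coords))
    for (i in seq_len(n)) {
      d <- dm[i, ]
      ord <- order(round(d, 8L), seq_len(n))
      ord <- ord[ord != i]
      take <- ord[seq_len(min(k, n - 1L))]
      nbr[i, seq_along(take)] <- take
      for (q in seq_along(take)) {
        disp[i, (3L * (q - 1L) + 1L):(3L * q)] <- coords[take[q], ] - coords[i, ]
      }
      dsum[i] <- sum(d[take])
    }
  }
  list(nbr = nbr, disp = disp, dsum = dsum)
}

#' Compute geometric edge features
#'
#' For an edge (i, j) the feature vector concatenates:
#' \itemize{
#'   \item the Ca distance d_ij (1 value);
#'   \item sine and cosine of each component of the displacement
#'     `coords[j,] - coords[i,]` at `n_freq` geometric frequencies
#'     `1, 1/2, 1/4, ...` rad/Angstrom (3 * 2 * n_freq values) --
#'     a translation-invariant positional encoding of relative geometry;
#'   \item displacements from i to its `k_neighbors` spatially nearest
#'     residues, flattened and zero-padded when fewer exist (3 * k values);
#'   \item the summed distance from i to those neighbours and the same sum
#'     for j (2 values).
#' }
#' Defaults give 1 + 24 + 15 + 2 = 42 dimensions.
#'
#' @param coords n x 3 coordinate matrix.
#' @param edge_index Edge matrix from [build_contact_map()].
#' @param n_freq Number of sine/cosine frequencies (default 4).
#' @param k_neighbors Number of nearest neighbours (default 5).
#' @return |E| x d_e numeric matrix, rows aligned with `edge_index`.
#' @export
compute_edge_features <- function(coords, edge_index, n_freq = 4L,
                                  k_neighbors = 5L) {
  coords <- as.matrix(coords)
  ne <- nrow(edge_index)
  d_e <- 1L + 3L * 2L * n_freq + 3L * k_neighbors + 2L
  if (ne == 0L) return(matrix(0, 0L, d_e))
  geo <- .knn_geometry(coords, k_neighbors)
  ii <- edge_index[, 1L]
  jj <- edge_index[, 2L]
  delta <- coords[jj, , drop = FALSE] - coords[ii, , drop = FALSE]
  dij <- sqrt(rowSums(delta * delta))
  freqs <- 2^(-(seq_len(n_freq) - 1L))
  enc <- matrix(0, ne, 6L * n_freq)
  for (f in seq_len(n_freq)) {
    ang <- delta * freqs[f]
    enc[, (6L * (f - 1L) + 1L):(6L * f)] <- cbind(sin(ang), cos(ang))
  }
  feats <- cbind(dij, enc, geo$disp[ii, , drop = FALSE],
                 geo$dsum[ii], geo$dsum[jj])
  dimnames(feats) <- NULL
  stopifnot(ncol(feats) == d_e)
  feats
}

#' Synthetic per-residue embedding provider
#'
#' Emits an L x dim matrix of i.i.d. standard normal features, deterministic
#' for a fixed sequence and seed (the sequence is hashed into the RNG seed).
#' Serves as the default stand-in for a protein language model; real
#' embeddings can be supplied with [table_embedding_provider()].
#'
#' @param dim Embedding dimension.
#' @param seed Base seed.
#' @param n_flank Number of special-token rows emitted at each end (stripped
#'   by [init_node_features()]); default 0.
#' @return An `embedding_provider` object.
#' @export
synthetic_embedding_provider <- function(dim = 16L, seed = 1L, n_flank = 0L) {
  structure(
    list(
      name = "synthetic-gaussian", dim = as.integer(dim),
      n_flank = as.integer(n_flank),
      fn = function(sequence) {
        L <- nchar(sequence)
        h <- sum(utf8ToInt(sequence) * seq_len(L)) %% 1000003L
        with_seed((seed * 7919L + h) %% .Machine$integer.max,
                  matrix(stats::rnorm((L + 2L * n_flank) * dim), ncol = dim))
      }
    ),
    class = "embedding_provider"
  )
}

#' Embedding provider backed by precomputed per-protein matrices
#'
#' @param mats Named list of L x dim matrices keyed by protein id, or a
#'   directory of per-protein TSV files named `<id>.tsv`.
#' @param dim Embedding dimension.
#' @param n_flank Special-token rows at each end to strip.
#' @return An `embedding_provider`; its `fn` takes the protein id.
#' @export
table_embedding_provider <- function(mats, dim, n_flank = 0L) {
  fetch <- if (is.character(mats)) {
    function(id) {
      f <- file.path(mats, paste0(id, ".tsv"))
      if (!file.exists(f)) stop("no embedding file for ", id, call. = FALSE)
      as.matrix(utils::read.table(f, header = FALSE))
    }
  } else {
    function(id) {
      if (is.null(mats[[id]])) stop("no embedding matrix for ", id, call. = FALSE)
      mats[[id]]
    }
  }
  structure(
    list(name = "table", dim = as.integer(dim), n_flank = as.integer(n_flank),
         fn = fetch, by_id = TRUE),
    class = "embedding_provider"
  )
}

#' Initialize node features from an embedding provider
#'
#' Strips the provider's declared flank rows (special tokens), then validates
#' that at least `n = nchar(sequence)` rows remain; extra trailing rows are
#' truncated so row i corresponds to residue i, and a deficit is an error
#' (never silently padded).
#'
#' @param provider An `embedding_provider`.
#' @param sequence Amino-acid string.
#' @param id Protein id (used by table providers).
#' @return n x dim numeric matrix.
#' @export
init_node_features <- function(provider, sequence, id = NULL) {
  stopifnot(inherits(provider, "embedding_provider"))
  raw <- if (isTRUE(provider$by_id)) provider$fn(id) else provider$fn(sequence)
  raw <- as.matrix(raw)
  nf <- provider$n_flank
  if (nf > 0L) {
    keep <- seq.int(nf + 1L, nrow(raw) - nf)
    raw <- raw[keep, , drop = FALSE]
  }
  n <- nchar(sequence)
  if (nrow(raw) < n) {
    stop("embedding provider returned ", nrow(raw), " rows for a length-", n,
         " sequence", call. = FALSE)
  }
  if (ncol(raw) != provider$dim) {
    stop("embedding width ", ncol(raw), " != provider dim ", provider$dim,
         call. = FALSE)
  }
  out <- raw[seq_len(n), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Assemble a residue graph for one protein
#'
#' @param node_feats n x d_h embedding matrix.
#' @param coords n x 3 Ca coordinates.
#' @param threshold Contact threshold (Angstroms).
#' @param n_freq,k_neighbors Edge featurization settings.
#' @return An object of class `residue_graph`: list(node_feats, edge_index,
#'   edge_feats, coords).
#' @export
residue_graph <- function(node_feats, coords, threshold = 4.5, n_freq = 4L,
                          k_neighbors = 5L) {
  node_feats <- as.matrix(node_feats)
  coords <- as.matrix(coords)
  stopifnot(nrow(node_feats) == nrow(coords))
  ei <- build_contact_map(coords, threshold)
  ef <- compute_edge_features(coords, ei, n_freq, k_neighbors)
  structure(
    list(node_feats = node_feats, edge_index = ei, edge_feats = ef,
         coords = coords),
    class = "residue_graph"
  )
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("residue_graph:", nrow(x$node_feats), "residues,",
      nrow(x$edge_index), "directed edges, d_h =", ncol(x$node_feats),
      ", d_e =", ncol(x$edge_feats), "\n")
  invisible(x)
}

#' Save / load a residue-graph cache file
#'
#' One self-describing file per protein (RDS container with a format-version
#' tag), used to avoid re-featurizing between runs.
#' @param graph A `residue_graph`.
#' @param path Cache file path.
#' @export
save_graph_cache <- function(graph, path) {
  saveRDS(list(format = "gtloc-graph", version = 1L, graph = graph), path)
  invisible(path)
}

#' @rdname save_graph_cache
#' @export
load_graph_cache <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "gtloc-graph")) {
    stop("not a gtloc graph cache: ", path, call. = FALSE)
  }
  obj$graph
}

# merge several residue graphs into one block-diagonal batch
merge_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) nrow(g$node_feats), 1L)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  ei <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    e <- graphs[[k]]$edge_index
    if (nrow(e) == 0L) return(matrix(integer(0), 0L, 2L))
    e + offs[k]
  }))
  list(
    node_feats = do.call(rbind, lapply(graphs, `[[`, "node_feats")),
    edge_feats = do.call(rbind, lapply(graphs, `[[`, "edge_feats")),
    edge_index = ei,
    graph_id = rep(seq_along(graphs), ns),
    n_nodes = sum(ns),
    n_graphs = length(graphs),
    sizes = ns,
    offsets = offs
  )
}
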