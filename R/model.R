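# Model configuration, parameter initialization, and the end-to-end forward
# pass over a (merged) batch of residue graphs:
#   graph transformer -> three ontology branches (projection + GAE +
#   score head) -> nLinear x3 -> functional cross-attention -> fusion ->
#   localization head.

#' Model configuration
#'
#' Collects every dimension, head count, loss weight and ablation flag.
#'
#' @param d_h Node embedding input dimension.
#' @param d_e Edge feature input dimension (42 for the default featurizer).
#' @param d_p Transformer width (`h_d * d_k`).
#' @param h_d Transformer attention heads.
#' @param n_layers Transformer layers.
#' @param d_fe Ontology branch feature width (`h_ki * d_ki`).
#' @param d_F Fused localization feature width.
#' @param h_ki Cross-attention heads per group.
#' @param n_groups Cross-attention groups.
#' @param ratio Self-attention pooling ratio in (0, 1].
#' @param M_bp,M_cc,M_mf GO vocabulary sizes.
#' @param C Number of localization classes.
#' @param alpha,beta,omega Loss weights (function BCE, reconstruction MSE,
#'   localization BCE).
#' @param lr Adam learning rate (the peak rate under the cosine schedule).
#' @param lr_schedule "constant", or "cosine" (linear warmup over
#'   `warmup_epochs`, then cosine decay to `lr_min` at the final epoch).
#' @param warmup_epochs Warmup epochs for the cosine schedule.
#' @param lr_min Final learning rate of the cosine schedule.
#' @param grad_clip Global gradient-norm clipping threshold (Inf disables).
#' @param weight_decay Decoupled (AdamW-style) weight decay coefficient.
#' @param epochs Training epochs.
#' @param batch_size Proteins per batch (merged as disjoint graphs).
#' @param seed Seed controlling initialization and data order.
#' @param contact_threshold Contact-map distance threshold (Angstroms).
#' @param leaky_slope LeakyReLU negative slope in the GAE encoder.
#' @param bn_momentum Batch-norm running-statistics momentum.
#' @param no_gt,no_funA,no_feaE,no_colT Ablation flags: drop the graph
#'   transformer (projection only), replace cross-attention by a summed
#'   nLinear path, bypass the GAE (forces beta = 0), or zero the auxiliary
#'   loss weights (alpha = beta = 0).
#' @return Object of class `model_config`.
#' @export
model_config <- function(d_h = 16L, d_e = 42L, d_p = 128L, h_d = 4L,
                         n_layers = 2L, d_fe = 64L, d_F = d_fe, h_ki = 4L,
                         n_groups = 3L, ratio = 0.5,
                         M_bp = 8L, M_cc = 5L, M_mf = 5L, C = 10L,
                         alpha = 1, beta = 1, omega = 1,
                         lr = 1e-4, lr_schedule = c("constant", "cosine"),
                         warmup_epochs = 2L, lr_min = lr / 20,
                         grad_clip = Inf, weight_decay = 0, epochs = 50L,
                         batch_size = 8L,
                         seed = 1L, contact_threshold = 4.5,
                         leaky_slope = 0.01, bn_momentum = 0.1,
                         no_gt = FALSE, no_funA = FALSE, no_feaE = FALSE,
                         no_colT = FALSE) {
  if (d_p %% h_d != 0L) stop("d_p must be divisible by h_d", call. = FALSE)
  if (d_fe %% h_ki != 0L) stop("d_fe must be divisible by h_ki", call. = FALSE)
  stopifnot(epochs >= 1L, contact_threshold > 0, ratio > 0, ratio <= 1,
            alpha >= 0, beta >= 0, omega >= 0)
  structure(
    list(d_h = as.integer(d_h), d_e = as.integer(d_e), d_p = as.integer(d_p),
         h_d = as.integer(h_d), n_layers = as.integer(n_layers),
         d_fe = as.integer(d_fe), d_F = as.integer(d_F),
         h_ki = as.integer(h_ki), n_groups = as.integer(n_groups),
         ratio = ratio, M_bp = as.integer(M_bp), M_cc = as.integer(M_cc),
         M_mf = as.integer(M_mf), C = as.integer(C),
         alpha = alpha, beta = beta, omega = omega, lr = lr,
         lr_schedule = match.arg(lr_schedule), warmup_epochs =
           as.integer(warmup_epochs), lr_min = lr_min,
         grad_clip = grad_clip, weight_decay = weight_decay,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), contact_threshold = contact_threshold,
         leaky_slope = leaky_slope, bn_momentum = bn_momentum,
         no_gt = isTRUE(no_gt), no_funA = isTRUE(no_funA),
         no_feaE = isTRUE(no_feaE), no_colT = isTRUE(no_colT)),
    class = "model_config"
  )
}

# effective loss weights after ablation rerouting
.effective_weights <- function(cfg) {
  alpha <- cfg$alpha; beta <- cfg$beta; omega <- cfg$omega
  if (cfg$no_colT) { alpha <- 0; beta <- 0 }
  if (cfg$no_feaE) beta <- 0
  list(alpha = alpha, beta = beta, omega = omega)
}

#' Initialize a model from a configuration
#'
#' All weights are drawn under `config$seed`; batch-norm running statistics
#' start at mean 0 / variance 1.
#'
#' @param config A [model_config()].
#' @param vocab Optional list of term-name vectors (bp, cc, mf, sl) used to
#'   name score columns; generic names otherwise.
#' @return Object of class `gtloc_model`.
#' @export
init_model <- function(config, vocab = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(vocab)) {
    vocab <- list(bp = paste0("bp", seq_len(config$M_bp)),
                  cc = paste0("cc", seq_len(config$M_cc)),
                  mf = paste0("mf", seq_len(config$M_mf)),
                  sl = paste0("sl", seq_len(config$C)))
  }
  stopifnot(length(vocab$bp) == config$M_bp, length(vocab$cc) == config$M_cc,
            length(vocab$mf) == config$M_mf, length(vocab$sl) == config$C)
  params <- with_seed(config$seed, list(
    gt = init_gt_params(config$d_h, config$d_e, config$d_p, config$n_layers),
    branch = list(
      bp = init_branch_params(config$d_p, config$d_fe, config$M_bp),
      cc = init_branch_params(config$d_p, config$d_fe, config$M_cc),
      mf = init_branch_params(config$d_p, config$d_fe, config$M_mf)
    ),
    funA = init_fun_attention_params(config$d_fe, config$d_F, config$n_groups),
    sl = init_sl_head_params(config$d_F, config$C)
  ))
  structure(
    list(config = config, params = params,
         bn = gt_bn_states(config$d_p, config$n_layers, config$bn_momentum),
         vocab = vocab),
    class = "gtloc_model"
  )
}

#' @export
print.gtloc_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(flatten_params(x$params), length, 1L))
  cat(sprintf(
    "gtloc_model: d_p=%d (%d heads, %d layers), d_fe=%d, d_F=%d, %d params\n",
    cfg$d_p, cfg$h_d, cfg$n_layers, cfg$d_fe, cfg$d_F, np))
  cat(sprintf("  vocab: %d BP, %d CC, %d MF terms, %d localization classes\n",
              cfg$M_bp, cfg$M_cc, cfg$M_mf, cfg$C))
  invisible(x)
}

# full forward pass on the tape over a merged batch.
# Returns score nodes per task, recon-loss nodes per branch (or NULL when
# the GAE is bypassed), and the raw localization pooling scores.
.forward_nodes <- function(tape, pw, bn, batch, cfg) {
  G <- batch$n_graphs
  st <- .gt_project_nodes(tape, ag_const(tape, batch$node_feats),
                          ag_const(tape, batch$edge_feats), pw$gt$proj)
  if (!cfg$no_gt) {
    for (l in seq_len(cfg$n_layers)) {
      st <- .gt_layer_nodes(tape, st$H, st$E, batch$edge_index,
                            pw$gt$layers[[l]], bn[[l]], cfg$h_d,
                            skip_edge_update = (l == cfg$n_layers))
    }
  }
  Ahat <- normalized_adjacency(batch$edge_index, batch$n_nodes)
  # the reconstruction loss is only materialized when its weight reaches
  # the total loss; its value does not feed the score paths
  want_recon <- !cfg$no_feaE && .effective_weights(cfg)$beta > 0
  abars <- if (want_recon) {
    lapply(seq_len(G), function(g) {
      idx <- which(batch$graph_id == g)
      sub <- batch$edge_index[batch$edge_index[, 1L] %in% idx, , drop = FALSE]
      .dense_abar(sub - batch$offsets[g], length(idx))
    })
  }

  branch_out <- list()
  for (t in c("bp", "cc", "mf")) {
    bw <- pw$branch[[t]]
    Hmid <- .branch_project_nodes(tape, st$H, bw)
    if (cfg$no_feaE) {
      Hfun <- Hmid
      recon <- NULL
    } else {
      Hfun <- .gae_encode_nodes(tape, Ahat, Hmid, bw$Wf, cfg$leaky_slope)
      recon <- if (want_recon) ag_mean_list(lapply(seq_len(G), function(g) {
        idx <- which(batch$graph_id == g)
        ag_gae_recon(Hfun, idx, abars[[g]], tape)
      }), tape)
    }
    pooled <- .sat_pool_nodes(tape, Ahat, Hfun, bw$pool$Ws, batch$graph_id, G,
                              cfg$ratio)
    branch_out[[t]] <- list(
      Hfun = Hfun, recon = recon,
      scores = .score_head_nodes(tape, pooled$readout, bw$head)
    )
  }

  nl <- list(
    bp = .nlinear_nodes(tape, branch_out$bp$Hfun, pw$funA$nlin$bp),
    cc = .nlinear_nodes(tape, branch_out$cc$Hfun, pw$funA$nlin$cc),
    mf = .nlinear_nodes(tape, branch_out$mf$Hfun, pw$funA$nlin$mf)
  )
  if (cfg$no_funA) {
    mixed <- ag_sum_list(list(nl$bp, nl$cc, nl$mf), tape)
    HF <- ag_relu(ag_matmul(mixed, pw$funA$Ot, tape), tape)
    ffn <- ag_relu(ag_matmul(ag_relu(ag_matmul(HF, pw$funA$W_F1, tape), tape),
                             pw$funA$W_F2, tape), tape)
    HSL <- ag_add(HF, ffn, tape)
  } else {
    groups <- .cross_attend_nodes(tape, nl$bp, nl$mf, nl$cc, pw$funA$groups,
                                  batch$graph_id, G, cfg$h_ki)
    HSL <- .fuse_nodes(tape, groups, pw$funA)
  }
  sl_pool <- .sat_pool_nodes(tape, Ahat, HSL, pw$sl$pool$Ws, batch$graph_id, G,
                             cfg$ratio)
  sl_scores <- .score_head_nodes(tape, sl_pool$readout, pw$sl$head)

  list(scores = list(bp = branch_out$bp$scores, cc = branch_out$cc$scores,
                     mf = branch_out$mf$scores, sl = sl_scores),
       recon = list(bp = branch_out$bp$recon, cc = branch_out$cc$recon,
                    mf = branch_out$mf$recon),
       sl_node_scores = sl_pool$scores)
}

# attach losses to a forward pass; labels: list(bp, cc, mf, sl) of G x M
# matrices.  Returns list(total = scalar node, components = numeric list).
.loss_nodes <- function(tape, fw, labels, cfg) {
  w <- .effective_weights(cfg)
  bce <- list(
    bp = ag_bce(fw$scores$bp, labels$bp, tape),
    cc = ag_bce(fw$scores$cc, labels$cc, tape),
    mf = ag_bce(fw$scores$mf, labels$mf, tape),
    sl = ag_bce(fw$scores$sl, labels$sl, tape)
  )
  zero <- function() numeric(1)
  comp <- list(
    bp_bce = ag_value(bce$bp)[1L], cc_bce = ag_value(bce$cc)[1L],
    mf_bce = ag_value(bce$mf)[1L],
    bp_mse = if (is.null(fw$recon$bp)) 0 else ag_value(fw$recon$bp)[1L],
    cc_mse = if (is.null(fw$recon$cc)) 0 else ag_value(fw$recon$cc)[1L],
    mf_mse = if (is.null(fw$recon$mf)) 0 else ag_value(fw$recon$mf)[1L],
    sl = ag_value(bce$sl)[1L]
  )
  terms <- list()
  if (w$alpha > 0) {
    terms <- c(terms, list(ag_scale(ag_sum_list(bce[c("bp", "cc", "mf")], tape),
                                    w$alpha, tape)))
  }
  if (w$beta > 0 && !is.null(fw$recon$bp)) {
    terms <- c(terms, list(ag_scale(
      ag_sum_list(fw$recon[c("bp", "cc", "mf")], tape), w$beta, tape)))
  }
  if (w$omega > 0) terms <- c(terms, list(ag_scale(bce$sl, w$omega, tape)))
  total <- if (length(terms) == 0L) ag_scale(bce$sl, 0, tape)
           else if (length(terms) == 1L) terms[[1L]]
           else ag_sum_list(terms, tape)
  list(total = total, components = comp, weights = w)
}

#' Run the model forward on a single protein
#'
#' @param model A `gtloc_model`.
#' @param graph A `residue_graph` built with the model's configuration.
#' @param labels Optional named list of binary label vectors (bp, cc, mf,
#'   sl); when supplied, the loss bundle is computed.
#' @param train Use batch statistics and update running batch-norm stats.
#' @return list(scores = named list of score vectors per task,
#'   importance = per-residue importance in the unit interval, loss = `loss_bundle` or
#'   NULL).
#' @export
forward_protein <- function(model, graph, labels = NULL, train = FALSE) {
  batch <- merge_graphs(list(graph))
  cfg <- model$config
  tape <- ag_tape(train = train)
  pw <- ag_wrap_params(tape, model$params)
  fw <- .forward_nodes(tape, pw, model$bn, batch, cfg)
  scores <- lapply(fw$scores, function(s) as.vector(ag_value(s)))
  names(scores$bp) <- model$vocab$bp; names(scores$cc) <- model$vocab$cc
  names(scores$mf) <- model$vocab$mf; names(scores$sl) <- model$vocab$sl
  loss <- NULL
  if (!is.null(labels)) {
    lab <- lapply(c("bp", "cc", "mf", "sl"), function(t) {
      matrix(labels[[t]], nrow = 1L)
    })
    names(lab) <- c("bp", "cc", "mf", "sl")
    ln <- .loss_nodes(tape, fw, lab, cfg)
    loss <- total_loss(ln$components, ln$weights$alpha, ln$weights$beta,
                       ln$weights$omega)
  }
  list(scores = scores,
       importance = residue_importance(as.vector(ag_value(fw$sl_node_scores))),
       loss = loss)
}
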