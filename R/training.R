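# Training, prediction and evaluation orchestration.

#' Assemble a training dataset from records
#'
#' Builds one residue graph per protein (contact map + edge features + node
#' features from the provider) and stacks the label vectors into matrices.
#'
#' @param records List of protein records: each a list with `id`,
#'   `sequence`, `coords`, and binary label vectors `go_bp`, `go_cc`,
#'   `go_mf`, `sl` (as produced by [generate_protein()] or read from disk).
#' @param provider An `embedding_provider`; records carrying their own
#'   `embedding` matrix (synthetic data) may set `provider = NULL`.
#' @param config A [model_config()] (contact threshold and featurization).
#' @return Object of class `gtloc_dataset`: list(ids, graphs, labels).
#' @export
prepare_dataset <- function(records, provider = NULL, config = model_config()) {
  ids <- vapply(records, `[[`, "", "id")
  graphs <- lapply(records, function(r) {
    emb <- if (!is.null(r$embedding)) {
      r$embedding
    } else if (!is.null(provider)) {
      init_node_features(provider, r$sequence, id = r$id)
    } else {
      stop("record ", r$id, " has no embedding and no provider given",
           call. = FALSE)
    }
    residue_graph(emb, r$coords, threshold = config$contact_threshold)
  })
  labels <- list(
    bp = do.call(rbind, lapply(records, `[[`, "go_bp")),
    cc = do.call(rbind, lapply(records, `[[`, "go_cc")),
    mf = do.call(rbind, lapply(records, `[[`, "go_mf")),
    sl = do.call(rbind, lapply(records, `[[`, "sl"))
  )
  for (t in names(labels)) rownames(labels[[t]]) <- ids
  structure(list(ids = ids, graphs = graphs, labels = labels),
            class = "gtloc_dataset")
}

#' Subset a dataset by protein id or index
#' @param data A `gtloc_dataset`.
#' @param which Ids (character) or indices (integer).
#' @return A `gtloc_dataset`.
#' @export
subset_dataset <- function(data, which) {
  idx <- if (is.character(which)) match(which, data$ids) else which
  structure(
    list(ids = data$ids[idx], graphs = data$graphs[idx],
         labels = lapply(data$labels, function(m) m[idx, , drop = FALSE])),
    class = "gtloc_dataset"
  )
}

# snapshot / restore batch-norm running statistics (environments)
.bn_snapshot <- function(bn) {
  lapply(bn, function(layer) lapply(layer, function(st) {
    list(rm = st$rm, rv = st$rv, momentum = st$momentum)
  }))
}

.bn_restore <- function(bn, snap) {
  for (l in seq_along(bn)) {
    for (k in names(bn[[l]])) {
      bn[[l]][[k]]$rm <- snap[[l]][[k]]$rm
      bn[[l]][[k]]$rv <- snap[[l]][[k]]$rv
    }
  }
  invisible(bn)
}

#' Train a model with the collaborative multi-task loss
#'
#' Adam optimization of the weighted total loss over shuffled mini-batches
#' of disjoint graphs.  When a validation set is given, per-epoch validation
#' metrics are logged and the parameters with the best validation
#' localization AP are retained.  Fully reproducible under the
#' configuration seed.
#'
#' @param model A `gtloc_model` from [init_model()].
#' @param train_data A `gtloc_dataset`.
#' @param valid_data Optional `gtloc_dataset` for model selection.
#' @param epochs Override `config$epochs`.
#' @param verbose Print per-epoch summaries.
#' @return The model with trained parameters, plus `$logs` (per-epoch loss
#'   components and validation AP) and `$best_epoch`.
#' @export
train_model <- function(model, train_data, valid_data = NULL, epochs = NULL,
                        verbose = FALSE) {
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  params <- model$params
  opt <- adam_state(params, lr = cfg$lr)
  n <- length(train_data$graphs)
  logs <- NULL
  best_ap <- -Inf
  best_params <- params
  best_bn <- .bn_snapshot(model$bn)
  best_epoch <- 0L

  lr_at <- function(ep) {
    if (identical(cfg$lr_schedule, "constant")) return(cfg$lr)
    if (ep <= cfg$warmup_epochs) return(cfg$lr * ep / cfg$warmup_epochs)
    frac <- (ep - cfg$warmup_epochs) / max(1L, epochs - cfg$warmup_epochs)
    cfg$lr_min + (cfg$lr - cfg$lr_min) * (1 + cos(pi * frac)) / 2
  }

  with_seed(cfg$seed * 2L + 1L, {
    for (ep in seq_len(epochs)) {
      opt$lr <- lr_at(ep)
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      comp_sums <- numeric(8)
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        batch <- merge_graphs(train_data$graphs[idx])
        labels <- lapply(train_data$labels, function(m) m[idx, , drop = FALSE])
        tape <- ag_tape(train = TRUE)
        pw <- ag_wrap_params(tape, params)
        fw <- .forward_nodes(tape, pw, model$bn, batch, cfg)
        ln <- .loss_nodes(tape, fw, labels, cfg)
        if (!is.finite(ag_value(ln$total)[1L])) {
          stop("non-finite loss at epoch ", ep, " (proteins ",
               paste(train_data$ids[idx], collapse = ","), ")", call. = FALSE)
        }
        ag_backward(tape, ln$total)
        grads <- ag_collect_grads(pw)
        stepped <- adam_step(params, grads, opt, clip = cfg$grad_clip,
                             weight_decay = cfg$weight_decay)
        params <- stepped$params
        opt <- stepped$opt
        wgt <- length(idx) / n
        lb <- total_loss(ln$components, ln$weights$alpha, ln$weights$beta,
                         ln$weights$omega)
        comp_sums <- comp_sums + wgt * c(lb$bp_bce, lb$cc_bce, lb$mf_bce,
                                         lb$bp_mse, lb$cc_mse, lb$mf_mse,
                                         lb$sl, lb$total)
      }
      row <- data.frame(epoch = ep, bp_bce = comp_sums[1], cc_bce = comp_sums[2],
                        mf_bce = comp_sums[3], bp_mse = comp_sums[4],
                        cc_mse = comp_sums[5], mf_mse = comp_sums[6],
                        sl = comp_sums[7], total = comp_sums[8],
                        valid_sl_ap = NA_real_)
      if (!is.null(valid_data)) {
        tmp <- model; tmp$params <- params
        # eval-mode output is batch-independent, so large batches are safe
        pred <- predict_proteins(tmp, valid_data$graphs,
                                 batch_size = max(cfg$batch_size, 16L))
        ap <- suppressWarnings(
          evaluate_multilabel(pred$scores$sl, valid_data$labels$sl)$ap)
        row$valid_sl_ap <- ap
        if (is.finite(ap) && ap > best_ap) {
          best_ap <- ap
          best_params <- params
          best_bn <- .bn_snapshot(model$bn)
          best_epoch <- ep
        }
      }
      logs <- rbind(logs, row)
      if (verbose) {
        message(sprintf("epoch %3d: total %.4f  sl %.4f  valid AP %s",
                        ep, row$total, row$sl,
                        ifelse(is.na(row$valid_sl_ap), "-",
                               sprintf("%.4f", row$valid_sl_ap))))
      }
    }
  })
  if (is.null(valid_data)) {
    model$params <- params
    model$best_epoch <- nrow(logs)
  } else {
    model$params <- best_params
    .bn_restore(model$bn, best_bn)
    model$best_epoch <- best_epoch
    model$final_params <- params
  }
  model$logs <- logs
  model
}

#' Predict scores and residue importances for a set of graphs
#'
#' Evaluation mode: batch-norm uses frozen running statistics, so output is
#' deterministic and independent of batch composition.
#'
#' @param model A trained `gtloc_model`.
#' @param graphs List of `residue_graph` objects.
#' @param ids Optional protein ids (names for the outputs).
#' @param batch_size Graphs per forward pass.
#' @return list(scores = list of score matrices per task (bp, cc, mf, sl),
#'   importance = list of per-residue importance vectors).
#' @export
predict_proteins <- function(model, graphs, ids = NULL,
                             batch_size = model$config$batch_size) {
  cfg <- model$config
  n <- length(graphs)
  if (is.null(ids)) ids <- paste0("protein", seq_len(n))
  out <- list(bp = NULL, cc = NULL, mf = NULL, sl = NULL)
  importance <- vector("list", n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- merge_graphs(graphs[idx])
    tape <- ag_tape(train = FALSE)
    pw <- ag_wrap_params(tape, model$params)
    fw <- .forward_nodes(tape, pw, model$bn, batch, cfg)
    for (t in names(out)) out[[t]] <- rbind(out[[t]], ag_value(fw$scores[[t]]))
    nsc <- as.vector(ag_value(fw$sl_node_scores))
    for (k in seq_along(idx)) {
      importance[[idx[k]]] <-
        residue_importance(nsc[batch$graph_id == k])
    }
  }
  colnames(out$bp) <- model$vocab$bp; colnames(out$cc) <- model$vocab$cc
  colnames(out$mf) <- model$vocab$mf; colnames(out$sl) <- model$vocab$sl
  for (t in names(out)) rownames(out[[t]]) <- ids
  names(importance) <- ids
  list(scores = out, importance = importance)
}

#' Format predictions for [write_predictions()]
#' @param pred Output of [predict_proteins()].
#' @return Nested named list keyed by protein, task, term.
#' @export
prediction_bundle <- function(pred) {
  ids <- rownames(pred$scores$sl)
  stats::setNames(lapply(ids, function(pid) {
    lapply(pred$scores, function(m) m[pid, ])
  }), ids)
}

#' Evaluate a trained model on a dataset
#'
#' @param model A trained `gtloc_model`.
#' @param data A `gtloc_dataset`.
#' @return Named list of `metric_report` objects for tasks bp, cc, mf, sl.
#' @export
evaluate_model <- function(model, data) {
  pred <- predict_proteins(model, data$graphs, ids = data$ids)
  out <- lapply(c(bp = "bp", cc = "cc", mf = "mf", sl = "sl"), function(t) {
    suppressWarnings(evaluate_multilabel(pred$scores[[t]], data$labels[[t]]))
  })
  out
}

#' Train an ablation variant
#'
#' @param config Base [model_config()].
#' @param variant One of "full", "no_gt", "no_funA", "no_feaE", "no_colT".
#' @param train_data,valid_data Datasets.
#' @param epochs Override epochs.
#' @param vocab Optional vocabulary for [init_model()].
#' @return Trained `gtloc_model`.
#' @export
train_ablation <- function(config, variant, train_data, valid_data = NULL,
                           epochs = NULL, vocab = NULL) {
  variant <- match.arg(variant,
                       c("full", "no_gt", "no_funA", "no_feaE", "no_colT"))
  if (variant != "full") config[[variant]] <- TRUE
  class(config) <- "model_config"
  model <- init_model(config, vocab)
  train_model(model, train_data, valid_data, epochs = epochs)
}

#' Save a model checkpoint
#'
#' A versioned container of all parameter matrices, batch-norm statistics,
#' configuration and vocabulary; reload is bit-exact.
#'
#' @param model A `gtloc_model`.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "gtloc-checkpoint", version = 1L,
               config = model$config, params = model$params,
               bn = .bn_snapshot(model$bn), vocab = model$vocab), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "gtloc-checkpoint")) {
    stop("not a gtloc checkpoint: ", path, call. = FALSE)
  }
  model <- init_model(obj$config, obj$vocab)
  model$params <- obj$params
  .bn_restore(model$bn, obj$bn)
  model
}
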