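# Multi-label evaluation suite.
#
# Macro (per-label) metrics: average precision, AUROC, area under the
# monotone-interpolated precision-recall curve.  Example-based metrics:
# Jaccard accuracy and Hamming loss at threshold 0.5, ranking loss
# (mis-ordered positive/negative pairs, ties counted half), one-error
# (top-scored label not a true positive), and the protein-centric Fmax over
# 99 thresholds (CAFA convention).

# average precision of one label column (step-wise sum of P at recall steps)
.ap_binary <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  npos <- sum(lab)
  if (npos == 0L) return(NA_real_)
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / npos
}

# AUROC via the rank-sum statistic with midranks for ties
.auroc_binary <- function(scores, labels) {
  npos <- sum(labels)
  nneg <- length(labels) - npos
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# area under the monotone-interpolated precision-recall curve
.aupr_binary <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  npos <- sum(lab)
  if (npos == 0L) return(NA_real_)
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / npos
  prec_env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * prec_env)
}

# precision-recall table of one label column (points at each rank)
.pr_binary <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  npos <- sum(lab)
  if (npos == 0L) return(data.frame(recall = numeric(0), precision = numeric(0)))
  tp <- cumsum(lab)
  data.frame(recall = tp / npos, precision = tp / seq_along(lab))
}

#' Evaluate multi-label predictions
#'
#' @param scores N x C matrix of prediction scores.
#' @param labels N x C binary matrix.
#' @param threshold Decision threshold for the set-valued metrics (Acc,
#'   Hamming loss).
#' @param fmax_thresholds Grid of thresholds for Fmax.
#' @return Object of class `metric_report` with fields `ap`, `auroc`,
#'   `aupr`, `acc`, `fmax`, `fmax_tau`, `hloss`, `rl`, `oerror` and
#'   `n_labels_skipped` (labels with a single class, excluded from the
#'   macro averages with a warning).
#' @export
evaluate_multilabel <- function(scores, labels, threshold = 0.5,
                                fmax_thresholds = seq(0.01, 0.99, by = 0.01)) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (!all(dim(scores) == dim(labels))) stop("shape mismatch", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  if (sum(labels) == 0L || sum(labels) == length(labels)) {
    stop("need at least one positive and one negative label overall",
         call. = FALSE)
  }
  N <- nrow(scores); C <- ncol(scores)

  single_class <- vapply(seq_len(C), function(j) {
    s <- sum(labels[, j]); s == 0L || s == N
  }, TRUE)
  if (any(single_class)) {
    warning(sum(single_class),
            " label(s) with a single class skipped in macro averages",
            call. = FALSE)
  }
  usable <- which(!single_class)
  macro <- function(f) {
    mean(vapply(usable, function(j) f(scores[, j], labels[, j]), 1))
  }
  ap <- macro(.ap_binary)
  auroc <- macro(.auroc_binary)
  aupr <- macro(.aupr_binary)

  pred <- 1 * (scores >= threshold)
  hloss <- mean(pred != labels)
  acc <- mean(vapply(seq_len(N), function(i) {
    inter <- sum(pred[i, ] == 1 & labels[i, ] == 1)
    uni <- sum(pred[i, ] == 1 | labels[i, ] == 1)
    if (uni == 0L) 1 else inter / uni
  }, 1))

  # protein-centric Fmax
  has_pos <- rowSums(labels) > 0
  fvals <- vapply(fmax_thresholds, function(tau) {
    ptau <- scores >= tau
    npred <- rowSums(ptau)
    tp <- rowSums(ptau & labels == 1)
    covered <- npred > 0
    prec <- if (any(covered)) mean(tp[covered] / npred[covered]) else 0
    rec <- if (any(has_pos)) mean(tp[has_pos] / rowSums(labels)[has_pos]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, 1)
  fmax <- max(fvals)
  fmax_tau <- fmax_thresholds[which.max(fvals)]

  # ranking loss and one-error (examples without positives skipped)
  rl_vals <- oe_vals <- numeric(0)
  for (i in seq_len(N)) {
    pos <- which(labels[i, ] == 1)
    neg <- which(labels[i, ] == 0)
    if (length(pos) > 0L) {
      top <- which.max(scores[i, ])
      oe_vals <- c(oe_vals, as.numeric(labels[i, top] == 0))
    }
    if (length(pos) > 0L && length(neg) > 0L) {
      sp <- scores[i, pos]; sn <- scores[i, neg]
      bad <- sum(outer(sp, sn, `<`)) + 0.5 * sum(outer(sp, sn, `==`))
      rl_vals <- c(rl_vals, bad / (length(pos) * length(neg)))
    }
  }
  rl <- if (length(rl_vals)) mean(rl_vals) else NA_real_
  oerror <- if (length(oe_vals)) mean(oe_vals) else NA_real_

  structure(
    list(ap = ap, auroc = auroc, aupr = aupr, acc = acc, fmax = fmax,
         fmax_tau = fmax_tau, hloss = hloss, rl = rl, oerror = oerror,
         n_labels_skipped = sum(single_class)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    paste0("metric_report: AP %.4f | AUROC %.4f | AUPR %.4f | Acc %.4f | ",
           "Fmax %.4f (tau %.2f)\n  Hloss %.4f | RL %.4f | Oerror %.4f\n"),
    x$ap, x$auroc, x$aupr, x$acc, x$fmax, x$fmax_tau, x$hloss, x$rl, x$oerror))
  invisible(x)
}

#' Serialize a metric report as JSON
#' @param report A `metric_report`.
#' @param path Output path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-class precision-recall curves
#'
#' @param scores N x C score matrix.
#' @param labels N x C binary matrix.
#' @param class_names Optional column names.
#' @return data.frame with columns class, recall, precision; classes without
#'   positives yield no rows (with a warning).
#' @export
pr_curves <- function(scores, labels, class_names = colnames(scores)) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(scores)))
  out <- list()
  for (j in seq_len(ncol(scores))) {
    tab <- .pr_binary(scores[, j], labels[, j])
    if (nrow(tab) == 0L) {
      warning("class ", class_names[j], " has no positives; empty PR curve",
              call. = FALSE)
      next
    }
    tab$class <- class_names[j]
    out[[length(out) + 1L]] <- tab[, c("class", "recall", "precision")]
  }
  if (length(out) == 0L) {
    return(data.frame(class = character(0), recall = numeric(0),
                      precision = numeric(0)))
  }
  do.call(rbind, out)
}
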