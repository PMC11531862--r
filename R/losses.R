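# Task losses and the collaborative total:
#   L_total = alpha * (L_bp_bce + L_cc_bce + L_mf_bce)
#           + beta  * (L_bp_mse + L_cc_mse + L_mf_mse)
#           + omega * L_sl

#' Multi-label binary cross-entropy
#'
#' Mean over all N x M entries of `-p log phat - (1-p) log(1-phat)` with
#' predictions clamped to `[eps, 1-eps]`.
#'
#' @param pred N x M matrix of probabilities.
#' @param truth N x M binary matrix.
#' @param eps Clamping constant.
#' @return Nonnegative scalar.
#' @export
bce_multilabel <- function(pred, truth, eps = 1e-7) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("prediction and label shapes differ", call. = FALSE)
  }
  if (!all(truth %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  p <- pmin(pmax(pred, eps), 1 - eps)
  mean(-truth * log(p) - (1 - truth) * log(1 - p))
}

#' Assemble the collaborative multi-task loss
#'
#' @param components Named list with elements `bp_bce`, `cc_bce`, `mf_bce`,
#'   `bp_mse`, `cc_mse`, `mf_mse`, `sl`.
#' @param alpha,beta,omega Nonnegative task weights (function BCE group,
#'   reconstruction MSE group, localization).
#' @return Object of class `loss_bundle`: the components plus `total` and
#'   the weights.
#' @export
total_loss <- function(components, alpha = 1, beta = 1, omega = 1) {
  if (alpha < 0 || beta < 0 || omega < 0) {
    stop("loss weights must be nonnegative", call. = FALSE)
  }
  need <- c("bp_bce", "cc_bce", "mf_bce", "bp_mse", "cc_mse", "mf_mse", "sl")
  missing <- setdiff(need, names(components))
  if (length(missing)) stop("missing loss components: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  comp <- lapply(components[need], as.numeric)
  total <- alpha * (comp$bp_bce + comp$cc_bce + comp$mf_bce) +
    beta * (comp$bp_mse + comp$cc_mse + comp$mf_mse) +
    omega * comp$sl
  structure(c(comp, list(total = total, alpha = alpha, beta = beta,
                         omega = omega)),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf(
    "loss_bundle: total = %.6f (fun bce %.4f | recon mse %.4f | sl %.4f)\n",
    x$total, x$bp_bce + x$cc_bce + x$mf_bce,
    x$bp_mse + x$cc_mse + x$mf_mse, x$sl))
  invisible(x)
}

#' Write per-epoch loss components as TSV
#' @param logs data.frame of per-epoch values (one row per epoch).
#' @param path Output path.
#' @export
write_loss_log <- function(logs, path) {
  utils::write.table(logs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
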