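test_that("perfect predictions score perfectly on every metric", {
  set.seed(1)
  labels <- matrix(rbinom(40, 1, 0.4), 10)
  labels[1, ] <- c(1, 0, 1, 0)  # guarantee both classes per column
  labels[2, ] <- c(0, 1, 0, 1)
  rep <- suppressWarnings(evaluate_multilabel(labels, labels))
  expect_equal(rep$ap, 1)
  expect_equal(rep$auroc, 1)
  expect_equal(rep$aupr, 1)
  expect_equal(rep$acc, 1)
  expect_equal(rep$fmax, 1)
  expect_equal(rep$hloss, 0)
  expect_equal(rep$rl, 0)
  expect_equal(rep$oerror, 0)
})

test_that("ranking loss and one-error agree with pair enumeration", {
  # one example: the positive is outranked by both negatives
  s <- matrix(c(0.9, 0.1, 0.3), 1)
  y <- matrix(c(0, 1, 0), 1)
  rep <- suppressWarnings(evaluate_multilabel(s, y))
  expect_equal(rep$oerror, 1.0)
  expect_equal(rep$rl, 1.0)
})

test_that("hamming loss matches the printed 2x2 fixture", {
  s <- rbind(c(0.9, 0.2), c(0.4, 0.7))
  y <- rbind(c(1, 1), c(0, 1))
  rep <- suppressWarnings(evaluate_multilabel(s, y))
  expect_equal(rep$hloss, 0.25)  # predictions [[1,0],[0,1]]: one mismatch of 4
})

test_that("evaluate matches brute-force implementations on random instances", {
  set.seed(42)
  for (trial in 1:25) {
    N <- sample(3:12, 1)
    C <- sample(2:6, 1)
    scores <- matrix(round(runif(N * C), 2), N)  # rounding forces ties
    labels <- matrix(rbinom(N * C, 1, 0.45), N)
    if (sum(labels) == 0 || sum(labels) == N * C) next
    got <- suppressWarnings(evaluate_multilabel(scores, labels))
    ref <- brute_metrics(scores, labels)
    expect_equal(got$ap, ref$ap, tolerance = 1e-12)
    expect_equal(got$auroc, ref$auroc, tolerance = 1e-12)
    expect_equal(got$hloss, ref$hloss, tolerance = 1e-12)
    expect_equal(got$rl, ref$rl, tolerance = 1e-12)
    expect_equal(got$oerror, ref$oerror, tolerance = 1e-12)
  }
})

test_that("auroc agrees with pROC on a random instance", {
  set.seed(5)
  s <- runif(60)
  y <- rbinom(60, 1, 0.3)
  got <- suppressWarnings(evaluate_multilabel(cbind(s), cbind(y)))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(got$auroc, ref, tolerance = 1e-10)
})

test_that("ranking metrics are invariant to monotone score transforms", {
  set.seed(3)
  scores <- matrix(runif(30), 6)
  labels <- matrix(rbinom(30, 1, 0.5), 6)
  labels[1, ] <- c(1, 1, 0, 0, 1)
  labels[2, ] <- c(0, 0, 1, 1, 0)
  a <- suppressWarnings(evaluate_multilabel(scores, labels))
  b <- suppressWarnings(evaluate_multilabel(scores^3, labels))
  for (f in c("ap", "auroc", "aupr", "rl", "oerror")) {
    expect_equal(a[[f]], b[[f]], label = f)
  }
  # threshold-based metrics are the documented exception
  expect_false(isTRUE(all.equal(a$hloss, b$hloss)) &&
                 isTRUE(all.equal(a$acc, b$acc)))
})

test_that("fmax dominates the F1 at every single threshold and stays in range", {
  set.seed(9)
  scores <- matrix(runif(50), 10)
  labels <- matrix(rbinom(50, 1, 0.4), 10)
  labels[1, 1] <- 1; labels[2, 1] <- 0
  rep <- suppressWarnings(evaluate_multilabel(scores, labels))
  expect_lte(rep$fmax, 1)
  f_at <- function(tau) {
    p <- scores >= tau
    npred <- rowSums(p); tp <- rowSums(p & labels == 1)
    prec <- mean((tp / npred)[npred > 0])
    rec <- mean((tp / rowSums(labels))[rowSums(labels) > 0])
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  for (tau in c(0.2, 0.5, 0.8)) expect_gte(rep$fmax, f_at(tau) - 1e-12)
  expect_equal(rep$fmax, f_at(rep$fmax_tau))  # attained at the reported tau
})

test_that("single-class labels are skipped with a warning", {
  scores <- matrix(runif(20), 5)
  labels <- cbind(rbinom(5, 1, 0.5), 1, rbinom(5, 1, 0.5), 0)
  labels[1, 1] <- 1; labels[2, 1] <- 0; labels[1, 3] <- 1; labels[2, 3] <- 0
  expect_warning(rep <- evaluate_multilabel(scores, labels), "skipped")
  expect_equal(rep$n_labels_skipped, 2L)
})

test_that("pr_curves produce sensible endpoints", {
  s <- cbind(c(0.9, 0.8, 0.3, 0.1))
  y <- cbind(c(1, 1, 0, 0))
  tab <- pr_curves(s, y)
  expect_equal(tab$precision[tab$recall == 1][1], 1)  # perfect separation
  # single positive at top rank: first point has precision 1
  tab2 <- pr_curves(cbind(c(0.9, 0.2, 0.1)), cbind(c(1, 0, 0)))
  expect_equal(tab2$precision[1], 1)
  expect_warning(pr_curves(cbind(c(0.5, 0.1)), cbind(c(0, 0))), "no positives")
})

test_that("random scores give AUPR near class prevalence", {
  set.seed(77)
  N <- 4000L
  prev <- 0.2
  s <- cbind(runif(N))
  y <- cbind(rbinom(N, 1, prev))
  rep <- suppressWarnings(evaluate_multilabel(s, y))
  expect_lt(abs(rep$aupr - mean(y)), 0.04)
  expect_lt(abs(rep$auroc - 0.5), 0.04)
})
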