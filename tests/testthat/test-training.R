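test_that("forward produces score vectors matching the vocabularies", {
  cfg <- tiny_model_config()
  ds <- tiny_dataset(n_proteins = 2L)
  model <- init_model(cfg)
  fp <- forward_protein(model, ds$graphs[[1]], labels = single_labels(ds, 1))
  expect_length(fp$scores$bp, cfg$M_bp)
  expect_length(fp$scores$cc, cfg$M_cc)
  expect_length(fp$scores$mf, cfg$M_mf)
  expect_length(fp$scores$sl, cfg$C)
  expect_true(all(unlist(fp$scores) > 0 & unlist(fp$scores) < 1))
  expect_length(fp$importance, nrow(ds$graphs[[1]]$node_feats))
  expect_true(all(fp$importance >= 0 & fp$importance <= 1))
  expect_s3_class(fp$loss, "loss_bundle")
  expect_equal(fp$loss$total,
               fp$loss$alpha * (fp$loss$bp_bce + fp$loss$cc_bce + fp$loss$mf_bce) +
                 fp$loss$beta * (fp$loss$bp_mse + fp$loss$cc_mse + fp$loss$mf_mse) +
                 fp$loss$omega * fp$loss$sl)
})

test_that("the full forward equals the manual composition of module calls", {
  cfg <- tiny_model_config()
  ds <- tiny_dataset(n_proteins = 1L)
  g <- ds$graphs[[1]]
  model <- init_model(cfg)
  p <- model$params
  fp <- forward_protein(model, g)

  enc <- gt_encode(g, p$gt, h_d = cfg$h_d)
  scores <- list()
  Hfun <- list()
  for (t in c("bp", "cc", "mf")) {
    Hmid <- branch_project(enc$H, p$branch[[t]])
    Hfun[[t]] <- gae_encode(Hmid, g$edge_index, p$branch[[t]]$Wf,
                            cfg$leaky_slope)
    scores[[t]] <- function_scores(Hfun[[t]], g$edge_index, p$branch[[t]],
                                   cfg$ratio)
  }
  nl <- lapply(c("bp", "cc", "mf"), function(t) {
    nlinear(Hfun[[t]], p$funA$nlin[[t]])
  })
  groups <- cross_attend(nl[[1]], nl[[3]], nl[[2]], p$funA, cfg$h_ki)
  HSL <- fuse_functional(groups, p$funA)
  scores$sl <- localization_scores(HSL, g$edge_index, p$sl, cfg$ratio)

  expect_equal(unname(fp$scores$bp), scores$bp, tolerance = 1e-12)
  expect_equal(unname(fp$scores$cc), scores$cc, tolerance = 1e-12)
  expect_equal(unname(fp$scores$mf), scores$mf, tolerance = 1e-12)
  expect_equal(unname(fp$scores$sl), scores$sl, tolerance = 1e-12)
})

test_that("no_colT changes only the loss weighting, not predictions", {
  ds <- tiny_dataset(n_proteins = 2L)
  m_full <- init_model(tiny_model_config())
  m_ablt <- init_model(tiny_model_config(no_colT = TRUE))
  f1 <- forward_protein(m_full, ds$graphs[[1]], labels = single_labels(ds, 1))
  f2 <- forward_protein(m_ablt, ds$graphs[[1]], labels = single_labels(ds, 1))
  expect_identical(f1$scores, f2$scores)
  expect_equal(f2$loss$total, f2$loss$sl)  # alpha = beta = 0
  expect_gt(f1$loss$total, f2$loss$total)
})

test_that("ablation flags silence exactly the documented parameter groups", {
  ds <- tiny_dataset(n_proteins = 3L)
  batch <- gtloc:::merge_graphs(ds$graphs)
  grads_for <- function(cfg) {
    model <- init_model(cfg)
    tape <- gtloc:::ag_tape(train = FALSE)
    pw <- gtloc:::ag_wrap_params(tape, model$params)
    fw <- gtloc:::.forward_nodes(tape, pw, model$bn, batch, cfg)
    ln <- gtloc:::.loss_nodes(tape, fw, ds$labels, cfg)
    gtloc:::ag_backward(tape, ln$total)
    gtloc:::flatten_params(gtloc:::ag_collect_grads(pw))
  }
  gsum <- function(g, prefix) {
    sum(vapply(g[startsWith(names(g), prefix)], function(m) sum(abs(m)), 1))
  }
  g_full <- grads_for(tiny_model_config())
  expect_gt(gsum(g_full, "gt.layers"), 0)
  expect_gt(gsum(g_full, "funA.groups"), 0)
  expect_gt(gsum(g_full, "branch.bp.Wf"), 0)

  expect_equal(gsum(grads_for(tiny_model_config(no_gt = TRUE)), "gt.layers"), 0)
  expect_equal(gsum(grads_for(tiny_model_config(no_funA = TRUE)),
                    "funA.groups"), 0)
  g_feae <- grads_for(tiny_model_config(no_feaE = TRUE))
  expect_equal(gsum(g_feae, "branch.bp.Wf"), 0)
  g_colt <- grads_for(tiny_model_config(no_colT = TRUE))
  expect_equal(gsum(g_colt, "branch.bp.head"), 0)
  expect_gt(gsum(g_colt, "gt.layers"), 0)  # SL path still reaches the GT
})

test_that("training descends, is seed-deterministic, and lr = 0 is a no-op", {
  ds <- tiny_dataset(n_proteins = 8L)
  cfg <- tiny_model_config(seed = 7L)
  m1 <- train_model(init_model(cfg), ds, epochs = 3)
  expect_lt(m1$logs$total[3], m1$logs$total[1])

  m2 <- train_model(init_model(cfg), ds, epochs = 3)
  expect_identical(m1$logs, m2$logs)
  expect_identical(m1$params, m2$params)

  cfg0 <- tiny_model_config(seed = 7L, lr = 0)
  m0 <- init_model(cfg0)
  before <- m0$params
  m0t <- train_model(m0, ds, epochs = 1)
  expect_identical(m0t$params, before)
})

test_that("prediction is deterministic and batch-composition independent", {
  ds <- tiny_dataset(n_proteins = 6L)
  cfg <- tiny_model_config()
  model <- train_model(init_model(cfg), ds, epochs = 2)
  p1 <- predict_proteins(model, ds$graphs, ids = ds$ids)
  p2 <- predict_proteins(model, ds$graphs, ids = ds$ids)
  expect_identical(p1, p2)
  expect_true(all(unlist(p1$scores) > 0 & unlist(p1$scores) < 1))

  one_at_a_time <- do.call(rbind, lapply(ds$graphs, function(g) {
    predict_proteins(model, list(g), batch_size = 1L)$scores$sl
  }))
  expect_equal(unname(p1$scores$sl), unname(one_at_a_time), tolerance = 1e-5)
})

test_that("validation-based model selection retains the best epoch", {
  ds <- tiny_dataset(n_proteins = 8L)
  valid <- tiny_dataset(n_proteins = 4L, seed = 77L)
  cfg <- tiny_model_config()
  model <- train_model(init_model(cfg), ds, valid_data = valid, epochs = 3)
  expect_true(model$best_epoch %in% 1:3)
  expect_true(all(is.finite(model$logs$valid_sl_ap)))
})

test_that("checkpoints reload bit-exactly", {
  ds <- tiny_dataset(n_proteins = 4L)
  model <- train_model(init_model(tiny_model_config()), ds, epochs = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, model$params)
  expect_identical(predict_proteins(back, ds$graphs),
                   predict_proteins(model, ds$graphs))
})

test_that("prediction bundles round-trip through the TSV writer", {
  ds <- tiny_dataset(n_proteins = 3L)
  model <- init_model(tiny_model_config())
  pred <- predict_proteins(model, ds$graphs, ids = ds$ids)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(prediction_bundle(pred), f)
  back <- read_predictions(f)
  expect_equal(back[[ds$ids[1]]]$sl,
               pred$scores$sl[ds$ids[1], ], tolerance = 1e-6)
})

test_that("train_ablation toggles the requested variant", {
  ds <- tiny_dataset(n_proteins = 4L)
  m <- train_ablation(tiny_model_config(), "no_gt", ds, epochs = 1)
  expect_true(m$config$no_gt)
  expect_error(train_ablation(tiny_model_config(), "bogus", ds), "arg")
})
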