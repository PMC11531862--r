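test_that("backbones have fixed bond length, excluded volume, determinism", {
  sc <- sim_config(seed = 5L)
  co <- generate_backbone(40, sc, seed = 9)
  steps <- sqrt(rowSums(diff(co)^2))
  expect_equal(steps, rep(3.8, 39), tolerance = 1e-9)

  # brute-force excluded-volume check over all non-consecutive pairs
  dm <- as.matrix(dist(co))
  nonconsec <- abs(row(dm) - col(dm)) > 1
  expect_gte(min(dm[nonconsec & upper.tri(dm)]), sc$exclusion_radius)

  expect_identical(co, generate_backbone(40, sc, seed = 9))
  expect_false(identical(co, generate_backbone(40, sc, seed = 10)))
})

test_that("noise-free localization labels equal the boolean rules exactly", {
  sc <- sim_config(n_proteins = 30, len_range = c(20L, 30L), noise_rate = 0,
                   seed = 13L)
  recs <- generate_records(sc)
  onto <- sc$catalogue$ontology
  for (r in recs) {
    go <- stats::setNames(numeric(nrow(sc$catalogue)), sc$catalogue$term)
    go[sc$catalogue$term[onto == "BP"]] <- r$go_bp
    go[sc$catalogue$term[onto == "CC"]] <- r$go_cc
    go[sc$catalogue$term[onto == "MF"]] <- r$go_mf
    expected <- vapply(sc$sl_rules, gtloc:::.eval_rule, numeric(1), go = go)
    expect_equal(unname(r$sl), unname(expected))
  }
  # a protein with no motifs has all-zero GO labels and all-zero SL labels;
  # low prevalence so motif-free proteins actually occur
  sc_sparse <- sim_config(n_proteins = 40, len_range = c(20L, 30L),
                          noise_rate = 0, seed = 19L,
                          catalogue = default_motif_catalogue(prevalence = 0.05))
  sparse <- generate_records(sc_sparse)
  none <- sparse[vapply(sparse, function(r) length(r$motif_windows) == 0L, TRUE)]
  expect_gt(length(none), 0L)
  for (r in none) {
    expect_equal(sum(r$go_bp, r$go_cc, r$go_mf), 0)
    expect_equal(sum(r$sl), 0)
  }
})

test_that("motif windows shift embeddings where GO labels say they do", {
  sc <- sim_config(seed = 3L)
  r <- generate_protein(sc, seed = 101, id = "x")
  expect_equal(length(r$go_bp), 8L)
  expect_equal(length(r$go_cc), 5L)
  expect_equal(length(r$go_mf), 5L)
  terms_on <- names(r$motif_windows)
  onto <- sc$catalogue$ontology
  all_go <- stats::setNames(numeric(nrow(sc$catalogue)), sc$catalogue$term)
  all_go[sc$catalogue$term[onto == "BP"]] <- r$go_bp
  all_go[sc$catalogue$term[onto == "CC"]] <- r$go_cc
  all_go[sc$catalogue$term[onto == "MF"]] <- r$go_mf
  expect_setequal(terms_on, names(all_go)[all_go == 1])
  for (w in r$motif_windows) {
    expect_true(all(diff(w) == 1L))  # contiguous
    expect_equal(length(w), sc$catalogue$k[1])
  }
})

test_that("empirical term prevalence matches the configured rate", {
  sc <- sim_config(n_proteins = 600L, len_range = c(12L, 16L), d_h = 4L,
                   catalogue = default_motif_catalogue(k = 5L,
                                                      prevalence = 0.3),
                   seed = 29L)
  recs <- generate_records(sc)
  bp1 <- vapply(recs, function(r) r$go_bp[1], 1)
  se <- sqrt(0.3 * 0.7 / length(recs))
  expect_lt(abs(mean(bp1) - 0.3), 3 * se)
})

test_that("mean-pooled embeddings are linearly separable iff motifs are planted", {
  probe_auroc <- function(mu, seed) {
    sc <- sim_config(n_proteins = 240L, len_range = c(12L, 18L), d_h = 8L,
                     catalogue = default_motif_catalogue(k = 6L, mu = mu,
                                                        prevalence = 0.4),
                     seed = seed)
    recs <- generate_records(sc)
    X <- t(vapply(recs, function(r) colMeans(r$embedding), numeric(8)))
    y <- vapply(recs, function(r) r$go_bp[1], 1)
    tr <- seq_len(160L)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X[tr, ]), y[tr],
                                           family = stats::binomial()))
    sc_te <- cbind(1, X[-tr, ]) %*% fit$coefficients
    suppressWarnings(
      evaluate_multilabel(cbind(1 / (1 + exp(-sc_te))), cbind(y[-tr]))$auroc)
  }
  expect_gt(probe_auroc(6, seed = 41L), 0.9)
  aur0 <- probe_auroc(0, seed = 43L)
  expect_gt(aur0, 0.35)
  expect_lt(aur0, 0.65)
})

test_that("dataset directories round-trip through the readers", {
  dir <- withr::local_tempdir()
  sc <- sim_config(n_proteins = 6L, len_range = c(10L, 14L), d_h = 5L,
                   catalogue = default_motif_catalogue(k = 5L), seed = 17L)
  recs <- generate_dataset(sc, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_dataset(dir)
  expect_equal(length(back), 6L)
  for (k in seq_along(recs)) {
    expect_equal(back[[k]]$id, recs[[k]]$id)
    expect_equal(back[[k]]$sequence, recs[[k]]$sequence)
    expect_equal(back[[k]]$coords, recs[[k]]$coords, tolerance = 1e-12)
    expect_equal(back[[k]]$embedding, recs[[k]]$embedding, tolerance = 1e-6)
    expect_identical(back[[k]]$go_bp, unname(recs[[k]]$go_bp))
    expect_identical(back[[k]]$go_cc, unname(recs[[k]]$go_cc))
    expect_identical(back[[k]]$go_mf, unname(recs[[k]]$go_mf))
    expect_identical(back[[k]]$sl, unname(recs[[k]]$sl))
  }

  # same seed -> byte-identical label tables
  dir2 <- withr::local_tempdir()
  generate_dataset(sc, dir2)
  for (t in c("bp", "cc", "mf", "sl")) {
    f <- paste0("labels_", t, ".tsv")
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }

  # vocabulary built from generated tables matches direct counts
  tab <- read_labels(file.path(dir, "labels_bp.tsv"))
  if (nrow(tab) > 0) {
    counts <- sapply(split(tab$protein_id, tab$term),
                     function(x) length(unique(x)))
    v <- suppressWarnings(build_vocabulary(tab, "BP", min_frequency = 2))
    expect_equal(v$terms, sort(names(counts)[counts >= 2]))
  }
})

test_that("oversized motifs are skipped with a warning", {
  sc <- sim_config(len_range = c(6L, 6L), d_h = 4L,
                   catalogue = default_motif_catalogue(k = 50L,
                                                      prevalence = 0.95),
                   seed = 3L)
  w <- capture_warnings(r <- generate_protein(sc, seed = 8, id = "tiny"))
  expect_true(any(grepl("skipped", w)))
  expect_equal(sum(r$go_bp, r$go_cc, r$go_mf), 0)
})
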