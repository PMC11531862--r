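test_that("build_contact_map recovers exactly the close residue pairs", {
  two <- matrix(c(0, 3.8, 0, 0, 0, 0), 2)
  expect_equal(build_contact_map(two),
               matrix(c(1L, 2L, 2L, 1L), 2, dimnames = list(NULL, c("i", "j"))))

  # 5 collinear residues 3.8 A apart: only consecutive pairs are contacts
  # (3.8 <= 4.5 < 7.6)
  line <- cbind(3.8 * (0:4), 0, 0)
  ei <- build_contact_map(line)
  expect_equal(nrow(ei), 8L)
  expect_true(all(abs(ei[, 1] - ei[, 2]) == 1L))

  expect_equal(nrow(build_contact_map(matrix(0, 1, 3))), 0L)
  expect_error(build_contact_map(matrix(c(0, NA, 0, 0, 0, 0), 2)),
               "non-finite")
})

test_that("contact map equals brute-force all-pairs filtering", {
  sc <- tiny_sim_config()
  for (trial in 1:20) {
    co <- generate_backbone(sample(5:25, 1), sc, seed = trial)
    ei <- build_contact_map(co, 4.5)
    manual <- NULL
    for (a in seq_len(nrow(co))) {
      for (b in seq_len(nrow(co))) {
        if (a != b && sqrt(sum((co[a, ] - co[b, ])^2)) <= 4.5) {
          manual <- rbind(manual, c(a, b))
        }
      }
    }
    expect_equal(unname(ei), manual)
  }
})

test_that("edge count is monotone in the contact threshold", {
  sc <- tiny_sim_config()
  co <- generate_backbone(30, sc, seed = 99)
  thresholds <- c(4.0, 4.5, 6.0, 8.0, 10.0)
  sets <- lapply(thresholds, function(th) {
    e <- build_contact_map(co, th)
    paste(e[, 1], e[, 2])
  })
  for (k in seq_along(sets)[-1]) {
    expect_true(all(sets[[k - 1]] %in% sets[[k]]))
  }
})

test_that("edge set is invariant under node relabeling", {
  sc <- tiny_sim_config()
  co <- generate_backbone(12, sc, seed = 3)
  ei <- build_contact_map(co)
  perm <- sample(12)
  ei_p <- build_contact_map(co[perm, , drop = FALSE])
  # map permuted edges back to original labels
  back <- cbind(perm[ei_p[, 1]], perm[ei_p[, 2]])
  expect_setequal(paste(back[, 1], back[, 2]), paste(ei[, 1], ei[, 2]))
})

test_that("edge features have the documented layout and values", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  ei <- build_contact_map(co, 4.5)
  fe <- compute_edge_features(co, ei)
  expect_equal(dim(fe), c(2L, 42L))
  expect_equal(fe[, 1], c(3, 3))  # distance component
  # sin/cos block of edge 1->2: displacement (3,0,0), frequency 1
  expect_equal(fe[1, 2:7], c(sin(3), 0, 0, cos(3), 1, 1))
})

test_that("neighbour-distance sums match a brute-force k-NN oracle", {
  set.seed(12)
  co <- matrix(rnorm(18, sd = 3), 6)
  ei <- build_contact_map(co, threshold = 50)
  fe <- compute_edge_features(co, ei)
  dm <- as.matrix(dist(co))
  for (r in seq_len(nrow(ei))) {
    for (col_node in 1:2) {
      node <- ei[r, col_node]
      dsum <- sum(sort(dm[node, -node])[1:5])
      expect_equal(fe[r, 40L + col_node], dsum)
    }
  }
})

test_that("edge features are translation invariant and distances rigid", {
  sc <- tiny_sim_config()
  co <- generate_backbone(10, sc, seed = 5)
  ei <- build_contact_map(co)
  fe <- compute_edge_features(co, ei)
  shifted <- sweep(co, 2, c(10, 10, 10), `+`)
  expect_equal(compute_edge_features(shifted, ei), fe)
  # rigid rotation preserves the distance and neighbour-sum components
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fe_rot <- compute_edge_features(co %*% R, ei)
  expect_equal(fe_rot[, 1], fe[, 1])
  expect_equal(fe_rot[, 41:42], fe[, 41:42])
})

test_that("zero-padding applies when fewer than five neighbours exist", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  fe <- compute_edge_features(co, build_contact_map(co))
  # neighbour displacement block: 2 real neighbours, 3 zero pads
  expect_equal(fe[1, (26 + 6):40], rep(0, 9))
})

test_that("init_node_features strips flanks, truncates, and rejects deficits", {
  # provider emitting (L+2) x d rows with one special row per end
  prov <- synthetic_embedding_provider(dim = 4, seed = 2, n_flank = 1L)
  raw <- prov$fn("ACDE")
  expect_equal(nrow(raw), 6L)
  out <- init_node_features(prov, "ACDE")
  expect_equal(out, raw[2:5, ], ignore_attr = TRUE)

  p0 <- synthetic_embedding_provider(dim = 4, seed = 2)
  expect_identical(init_node_features(p0, "ACDEFG"),
                   init_node_features(p0, "ACDEFG"))

  short <- table_embedding_provider(list(x = matrix(0, 3, 4)), dim = 4)
  expect_error(init_node_features(short, "ACDE", id = "x"), "3 rows")
})

test_that("graph cache round-trips a residue graph", {
  sc <- tiny_sim_config()
  co <- generate_backbone(8, sc, seed = 1)
  g <- residue_graph(matrix(rnorm(48), 8), co)
  f <- withr::local_tempfile(fileext = ".rds")
  save_graph_cache(g, f)
  expect_equal(load_graph_cache(f), g)
})
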