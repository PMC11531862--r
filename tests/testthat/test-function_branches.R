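test_that("branch_project is two stacked affine maps with no activation", {
  p <- list(W1 = diag(4), b1 = matrix(0, 1, 4),
            W2 = diag(4), b2 = matrix(0, 1, 4))
  H <- matrix(rnorm(12), 3, 4)
  expect_equal(branch_project(H, p), H)

  set.seed(2)
  p2 <- list(W1 = matrix(rnorm(12), 4, 3), b1 = matrix(rnorm(3), 1),
             W2 = matrix(rnorm(9), 3, 3), b2 = matrix(rnorm(3), 1))
  z <- branch_project(matrix(0, 2, 4), p2)
  expected0 <- sweep(matrix(rep(as.vector(p2$b1), 2), 2, byrow = TRUE) %*% p2$W2,
                     2, as.vector(p2$b2), `+`)
  expect_equal(z, expected0)

  X <- matrix(rnorm(12), 3, 4)
  manual <- sweep(sweep(X %*% p2$W1, 2, as.vector(p2$b1), `+`) %*% p2$W2,
                  2, as.vector(p2$b2), `+`)
  expect_equal(branch_project(X, p2), manual)
  expect_error(branch_project(matrix(0, 2, 5), p2), "shape")
})

test_that("normalized_adjacency matches hand values on the 3-node path", {
  expect_equal(as.matrix(normalized_adjacency(matrix(integer(0), 0, 2), 1)),
               matrix(1), ignore_attr = TRUE)
  ei <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L))
  Aop <- as.matrix(normalized_adjacency(ei, 3))
  # Abar = [[1,1,0],[1,1,1],[0,1,1]], degrees (2,3,2)
  expect_equal(Aop[1, 1], 0.5)
  expect_equal(Aop[1, 2], 1 / sqrt(6))
  expect_equal(Aop[2, 2], 1 / 3)
  expect_equal(Aop[3, 3], 0.5)
  expect_equal(Aop[1, 3], 0)
  expect_equal(Aop, t(Aop))
})

test_that("gae_encode equals the dense operator oracle on random graphs", {
  # single node, identity weight: plain LeakyReLU
  H1 <- matrix(c(-2, 3), 1)
  expect_equal(gae_encode(H1, matrix(integer(0), 0, 2), diag(2)),
               matrix(c(-0.02, 3), 1))
  for (trial in 1:12) {
    set.seed(trial)
    n <- sample(2:10, 1)
    ei <- rand_edges(n, p = 0.35)
    H <- matrix(rnorm(n * 4), n)
    W <- matrix(rnorm(12), 4, 3)
    expect_equal(gae_encode(H, ei, W), naive_gae_encode(H, ei, W),
                 tolerance = 1e-6)
  }
  # nonnegative inputs and weights: LeakyReLU acts as the identity
  Hp <- matrix(abs(rnorm(8)), 4)
  Wp <- matrix(abs(rnorm(4)), 2)
  ei <- rand_edges(4)
  expect_equal(gae_encode(Hp, ei, Wp),
               as.matrix(normalized_adjacency(ei, 4) %*% Hp %*% Wp),
               ignore_attr = TRUE)
})

test_that("reconstruction loss has its analytic values and loop equivalence", {
  # features engineered for saturated, perfect reconstruction
  ei <- rbind(c(1L, 2L), c(2L, 1L))
  # inner products: (1,2) = +100 (edge), (1,3) = (2,3) = -100 (non-edges),
  # diagonals +100/+200 (self-loops) -> sigmoids saturate at the target
  H <- rbind(c(10, 0), c(10, 0), c(-10, 10))
  expect_lt(gae_reconstruction_loss(H, ei), 1e-9)

  # H = 0: every reconstructed entry is 0.5, loss is 0.25 for any adjacency
  expect_equal(gae_reconstruction_loss(matrix(0, 4, 3), rand_edges(4)), 0.25)

  set.seed(9)
  H5 <- matrix(rnorm(15), 5)
  ei5 <- rand_edges(5)
  expect_equal(gae_reconstruction_loss(H5, ei5), naive_gae_recon(H5, ei5))
})

test_that("reconstruction loss is invariant to matched node permutation", {
  set.seed(4)
  n <- 6L
  H <- matrix(rnorm(n * 3), n)
  ei <- rand_edges(n)
  perm <- sample(n)
  inv <- order(perm)
  ei_p <- cbind(inv[ei[, 1]], inv[ei[, 2]])
  expect_equal(gae_reconstruction_loss(H[perm, , drop = FALSE], ei_p),
               gae_reconstruction_loss(H, ei))
})

test_that("function_scores composes pooling and the MLP head", {
  set.seed(5)
  n <- 6L
  d_fe <- 4L
  p <- with_seed(8, init_branch_params(4, d_fe, n_terms = 7))
  H <- matrix(rnorm(n * d_fe), n)
  ei <- rand_edges(n)
  sc <- function_scores(H, ei, p, ratio = 0.5)
  expect_length(sc, 7L)
  expect_true(all(sc > 0 & sc < 1))

  # hand-composed oracle: sat_pool readout through the two-layer head
  pooled <- sat_pool(H, ei, p$pool$Ws, ratio = 0.5)$vector
  hidden <- pmax(pooled %*% p$head$Wm1 + as.vector(p$head$bm1), 0)
  logits <- hidden %*% p$head$Wm2 + as.vector(p$head$bm2)
  expect_equal(sc, as.vector(1 / (1 + exp(-logits))))

  # all-zero features: scores are sigmoid of the head biases
  sc0 <- function_scores(matrix(0, n, d_fe), ei, p, ratio = 1)
  b <- as.vector(p$head$bm1)
  expect_equal(sc0, as.vector(
    1 / (1 + exp(-(pmax(b, 0) %*% p$head$Wm2 + as.vector(p$head$bm2))))))
})

test_that("the three ontology branches share no parameters", {
  cfg <- tiny_model_config()
  ds <- tiny_dataset(n_proteins = 2L)
  model <- init_model(cfg)
  base <- forward_protein(model, ds$graphs[[1]])
  perturbed <- model
  perturbed$params$branch$bp$W1 <- perturbed$params$branch$bp$W1 + 0.3
  got <- forward_protein(perturbed, ds$graphs[[1]])
  expect_identical(got$scores$cc, base$scores$cc)
  expect_identical(got$scores$mf, base$scores$mf)
  expect_false(identical(got$scores$bp, base$scores$bp))
})
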