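# The alignment itself: zero-shot mapping, MSE, PCA.

make_linear_model <- function(M, activation = "linear",
                              activation_layers = 1L, M2 = NULL) {
  cfg <- grounding_config(d = nrow(M), c = ncol(M), D_img = ncol(M),
                          encoder_kind = "bow", encoder_units = ncol(M),
                          activation = activation,
                          activation_layers = activation_layers)
  params <- list(M = M)
  if (!is.null(M2)) params$M2 <- M2
  structure(list(config = cfg, params = params, pca = NULL,
                 vocabulary = character()), class = "GroundingModel")
}

test_that("grounding a word vector is exactly t . M in the linear variant", {
  set.seed(8)
  model <- make_linear_model(diag(4))
  t1 <- rnorm(4)
  expect_equal(ground_word_vector(model, t1), t1)      # identity M
  M <- matrix(rnorm(12), 3, 4)
  model <- make_linear_model(M)
  expect_equal(ground_word_vector(model, rep(0, 3)), rep(0, 4))
  for (i in 1:20) {
    t_i <- rnorm(3)
    expect_equal(ground_word_vector(model, t_i), drop(t_i %*% M),
                 tolerance = 1e-12)
  }
  expect_error(ground_word_vector(model, rnorm(5)), "dimension")
})

test_that("relu variants map zero to zero (no bias anywhere)", {
  set.seed(9)
  M <- matrix(rnorm(12), 3, 4)
  for (act in c("relu", "leaky_relu")) {
    model <- make_linear_model(M, activation = act)
    expect_equal(ground_word_vector(model, rep(0, 3)), rep(0, 4))
  }
  # 2-layer leaky-relu stack is the documented deep ablation
  model2 <- make_linear_model(M, "leaky_relu", 2L,
                              M2 = matrix(rnorm(16), 4, 4))
  g <- ground_word_vector(model2, rnorm(3))
  expect_length(g, 4L)
  expect_equal(ground_word_vector(model2, rep(0, 3)), rep(0, 4))
})

test_that("zero-shot grounding is linear and covers unseen words", {
  set.seed(10)
  M <- matrix(rnorm(6 * 4), 6, 4)
  model <- make_linear_model(M)
  a <- rnorm(6); b <- rnorm(6); al <- 0.3; be <- -1.7
  expect_equal(ground_word_vector(model, al * a + be * b),
               al * ground_word_vector(model, a) +
                 be * ground_word_vector(model, b),
               tolerance = 1e-12)
  tab <- tiny_table(V = 12, d = 6, seed = 4)
  g1 <- ground_vocabulary(model, tab)
  expect_equal(g1$words, tab$words)
  expect_equal(g1$dim, 4L)
  # every row (trained-on or not) equals the direct multiply oracle
  expect_equal(unname(g1$vectors), unname(tab$vectors %*% M),
               tolerance = 1e-12)
  # identity alignment reproduces the table; doubling M doubles the output
  ident <- make_linear_model(diag(6))
  expect_equal(ground_vocabulary(ident, tab)$vectors, tab$vectors)
  model2 <- make_linear_model(2 * M)
  expect_equal(model2$params$M[1, 1], 2 * M[1, 1])
  expect_equal(ground_vocabulary(model2, tab)$vectors, 2 * g1$vectors)
})

test_that("mse loss matches an elementwise double-loop oracle", {
  set.seed(12)
  A <- matrix(rnorm(15), 3, 5)
  expect_equal(mse_loss(A, A), 0)
  expect_equal(mse_loss(A, A - 1), 1)
  B <- matrix(rnorm(15), 3, 5)
  acc <- 0
  for (i in 1:3) for (j in 1:5) acc <- acc + (A[i, j] - B[i, j])^2
  expect_equal(mse_loss(A, B), acc / 15, tolerance = 1e-10)
  expect_equal(mse_loss(A, B), mse_loss(B, A))
  expect_error(mse_loss(A, matrix(0, 2, 5)), "shape")
})

test_that("pca reduction matches the covariance eigen-decomposition", {
  set.seed(13)
  X <- matrix(rnorm(200 * 10), 200, 10)
  p <- pca_reduce(X, 3)
  expect_true(all(diff(p$sdev) <= 1e-12))       # non-increasing variance
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(p$sdev^2, ev[1:3], tolerance = 1e-8)
  # projection is orthonormal
  expect_equal(unname(crossprod(p$rotation)), diag(3), tolerance = 1e-10)
  # data already in a 3-dim subspace reconstructs exactly
  base <- matrix(rnorm(3 * 10), 3, 10)
  low <- matrix(rnorm(50 * 3), 50, 3) %*% base
  pl <- pca_reduce(low, 3)
  recon <- pl$reduced %*% t(pl$rotation)
  recon <- sweep(recon, 2, -pl$center)
  expect_lt(max(abs(recon - low)), 1e-8)
  expect_error(pca_reduce(low, 5), "rank")
  expect_error(pca_reduce(X[1:2, ], 3), "at least")
})
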