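# Concreteness prediction from embeddings: ordinary least squares and a
# two-hidden-layer perceptron (512/100 units, batch normalization, dropout),
# scored by mean Spearman rho x 100 under tenfold cross-validation.

#' Fit an ordinary-least-squares regressor
#'
#' @param X n x p predictor matrix.
#' @param y numeric response of length n.
#' @return a `linear_regressor` with a `predict()` method.
#' @export
fit_linear_regressor <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 1L || ncol(X) < 1L)
    stop("fit_linear_regressor: degenerate predictor matrix")
  if (length(y) != nrow(X))
    stop("fit_linear_regressor: length(y) != nrow(X)")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  coefs <- fit$coefficients
  if (all(is.na(coefs)))
    stop("fit_linear_regressor: degenerate predictor matrix")
  coefs[is.na(coefs)] <- 0  # rank-deficient pivots
  structure(list(coefficients = coefs), class = "linear_regressor")
}

#' @export
predict.linear_regressor <- function(object, newdata, ...) {
  drop(cbind(1, as.matrix(newdata)) %*% object$coefficients)
}

# -- batch-norm helpers -----------------------------------------------------

.bn_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  v <- colMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Z <- sweep(Xc, 2L, inv, `*`)
  Y <- sweep(sweep(Z, 2L, gamma, `*`), 2L, beta, `+`)
  list(Y = Y, Z = Z, inv = inv, mu = mu, v = v)
}

.bn_backward <- function(cache, gamma, dY) {
  Z <- cache$Z
  dZ <- sweep(dY, 2L, gamma, `*`)
  m1 <- colMeans(dZ)
  m2 <- colMeans(dZ * Z)
  dX <- sweep(sweep(sweep(dZ, 2L, m1) - sweep(Z, 2L, m2, `*`),
                    2L, cache$inv, `*`), 2L, 1, `*`)
  list(dX = dX, dgamma = colSums(dY * Z), dbeta = colSums(dY))
}

.bn_infer <- function(X, gamma, beta, rmu, rvar, eps = 1e-5) {
  Z <- sweep(sweep(X, 2L, rmu), 2L, 1 / sqrt(rvar + eps), `*`)
  sweep(sweep(Z, 2L, gamma, `*`), 2L, beta, `+`)
}

#' Fit a multilayer-perceptron regressor
#'
#' Two hidden layers of 512 and 100 ReLU units, each followed by batch
#' normalization and dropout during training (dropout disabled at
#' prediction, batch norm switched to running statistics), trained with
#' minibatch NAdam on the MSE. Fully deterministic given `seed`.
#'
#' @param X n x p predictor matrix.
#' @param y numeric response of length n.
#' @param seed RNG seed for initialization, shuffling and dropout masks.
#' @param hidden hidden-layer sizes.
#' @param dropout dropout rate during training.
#' @param epochs,batch_size,learning_rate training knobs.
#' @return an `mlp_regressor` with a `predict()` method.
#' @export
fit_mlp_regressor <- function(X, y, seed = 1L, hidden = c(512L, 100L),
                              dropout = 0.2, epochs = 50L,
                              batch_size = 64L, learning_rate = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L || ncol(X) < 1L)
    stop("fit_mlp_regressor: degenerate predictor matrix")
  if (length(y) != n) stop("fit_mlp_regressor: length(y) != nrow(X)")
  set.seed(seed)
  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L
  params <- list()
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- .glorot(sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
    if (l < L) {
      params[[paste0("g", l)]] <- rep(1, sizes[l + 1L])
      params[[paste0("be", l)]] <- numeric(sizes[l + 1L])
    }
  }
  running <- lapply(seq_len(L - 1L), function(l)
    list(mu = numeric(sizes[l + 1L]), var = rep(1, sizes[l + 1L])))
  mom <- 0.9
  opt <- .opt_init(params, "nadam", learning_rate)
  trace <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0; cnt <- 0
    for (start in seq(1L, n, by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, n)]
      if (length(sel) < 2L) next  # batch norm needs >= 2 rows
      A <- X[sel, , drop = FALSE]
      caches <- vector("list", L)
      for (l in seq_len(L - 1L)) {
        Zlin <- sweep(A %*% params[[paste0("W", l)]], 2L,
                      params[[paste0("b", l)]], `+`)
        bn <- .bn_forward(Zlin, params[[paste0("g", l)]],
                          params[[paste0("be", l)]])
        H <- pmax(bn$Y, 0)
        mask <- (matrix(stats::runif(length(H)), nrow(H)) >= dropout) /
          (1 - dropout)
        Hd <- H * mask
        caches[[l]] <- list(A = A, bn = bn, H = H, mask = mask)
        running[[l]]$mu <- mom * running[[l]]$mu + (1 - mom) * bn$mu
        running[[l]]$var <- mom * running[[l]]$var + (1 - mom) * bn$v
        A <- Hd
      }
      pred <- drop(sweep(A %*% params[[paste0("W", L)]], 2L,
                         params[[paste0("b", L)]], `+`))
      caches[[L]] <- list(A = A)
      res <- pred - y[sel]
      tot <- tot + sum(res^2); cnt <- cnt + length(res)
      dpred <- matrix(2 * res / length(res), ncol = 1L)
      grads <- list()
      grads[[paste0("W", L)]] <- crossprod(caches[[L]]$A, dpred)
      grads[[paste0("b", L)]] <- colSums(dpred)
      dA <- dpred %*% t(params[[paste0("W", L)]])
      for (l in rev(seq_len(L - 1L))) {
        cc <- caches[[l]]
        dH <- dA * cc$mask
        dY <- dH * (cc$bn$Y > 0)
        bnb <- .bn_backward(cc$bn, params[[paste0("g", l)]], dY)
        grads[[paste0("g", l)]] <- bnb$dgamma
        grads[[paste0("be", l)]] <- bnb$dbeta
        grads[[paste0("W", l)]] <- crossprod(cc$A, bnb$dX)
        grads[[paste0("b", l)]] <- colSums(bnb$dX)
        dA <- bnb$dX %*% t(params[[paste0("W", l)]])
      }
      st <- .opt_step(opt, params, grads)
      opt <- st$opt; params <- st$params
    }
    trace[epoch] <- tot / max(cnt, 1L)
  }
  structure(list(params = params, running = running, sizes = sizes,
                 dropout = dropout, loss_trace = trace, seed = seed),
            class = "mlp_regressor")
}

#' @export
predict.mlp_regressor <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  L <- length(object$sizes) - 1L
  params <- object$params
  for (l in seq_len(L - 1L)) {
    Zlin <- sweep(A %*% params[[paste0("W", l)]], 2L,
                  params[[paste0("b", l)]], `+`)
    A <- pmax(.bn_infer(Zlin, params[[paste0("g", l)]],
                        params[[paste0("be", l)]],
                        object$running[[l]]$mu, object$running[[l]]$var),
              0)
  }
  drop(sweep(A %*% params[[paste0("W", L)]], 2L,
             params[[paste0("b", L)]], `+`))
}

#' Tenfold cross-validated concreteness prediction
#'
#' Intersects the rated words with the table's vocabulary, shuffles them
#' under `seed` into 10 near-equal folds, trains the chosen regressor on
#' each 9-fold complement to predict STANDARDIZED concreteness scores from
#' word vectors, and reports the per-fold Spearman correlations and their
#' mean (x 100).
#'
#' @param table an `EmbeddingTable`.
#' @param ratings a `ConcretenessRatings` mapping (raw rating-scale units;
#'   standardized internally).
#' @param model_kind `"linear"` or `"mlp"`.
#' @param seed fold-assignment (and MLP training) seed.
#' @param ... passed to [fit_mlp_regressor()].
#' @return a `CVResult`: list with `model_kind`, `fold_rho`,
#'   `mean_rho_x100`, `seed`, `n_words`, `fold_sizes`.
#' @export
crossval_concreteness <- function(table, ratings,
                                  model_kind = c("linear", "mlp"),
                                  seed = 1L, ...) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(table, "EmbeddingTable"))
  words <- intersect(table$words, names(ratings))
  if (length(words) < 10L)
    stop("crossval_concreteness: need >= 10 rated words in the table, got ",
         length(words))
  y_raw <- unname(ratings[words])
  if (stats::sd(y_raw) == 0)
    stop("crossval_concreteness: constant concreteness targets")
  y <- standardize(y_raw)
  X <- table$vectors[match(words, table$words), , drop = FALSE]
  set.seed(seed)
  ord <- sample.int(length(words))
  fold_of <- integer(length(words))
  fold_of[ord] <- rep_len(1:10, length(words))
  fold_rho <- numeric(10)
  for (k in 1:10) {
    te <- fold_of == k
    model <- if (model_kind == "linear")
      fit_linear_regressor(X[!te, , drop = FALSE], y[!te])
    else fit_mlp_regressor(X[!te, , drop = FALSE], y[!te],
                           seed = seed + k, ...)
    pred <- stats::predict(model, X[te, , drop = FALSE])
    fold_rho[k] <- spearman_rho(pred, y[te])
  }
  structure(list(model_kind = model_kind, fold_rho = fold_rho,
                 mean_rho_x100 = 100 * mean(fold_rho), seed = seed,
                 n_words = length(words),
                 fold_sizes = as.integer(table(fold_of))),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult (%s, %d words): mean rho x 100 = %.2f over 10 folds\n",
              x$model_kind, x$n_words, x$mean_rho_x100))
  invisible(x)
}
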