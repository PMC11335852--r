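#' Grounding model configuration
#'
#' Collects every tunable of the grounding model and its training loop. The
#' defaults are the reference training regime: grounded dimension 1024,
#' image dimension 2048, one-layer LSTM bridge with 2048 units, batch size
#' 256, at most 20 epochs with 5-epoch-patience early stopping, NAdam at
#' learning rate 0.001, linear alignment without bias. The transformer
#' bridge defaults to hidden size 1024, 16 attention heads and learning
#' rate 1e-4 when those fields are not supplied explicitly.
#'
#' @param d textual embedding dimension (required).
#' @param c grounded dimension (output of the alignment M).
#' @param D_img image-vector dimension.
#' @param encoder_kind bridge between grounded word vectors and the image
#'   vector: `"word_level"`, `"bow"`, `"gru"`, `"lstm"` or `"transformer"`.
#' @param encoder_layers number of stacked encoder layers (recurrent depth /
#'   transformer-encoder count).
#' @param encoder_units encoder hidden size. For LSTM/GRU a projection head
#'   to `D_img` is added automatically whenever `encoder_units != D_img`.
#' @param n_heads attention heads (transformer only; must divide
#'   `encoder_units`).
#' @param activation activation applied after the alignment multiply:
#'   `"linear"`, `"relu"` or `"leaky_relu"`. With `"linear"` the grounded
#'   vector is exactly `t %*% M`.
#' @param activation_layers stacked activated layers in the alignment
#'   pathway (1 = just M; 2 adds a second c x c activated layer). Must be 1
#'   when `activation = "linear"`.
#' @param batch_size,max_epochs,patience,learning_rate training loop knobs.
#' @param optimizer_kind `"nadam"` (default), `"adam"` or `"sgd"`.
#' @param init_state LSTM/GRU initial state: `"zeros"` (default,
#'   deterministic) or `"learned"` (trainable h0/c0).
#' @param val_fraction validation fraction used when the dataset has no
#'   validation records of its own.
#' @param top_k caption-vocabulary truncation when no vocabulary is passed
#'   to [train_grounding()].
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @return a validated `GroundingConfig` list.
#' @export
grounding_config <- function(d,
                             c = 1024L,
                             D_img = 2048L,
                             encoder_kind = c("lstm", "gru", "bow",
                                              "word_level", "transformer"),
                             encoder_layers = 1L,
                             encoder_units = NULL,
                             n_heads = NULL,
                             activation = c("linear", "relu", "leaky_relu"),
                             activation_layers = 1L,
                             batch_size = 256L,
                             max_epochs = 20L,
                             patience = 5L,
                             learning_rate = NULL,
                             optimizer_kind = c("nadam", "adam", "sgd"),
                             init_state = c("zeros", "learned"),
                             val_fraction = 0.1,
                             top_k = 10000L,
                             seed = 1L) {
  encoder_kind <- match.arg(encoder_kind)
  activation <- match.arg(activation)
  optimizer_kind <- match.arg(optimizer_kind)
  init_state <- match.arg(init_state)
  if (is.null(encoder_units))
    encoder_units <- if (encoder_kind == "transformer") 1024L else D_img
  if (is.null(n_heads)) n_heads <- 16L
  if (is.null(learning_rate))
    learning_rate <- if (encoder_kind == "transformer") 1e-4 else 1e-3
  cfg <- list(d = as.integer(d), c = as.integer(c),
              D_img = as.integer(D_img),
              encoder_kind = encoder_kind,
              encoder_layers = as.integer(encoder_layers),
              encoder_units = as.integer(encoder_units),
              n_heads = as.integer(n_heads),
              activation = activation,
              activation_layers = as.integer(activation_layers),
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              learning_rate = as.numeric(learning_rate),
              optimizer_kind = optimizer_kind,
              init_state = init_state,
              val_fraction = as.numeric(val_fraction),
              top_k = as.integer(top_k),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(d >= 1L, c >= 1L, D_img >= 1L, encoder_units >= 1L,
              encoder_layers >= 1L, activation_layers >= 1L,
              batch_size >= 1L, max_epochs >= 1L, patience >= 1L,
              learning_rate > 0, val_fraction >= 0, val_fraction < 1)
  })
  if (cfg$activation == "linear" && cfg$activation_layers != 1L)
    stop("grounding_config: stacked alignment layers require a nonlinear ",
         "activation")
  if (cfg$encoder_kind == "transformer" &&
      cfg$encoder_units %% cfg$n_heads != 0L)
    stop("grounding_config: encoder_units must be divisible by n_heads")
  if (cfg$encoder_kind == "word_level" && cfg$activation_layers > 1L)
    cfg$activation_layers <- cfg$activation_layers  # allowed; M stack only
  structure(cfg, class = "GroundingConfig")
}

# -- activations (no bias anywhere in the alignment pathway) ----------------

.act <- function(x, kind) {
  switch(kind,
         linear = x,
         relu = pmax(x, 0),
         leaky_relu = ifelse(x > 0, x, 0.01 * x))
}

.dact <- function(x, kind) {  # derivative as a function of pre-activation
  switch(kind,
         linear = array(1, dim = dim(x)),
         relu = (x > 0) * 1,
         leaky_relu = ifelse(x > 0, 1, 0.01))
}

# Alignment-stack forward: X (n x d) -> grounded (n x c), caching
# pre-activations for backprop. Layer 1 is M (d x c); layers 2..L are
# c x c matrices M2, M3, ... each followed by the activation. No biases.
.ground_forward <- function(params, config, X) {
  L <- config$activation_layers
  inputs <- vector("list", L)
  pre <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    W <- params[[if (l == 1L) "M" else paste0("M", l)]]
    inputs[[l]] <- A
    Z <- A %*% W
    pre[[l]] <- Z
    A <- .act(Z, config$activation)
  }
  list(G = A, inputs = inputs, pre = pre)
}

# Backward through the alignment stack: dG (n x c) -> gradient list for the
# M matrices plus dX (unused: the textual table is frozen).
.ground_backward <- function(params, config, cache, dG) {
  L <- config$activation_layers
  grads <- list()
  dA <- dG
  for (l in rev(seq_len(L))) {
    nm <- if (l == 1L) "M" else paste0("M", l)
    dZ <- dA * .dact(cache$pre[[l]], config$activation)
    grads[[nm]] <- crossprod(cache$inputs[[l]], dZ)
    if (l > 1L) dA <- dZ %*% t(params[[nm]])
  }
  grads
}

#' Ground a single textual word vector
#'
#' Applies the learned alignment: with the linear variant this is exactly
#' the matrix product `t %*% M`; the nonlinear ablation variants pass the
#' product through the configured activation stack (no bias terms anywhere,
#' so the zero vector always maps to zero).
#'
#' @param model a trained `GroundingModel`.
#' @param t numeric vector of length `d` (or an n x d matrix).
#' @return grounded vector of length `c` (or n x c matrix).
#' @export
ground_word_vector <- function(model, t) {
  stopifnot(inherits(model, "GroundingModel"))
  one <- is.null(dim(t))
  X <- if (one) matrix(t, nrow = 1L) else as.matrix(t)
  if (ncol(X) != model$config$d)
    stop("ground_word_vector: vector has dimension ", ncol(X),
         ", model expects ", model$config$d)
  G <- .ground_forward(model$params, model$config, X)$G
  if (one) drop(G) else G
}

#' Ground an entire vocabulary zero-shot
#'
#' Applies the alignment row-by-row to every word in the table — words that
#' never occurred in the training captions (including abstract words) are
#' grounded exactly like trained words. The input table is left untouched.
#'
#' @param model a trained `GroundingModel`.
#' @param table an `EmbeddingTable` of dimension `d`.
#' @return an `EmbeddingTable` with the same vocabulary and dimension `c`.
#' @export
ground_vocabulary <- function(model, table) {
  stopifnot(inherits(model, "GroundingModel"),
            inherits(table, "EmbeddingTable"))
  if (table$dim != model$config$d)
    stop("ground_vocabulary: table dimension ", table$dim,
         " != model d ", model$config$d)
  embedding_table(table$words, ground_word_vector(model, table$vectors))
}

#' Mean-squared-error loss
#'
#' Mean over all batch x dimension elements of the squared differences —
#' the training criterion matching encoder output to the image vector.
#'
#' @param pred,target numeric matrices (or vectors) of identical shape.
#' @export
mse_loss <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!identical(dim(pred), dim(target)))
    stop("mse_loss: shape mismatch: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(target), collapse = "x"))
  mean((pred - target)^2)
}

#' Principal-component reduction of image vectors
#'
#' Fits an orthonormal projection onto the top `target_dim` principal axes
#' (centered, unscaled), used by the word-level bridge to match the image
#' dimension to the alignment output dimension. Fit on the training split
#' only; components are ordered by decreasing explained variance.
#'
#' @param vectors n x D matrix of image vectors, n >= target_dim.
#' @param target_dim output dimensionality.
#' @return list with `rotation` (D x target_dim), `center` (length D),
#'   `sdev` (component standard deviations) and `reduced` (n x target_dim
#'   scores).
#' @export
pca_reduce <- function(vectors, target_dim) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < target_dim)
    stop("pca_reduce: need at least target_dim = ", target_dim,
         " vectors, got ", nrow(vectors))
  p <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  if (sum(p$sdev > 1e-12) < target_dim)
    stop("pca_reduce: data rank ", sum(p$sdev > 1e-12),
         " below target_dim ", target_dim)
  list(rotation = p$rotation[, seq_len(target_dim), drop = FALSE],
       center = p$center,
       sdev = p$sdev[seq_len(target_dim)],
       reduced = p$x[, seq_len(target_dim), drop = FALSE])
}

.pca_apply <- function(pca, vectors) {
  sweep(as.matrix(vectors), 2L, pca$center) %*% pca$rotation
}

#' @export
print.GroundingModel <- function(x, ...) {
  cfg <- x$config
  cat("GroundingModel: ", cfg$d, " -> ", cfg$c, " alignment (",
      cfg$activation, ", ", cfg$activation_layers, " layer",
      if (cfg$activation_layers > 1L) "s", "), bridge = ", cfg$encoder_kind,
      if (cfg$encoder_kind %in% c("lstm", "gru", "transformer"))
        paste0(" (", cfg$encoder_layers, " x ", cfg$encoder_units, ")"),
      ", image dim ", cfg$D_img, "\n", sep = "")
  invisible(x)
}
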