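# Training loop: minibatch NAdam on the MSE between encoder output and
# image vectors, with patience-based early stopping on the validation loss.

.caption_indices <- function(tokens_list, vocab) {
  lapply(tokens_list, function(tk) {
    idx <- match(tk, vocab)
    idx[!is.na(idx)]
  })
}

# Preprocess a dataset against a model vocabulary: vocabulary filtering,
# stop-word removal for the word-level bridge, exclusion of captions that
# become empty.
.prepare_split <- function(dataset, vocab, config, split) {
  sel <- which(dataset$split == split)
  toks <- dataset$tokens[sel]
  if (config$encoder_kind == "word_level")
    toks <- lapply(toks, remove_stop_words)
  idx <- .caption_indices(toks, vocab)
  keep <- lengths(idx) > 0L
  list(cap_idx = idx[keep],
       images = dataset$images[sel[keep], , drop = FALSE],
       n_dropped = sum(!keep))
}

#' Train the grounding model
#'
#' Learns the alignment `M` (and the bridge parameters) by regressing image
#' vectors from caption encodings with minibatch NAdam on the MSE loss. The
#' textual embedding table is frozen throughout: only the alignment, the
#' encoder and any projection head are updated. Training halts at
#' `max_epochs`, or earlier when the validation loss has failed to improve
#' for `patience` consecutive epochs, and the best-epoch parameters are
#' restored. The whole run is deterministic given `config$seed`.
#'
#' For `encoder_kind = "word_level"` the sequence encoder is bypassed: stop
#' words are removed from each caption and every remaining token is
#' regressed directly onto its caption's image vector, reduced beforehand by
#' PCA to the alignment output dimension `c` whenever `D_img != c` (the PCA
#' is fit on the training split only).
#'
#' @param dataset a `CaptionImageDataset` (tokens already normalized). If it
#'   has no validation records, a fraction `config$val_fraction` is carved
#'   off deterministically under the seed.
#' @param table the frozen textual `EmbeddingTable` (dimension `config$d`).
#' @param vocabulary a `CaptionVocabulary`, or `NULL` to build the top-`top_k`
#'   caption vocabulary from the training split. Either way the vocabulary is
#'   intersected with the table's words before training, so lookups cannot
#'   fail mid-epoch.
#' @param config a [grounding_config()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (a `GroundingModel`) and `trace` (a
#'   `TrainingTrace` data frame of per-epoch train/validation losses with
#'   `best_epoch` and `stopped_epoch` attributes).
#' @export
train_grounding <- function(dataset, table, vocabulary = NULL, config,
                            verbose = FALSE) {
  stopifnot(inherits(dataset, "CaptionImageDataset"),
            inherits(table, "EmbeddingTable"),
            inherits(config, "GroundingConfig"))
  if (table$dim != config$d)
    stop("train_grounding: table dimension ", table$dim, " != config d ",
         config$d)
  if (ncol(dataset$images) != config$D_img)
    stop("train_grounding: image dimension ", ncol(dataset$images),
         " != config D_img ", config$D_img)
  set.seed(config$seed)

  # carve a validation split if the dataset has none
  if (!any(dataset$split == "validation") && config$val_fraction > 0) {
    n <- length(dataset$tokens)
    n_val <- max(1L, floor(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    dataset$split[val_idx] <- "validation"
  }
  if (!any(dataset$split == "train"))
    stop("train_grounding: empty training split")

  # vocabulary: build from train captions if absent, then intersect with
  # the table so embed lookups are total
  train_tokens <- dataset$tokens[dataset$split == "train"]
  if (is.null(vocabulary))
    vocabulary <- build_vocabulary(train_tokens, top_k = config$top_k)
  vocab <- if (inherits(vocabulary, "CaptionVocabulary")) vocabulary$tokens
           else as.character(vocabulary)
  n_missing <- sum(!(vocab %in% table$words))
  if (n_missing > 0)
    message("train_grounding: dropping ", n_missing,
            " vocabulary tokens absent from the embedding table")
  vocab <- vocab[vocab %in% table$words]
  if (length(vocab) == 0)
    stop("train_grounding: no vocabulary tokens covered by the table")

  tr <- .prepare_split(dataset, vocab, config, "train")
  va <- .prepare_split(dataset, vocab, config, "validation")
  if (length(tr$cap_idx) == 0)
    stop("train_grounding: no nonempty training captions after filtering")
  E <- table$vectors[match(vocab, table$words), , drop = FALSE]

  word_level <- config$encoder_kind == "word_level"
  pca <- NULL
  if (word_level) {
    if (config$D_img != config$c) {
      pca <- pca_reduce(tr$images, config$c)
      Ytr_rec <- pca$reduced
      Yva_rec <- if (nrow(va$images)) .pca_apply(pca, va$images)
                 else matrix(0, 0L, config$c)
    } else {
      Ytr_rec <- tr$images
      Yva_rec <- va$images
    }
    # one regression row per surviving token
    expand <- function(cap_idx, Y) {
      rows <- unlist(cap_idx, use.names = FALSE)
      rep_idx <- rep(seq_along(cap_idx), lengths(cap_idx))
      list(X = E[rows, , drop = FALSE], Y = Y[rep_idx, , drop = FALSE])
    }
    tr_xy <- expand(tr$cap_idx, Ytr_rec)
    va_xy <- expand(va$cap_idx, Yva_rec)
    n_train <- nrow(tr_xy$X)
  } else {
    n_train <- length(tr$cap_idx)
  }

  params <- .init_params(config)
  opt <- .opt_init(params, config$optimizer_kind, config$learning_rate)
  out_dim <- if (word_level) config$c else config$D_img

  val_loss_fn <- function(params) {
    if (word_level) {
      if (nrow(va_xy$X) == 0) return(NA_real_)
      pred <- .ground_forward(params, config, va_xy$X)$G
      return(mean((pred - va_xy$Y)^2))
    }
    if (length(va$cap_idx) == 0) return(NA_real_)
    Gv <- .ground_forward(params, config, E)$G
    tot <- 0; nel <- 0
    for (start in seq(1L, length(va$cap_idx), by = 512L)) {
      sel <- start:min(start + 511L, length(va$cap_idx))
      fw <- .encoder_forward(params, config, va$cap_idx[sel], Gv)
      tot <- tot + sum((fw$pred - va$images[sel, , drop = FALSE])^2)
      nel <- nel + length(sel) * config$D_img
    }
    tot / nel
  }

  epochs <- integer(0); tr_losses <- numeric(0); va_losses <- numeric(0)
  best_val <- Inf; best_epoch <- 0L; best_params <- params
  since_best <- 0L; stopped_epoch <- config$max_epochs
  has_val <- if (word_level) nrow(va_xy$X) > 0 else length(va$cap_idx) > 0

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_train)
    tot <- 0; nel <- 0
    for (start in seq(1L, n_train, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, n_train)]
      if (word_level) {
        Xb <- tr_xy$X[sel, , drop = FALSE]
        Yb <- tr_xy$Y[sel, , drop = FALSE]
        gr <- .ground_forward(params, config, Xb)
        pred <- gr$G
        dpred <- 2 * (pred - Yb) / length(Yb)
        grads <- .ground_backward(params, config, gr, dpred)
      } else {
        gr <- .ground_forward(params, config, E)
        fw <- .encoder_forward(params, config, tr$cap_idx[sel], gr$G)
        pred <- fw$pred
        Yb <- tr$images[sel, , drop = FALSE]
        dpred <- 2 * (pred - Yb) / length(Yb)
        bk <- .encoder_backward(params, config, fw$cache, dpred,
                                nrow(E))
        grads <- c(bk$grads, .ground_backward(params, config, gr, bk$dGv))
      }
      tot <- tot + sum((pred - Yb)^2); nel <- nel + length(Yb)
      st <- .opt_step(opt, params, grads)
      opt <- st$opt; params <- st$params
    }
    train_loss <- tot / nel
    val_loss <- val_loss_fn(params)
    epochs <- c(epochs, epoch)
    tr_losses <- c(tr_losses, train_loss)
    va_losses <- c(va_losses, val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.6g  val %.6g", epoch,
                      train_loss, val_loss))
    monitor <- if (has_val) val_loss else train_loss
    if (monitor < best_val) {
      best_val <- monitor; best_epoch <- epoch
      best_params <- params; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) {
        stopped_epoch <- epoch
        break
      }
    }
    stopped_epoch <- epoch
  }

  trace <- data.frame(epoch = epochs, train_loss = tr_losses,
                      val_loss = va_losses)
  attr(trace, "best_epoch") <- best_epoch
  attr(trace, "stopped_epoch") <- stopped_epoch
  class(trace) <- c("TrainingTrace", "data.frame")

  model <- structure(list(config = config, params = best_params, pca = pca,
                          vocabulary = vocab),
                     class = "GroundingModel")
  list(model = model, trace = trace)
}

#' @export
print.TrainingTrace <- function(x, ...) {
  cat("TrainingTrace: ", nrow(x), " epochs (best ",
      attr(x, "best_epoch"), ", stopped ", attr(x, "stopped_epoch"),
      ")\n", sep = "")
  print.data.frame(utils::tail(x, 5L))
  invisible(x)
}

#' Dataset loss of a trained model
#'
#' Recomputes the MSE of a `GroundingModel` on one split of a dataset,
#' using exactly the training-time preprocessing (vocabulary filtering,
#' stop-word removal and PCA reduction for the word-level bridge).
#'
#' @param model a trained `GroundingModel`.
#' @param dataset a `CaptionImageDataset`.
#' @param table the textual `EmbeddingTable` used in training.
#' @param split `"validation"` (default) or `"train"`.
#' @export
grounding_loss <- function(model, dataset, table, split = "validation") {
  stopifnot(inherits(model, "GroundingModel"))
  config <- model$config
  vocab <- model$vocabulary
  sp <- .prepare_split(dataset, vocab, config, split)
  if (length(sp$cap_idx) == 0)
    stop("grounding_loss: no usable captions in split '", split, "'")
  E <- table$vectors[match(vocab, table$words), , drop = FALSE]
  if (config$encoder_kind == "word_level") {
    Y <- if (!is.null(model$pca)) .pca_apply(model$pca, sp$images)
         else sp$images
    rows <- unlist(sp$cap_idx, use.names = FALSE)
    rep_idx <- rep(seq_along(sp$cap_idx), lengths(sp$cap_idx))
    pred <- .ground_forward(model$params, config,
                            E[rows, , drop = FALSE])$G
    return(mean((pred - Y[rep_idx, , drop = FALSE])^2))
  }
  Gv <- .ground_forward(model$params, config, E)$G
  tot <- 0; nel <- 0
  for (start in seq(1L, length(sp$cap_idx), by = 512L)) {
    sel <- start:min(start + 511L, length(sp$cap_idx))
    fw <- .encoder_forward(model$params, config, sp$cap_idx[sel], Gv)
    tot <- tot + sum((fw$pred - sp$images[sel, , drop = FALSE])^2)
    nel <- nel + length(sel) * config$D_img
  }
  tot / nel
}
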