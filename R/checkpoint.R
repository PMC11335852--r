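# Model checkpoints: a JSON container holding the config, all parameter
# arrays, the PCA projection (word-level bridge) and the training
# vocabulary with an md5 fingerprint. Plain text, portable, diffable.

.mat_to_json <- function(x) {
  if (is.null(dim(x))) list(dim = length(x), values = as.numeric(x))
  else list(dim = dim(x), values = as.numeric(x))
}

.mat_from_json <- function(j) {
  d <- as.integer(unlist(j$dim))
  v <- as.numeric(unlist(j$values))
  if (length(d) == 1L) v else array(v, dim = d)
}

.vocab_md5 <- function(vocab) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(vocab, tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

#' Save a grounding-model checkpoint
#'
#' @param model a `GroundingModel`.
#' @param path output JSON file.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "GroundingModel"))
  obj <- list(
    format = "groundlex-checkpoint-1",
    config = unclass(model$config),
    params = lapply(model$params, .mat_to_json),
    pca = if (!is.null(model$pca))
      list(rotation = .mat_to_json(model$pca$rotation),
           center = as.numeric(model$pca$center),
           sdev = as.numeric(model$pca$sdev)),
    vocabulary = model$vocabulary,
    vocabulary_md5 = .vocab_md5(model$vocabulary))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a grounding-model checkpoint
#'
#' @param path JSON file written by [save_checkpoint()].
#' @return a `GroundingModel`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "groundlex-checkpoint-1"))
    stop("load_checkpoint: not a groundlex checkpoint: ", path)
  cfg <- obj$config
  config <- grounding_config(
    d = cfg$d, c = cfg$c, D_img = cfg$D_img,
    encoder_kind = cfg$encoder_kind, encoder_layers = cfg$encoder_layers,
    encoder_units = cfg$encoder_units, n_heads = cfg$n_heads,
    activation = cfg$activation, activation_layers = cfg$activation_layers,
    batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
    patience = cfg$patience, learning_rate = cfg$learning_rate,
    optimizer_kind = cfg$optimizer_kind, init_state = cfg$init_state,
    val_fraction = cfg$val_fraction, top_k = cfg$top_k, seed = cfg$seed)
  params <- lapply(obj$params, .mat_from_json)
  pca <- if (!is.null(obj$pca))
    list(rotation = .mat_from_json(obj$pca$rotation),
         center = as.numeric(unlist(obj$pca$center)),
         sdev = as.numeric(unlist(obj$pca$sdev)))
  vocab <- as.character(unlist(obj$vocabulary))
  structure(list(config = config, params = params, pca = pca,
                 vocabulary = vocab),
            class = "GroundingModel")
}
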