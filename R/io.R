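#' Construct an embedding table
#'
#' An `EmbeddingTable` holds an ordered vocabulary together with a V x d
#' numeric matrix of word vectors; row i is the vector of word i. It is the
#' carrier for both textual embeddings (the frozen input space) and grounded
#' embeddings (the output of the learned alignment).
#'
#' @param words character vector of unique tokens.
#' @param vectors numeric matrix with one row per word.
#' @return an object of class `EmbeddingTable` with fields `words`,
#'   `vectors` (rownames set to the words) and `dim`.
#' @export
embedding_table <- function(words, vectors) {
  words <- as.character(words)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(words) != nrow(vectors))
    stop("embedding_table: ", length(words), " words but ",
         nrow(vectors), " matrix rows")
  if (anyDuplicated(words))
    stop("embedding_table: duplicate words: ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  if (length(words) > 0 && ncol(vectors) < 1)
    stop("embedding_table: embedding dimension must be >= 1")
  if (length(words) > 0 && !all(is.finite(vectors)))
    stop("embedding_table: non-finite entries in embedding matrix")
  if (length(words) == 0)
    warning("embedding_table: empty vocabulary")
  rownames(vectors) <- words
  structure(list(words = words, vectors = vectors, dim = ncol(vectors)),
            class = "EmbeddingTable")
}

#' @export
print.EmbeddingTable <- function(x, ...) {
  cat("EmbeddingTable: ", length(x$words), " words, dimension ", x$dim, "\n",
      sep = "")
  if (length(x$words) > 0)
    cat("  head: ", paste(utils::head(x$words, 5L), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Look up the vector of a word
#'
#' @param table an `EmbeddingTable`.
#' @param word a single token.
#' @return the word's numeric vector.
#' @export
lookup <- function(table, word) {
  stopifnot(inherits(table, "EmbeddingTable"), length(word) == 1L)
  i <- match(word, table$words)
  if (is.na(i)) stop("lookup: word not in table: '", word, "'")
  table$vectors[i, ]
}

#' Read a word-embedding text file
#'
#' Reads whitespace-delimited embedding files: one word followed by d decimals
#' per line. Both the headerless (GloVe-style) dialect and the dialect whose
#' first line gives the two counts "V d" (word2vec-style) are accepted; the
#' header is auto-detected by testing whether line 1 parses as two integers.
#' Duplicate words keep the first occurrence (with a warning).
#'
#' @param path file to read.
#' @param lowercase lowercase all tokens on load (off by default: pre-trained
#'   vocabularies are frequently case-sensitive).
#' @return an [embedding_table()].
#' @export
read_embeddings <- function(path, lowercase = FALSE) {
  if (!file.exists(path)) stop("read_embeddings: no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("read_embeddings: empty file: ", path)
  first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  skip <- 0L
  if (length(first) == 2L && !anyNA(suppressWarnings(as.integer(first))) &&
      all(grepl("^[0-9]+$", first)))
    skip <- 1L  # word2vec-style "V d" count header
  lines <- lines[seq.int(skip + 1L, length(lines))]
  if (length(lines) == 0) stop("read_embeddings: no data lines in ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  d <- length(parts[[1L]]) - 1L
  if (d < 1L) stop("read_embeddings: line 1 has no vector components")
  words <- character(length(parts))
  mat <- matrix(NA_real_, nrow = length(parts), ncol = d)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != d + 1L)
      stop("read_embeddings: line ", i + skip, " has ", length(p) - 1L,
           " components, expected ", d)
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(v))
      stop("read_embeddings: non-numeric component on line ", i + skip)
    words[i] <- p[1L]
    mat[i, ] <- v
  }
  if (lowercase) words <- tolower(words)
  dup <- duplicated(words)
  if (any(dup)) {
    warning("read_embeddings: ", sum(dup),
            " duplicate words dropped (first occurrence kept)")
    words <- words[!dup]
    mat <- mat[!dup, , drop = FALSE]
  }
  embedding_table(words, mat)
}

#' Write an embedding table as whitespace-delimited text
#'
#' One line per word, file order = table order, values printed with enough
#' significant digits that a read/write round trip reproduces the matrix to
#' better than 1e-6.
#'
#' @param table an `EmbeddingTable`.
#' @param path output file.
#' @param digits significant digits (default 9).
#' @export
write_embeddings <- function(table, path, digits = 9L) {
  stopifnot(inherits(table, "EmbeddingTable"))
  if (length(table$words) == 0) {
    warning("write_embeddings: empty vocabulary, writing empty file")
    cat("", file = path)
    return(invisible(path))
  }
  vals <- matrix(trimws(formatC(table$vectors, digits = digits,
                                format = "g")),
                 nrow = nrow(table$vectors))
  lines <- paste(table$words, apply(vals, 1L, paste, collapse = " "))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an image-vector store from TSV
#'
#' Each line holds an image id followed by the D_img feature components
#' (tab- or space-separated). All vectors must share one dimension. Image
#' features are treated as opaque numeric inputs; they come from an upstream
#' image encoder such as the penultimate layer of a pre-trained CNN.
#'
#' @param path TSV file.
#' @return an `ImageVectorStore`: numeric matrix with image ids as rownames.
#' @export
read_image_vectors <- function(path) {
  if (!file.exists(path)) stop("read_image_vectors: no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("read_image_vectors: empty file: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  dimg <- length(parts[[1L]]) - 1L
  ids <- character(length(parts))
  mat <- matrix(NA_real_, nrow = length(parts), ncol = dimg)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != dimg + 1L)
      stop("read_image_vectors: line ", i, " has dimension ",
           length(p) - 1L, ", expected ", dimg)
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(v) || !all(is.finite(v)))
      stop("read_image_vectors: non-finite component on line ", i)
    ids[i] <- p[1L]
    mat[i, ] <- v
  }
  if (anyDuplicated(ids))
    stop("read_image_vectors: duplicate image ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  rownames(mat) <- ids
  structure(mat, class = c("ImageVectorStore", "matrix", "array"))
}

#' Write an image-vector store as TSV
#' @param store matrix with image-id rownames.
#' @param path output file.
#' @export
write_image_vectors <- function(store, path, digits = 9L) {
  vals <- matrix(trimws(formatC(unclass(store), digits = digits,
                                format = "g")),
                 nrow = nrow(store))
  lines <- paste(rownames(store), apply(vals, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a caption--image dataset
#'
#' The training set: one record per (caption, image) pair. An image captioned
#' k times contributes k records that share one image vector.
#'
#' @param tokens list of character vectors (normalized caption tokens).
#' @param image_ids character vector, one id per record.
#' @param images numeric matrix of image vectors, one row per record.
#' @param split per-record split label, `"train"` or `"validation"`.
#' @return a `CaptionImageDataset`.
#' @export
caption_image_dataset <- function(tokens, image_ids, images,
                                  split = rep("train", length(tokens))) {
  stopifnot(is.list(tokens), length(tokens) == length(image_ids),
            length(tokens) == nrow(images),
            length(split) == length(tokens),
            all(split %in% c("train", "validation")))
  if (length(tokens) > 0 && !all(is.finite(images)))
    stop("caption_image_dataset: non-finite image vectors")
  structure(list(tokens = tokens, image_ids = as.character(image_ids),
                 images = as.matrix(images), split = split),
            class = "CaptionImageDataset")
}

#' @export
print.CaptionImageDataset <- function(x, ...) {
  cat("CaptionImageDataset: ", length(x$tokens), " caption-image records (",
      sum(x$split == "train"), " train / ",
      sum(x$split == "validation"), " validation), image dim ",
      ncol(x$images), "\n", sep = "")
  invisible(x)
}

#' Read a caption--image dataset
#'
#' Captions come as a JSON array of records with keys `image_id` and
#' `caption` (the dialect of COCO's `annotations` entries); image vectors as
#' TSV keyed by image id. Every caption's `image_id` must resolve in the
#' vector store. Captions are normalized with [normalize_caption()] on load.
#'
#' @param captions_path JSON caption file.
#' @param vectors_path TSV image-vector file (or an already-read store).
#' @param val_fraction fraction of records labelled `"validation"` (taken
#'   deterministically from the tail of the file; use 0 to label everything
#'   train and split later).
#' @return a [caption_image_dataset()].
#' @export
read_caption_dataset <- function(captions_path, vectors_path,
                                 val_fraction = 0) {
  if (!file.exists(captions_path))
    stop("read_caption_dataset: no such file: ", captions_path)
  recs <- jsonlite::fromJSON(captions_path, simplifyDataFrame = TRUE)
  store <- if (inherits(vectors_path, "ImageVectorStore")) vectors_path
           else read_image_vectors(vectors_path)
  if (is.null(dim(recs)) || nrow(recs) == 0) {
    warning("read_caption_dataset: no captions")
    return(caption_image_dataset(list(), character(),
                                 matrix(0, 0, ncol(store))))
  }
  if (!all(c("image_id", "caption") %in% names(recs)))
    stop("read_caption_dataset: caption records need image_id and caption keys")
  ids <- as.character(recs$image_id)
  missing <- setdiff(unique(ids), rownames(store))
  if (length(missing) > 0)
    stop("read_caption_dataset: image ids without vectors: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  tokens <- lapply(recs$caption, normalize_caption)
  n <- length(tokens)
  n_val <- floor(val_fraction * n)
  split <- rep("train", n)
  if (n_val > 0) split[seq.int(n - n_val + 1L, n)] <- "validation"
  caption_image_dataset(tokens, ids,
                        unclass(store)[ids, , drop = FALSE], split)
}

#' Write captions as JSON (COCO-annotations dialect)
#' @export
write_captions_json <- function(tokens, image_ids, path) {
  df <- data.frame(image_id = image_ids,
                   caption = vapply(tokens, paste, "", collapse = " "),
                   stringsAsFactors = FALSE)
  jsonlite::write_json(df, path, auto_unbox = FALSE)
  invisible(path)
}

#' Construct a word-pair benchmark
#'
#' A set of (word1, word2, human score) triples such as MEN, WordSim353 or
#' SimLex999, with the observed score bounds recorded for min-max
#' normalization. Extra columns in `pairs` (part of speech, concreteness
#' quartile, ...) travel along untouched.
#'
#' @param pairs data.frame with at least columns `word1`, `word2`, `score`.
#' @param name benchmark label.
#' @param normalized whether `score` is already the min-max normalized
#'   score in \[0, 1\].
#' @return a `WordPairBenchmark`.
#' @export
word_pair_benchmark <- function(pairs, name = "benchmark",
                                normalized = FALSE) {
  stopifnot(is.data.frame(pairs),
            all(c("word1", "word2", "score") %in% names(pairs)))
  pairs$word1 <- as.character(pairs$word1)
  pairs$word2 <- as.character(pairs$word2)
  pairs$score <- as.numeric(pairs$score)
  if (nrow(pairs) > 0 && anyNA(pairs$score))
    stop("word_pair_benchmark: non-numeric scores")
  structure(list(name = name, pairs = pairs,
                 score_min = if (nrow(pairs)) min(pairs$score) else NA_real_,
                 score_max = if (nrow(pairs)) max(pairs$score) else NA_real_,
                 normalized = isTRUE(normalized)),
            class = "WordPairBenchmark")
}

#' @export
print.WordPairBenchmark <- function(x, ...) {
  cat("WordPairBenchmark '", x$name, "': ", nrow(x$pairs), " pairs, scores [",
      format(x$score_min), ", ", format(x$score_max), "]",
      if (x$normalized) " (normalized)", "\n", sep = "")
  invisible(x)
}

#' Read a word-pair benchmark from TSV
#'
#' Data lines are `word1 TAB word2 TAB score` with optional extra metadata
#' columns after the score. A header row is auto-detected by a non-numeric
#' third field and skipped.
#'
#' @param path TSV file.
#' @param name benchmark label (defaults to the file name).
#' @export
read_benchmark <- function(path, name = NULL) {
  if (!file.exists(path)) stop("read_benchmark: no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(word_pair_benchmark(
      data.frame(word1 = character(), word2 = character(),
                 score = numeric()), name))
  parts <- strsplit(lines, "\t")
  first_score <- suppressWarnings(as.numeric(parts[[1L]][3L]))
  if (is.na(first_score)) parts <- parts[-1L]  # header row
  ncols <- length(parts[[1L]])
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3L)
      stop("read_benchmark: line ", i, " has fewer than 3 fields")
    s <- suppressWarnings(as.numeric(p[3L]))
    if (is.na(s)) stop("read_benchmark: non-numeric score on data line ", i)
    p
  })
  df <- data.frame(word1 = vapply(rows, `[`, "", 1L),
                   word2 = vapply(rows, `[`, "", 2L),
                   score = as.numeric(vapply(rows, `[`, "", 3L)),
                   stringsAsFactors = FALSE)
  if (ncols > 3L) {
    extra_names <- paste0("meta", seq_len(ncols - 3L))
    hdr <- strsplit(lines[[1L]], "\t")[[1L]]
    if (is.na(first_score) && length(hdr) == ncols)
      extra_names <- make.names(hdr[-(1:3)], unique = TRUE)
    for (k in seq_len(ncols - 3L))
      df[[extra_names[k]]] <- vapply(rows, function(p)
        if (length(p) >= 3L + k) p[3L + k] else NA_character_, "")
  }
  word_pair_benchmark(df, name)
}

#' Write a benchmark as TSV
#' @export
write_benchmark <- function(benchmark, path) {
  stopifnot(inherits(benchmark, "WordPairBenchmark"))
  utils::write.table(benchmark$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read concreteness ratings from TSV
#'
#' Lines of `word TAB rating` (rating-scale units, e.g. 1-5 for the
#' Brysbaert-style crowd-sourced norms). Duplicate words keep the last value.
#'
#' @param path TSV file.
#' @return a named numeric vector of class `ConcretenessRatings`.
#' @export
read_concreteness <- function(path) {
  if (!file.exists(path)) stop("read_concreteness: no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("read_concreteness: empty file")
    return(structure(stats::setNames(numeric(), character()),
                     class = "ConcretenessRatings"))
  }
  parts <- strsplit(lines, "\t")
  words <- vapply(parts, `[`, "", 1L)
  scores <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(scores))
    stop("read_concreteness: non-numeric score on line ",
         which(is.na(scores))[1L])
  if (anyDuplicated(words)) {
    warning("read_concreteness: duplicate words, last value kept")
    keep <- !duplicated(words, fromLast = TRUE)
    words <- words[keep]; scores <- scores[keep]
  }
  structure(stats::setNames(scores, words), class = "ConcretenessRatings")
}

#' Write concreteness ratings as TSV
#' @export
write_concreteness <- function(ratings, path) {
  writeLines(paste(names(ratings), format(as.numeric(ratings), digits = 9,
                                          trim = TRUE), sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}
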