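#' Normalize a raw caption
#'
#' Lowercases, strips every ASCII punctuation character (removed in place,
#' not replaced by a space, so "co-pilot's" becomes "copilots"), splits on
#' whitespace and drops empty tokens.
#'
#' @param text a character string (or vector; normalized elementwise and
#'   concatenated is NOT done — each element gives one token list).
#' @return character vector of normalized tokens (empty for empty input).
#' @export
normalize_caption <- function(text) {
  if (length(text) != 1L) stop("normalize_caption: expected a single string")
  if (is.na(text) || !nzchar(text)) return(character())
  x <- tolower(text)
  x <- gsub("[][!\"#$%&'()*+,./:;<=>?@\\^_`{|}~-]", "", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

#' Build a frequency-truncated caption vocabulary
#'
#' Counts token frequencies over all captions and keeps the `top_k` most
#' frequent tokens, ties broken lexicographically. Mirrors the usual NLP
#' practice of processing only the most frequent caption words (the
#' reference setup keeps the top 10,000).
#'
#' @param captions list of normalized token vectors.
#' @param top_k maximum vocabulary size.
#' @return a `CaptionVocabulary`: list with `tokens` (descending frequency
#'   order) and `frequencies` (named integer vector, same order).
#' @export
build_vocabulary <- function(captions, top_k = 10000L) {
  stopifnot(top_k >= 1L)
  all_tokens <- unlist(captions, use.names = FALSE)
  if (length(all_tokens) == 0)
    stop("build_vocabulary: no tokens in any caption")
  tab <- table(all_tokens)
  ord <- order(-as.integer(tab), names(tab))
  keep <- utils::head(ord, top_k)
  structure(list(tokens = names(tab)[keep],
                 frequencies = stats::setNames(as.integer(tab)[keep],
                                               names(tab)[keep])),
            class = "CaptionVocabulary")
}

#' @export
print.CaptionVocabulary <- function(x, ...) {
  cat("CaptionVocabulary: ", length(x$tokens), " tokens\n", sep = "")
  invisible(x)
}

#' Drop out-of-vocabulary tokens from a caption
#'
#' Order-preserving; a caption that becomes empty is excluded from training
#' batches downstream (the return value carries an `excluded` attribute).
#'
#' @param tokens normalized token vector.
#' @param vocabulary a `CaptionVocabulary` (or plain character vector).
#' @export
filter_caption <- function(tokens, vocabulary) {
  vocab <- if (inherits(vocabulary, "CaptionVocabulary")) vocabulary$tokens
           else as.character(vocabulary)
  out <- tokens[tokens %in% vocab]
  attr(out, "excluded") <- length(out) == 0L
  out
}

#' Embed a token sequence
#'
#' Maps each token to its row in the embedding table, in order.
#'
#' @param tokens normalized token vector (every token must be in the table).
#' @param table an `EmbeddingTable`.
#' @return an n x d matrix (0-row matrix for an empty caption).
#' @export
embed_caption <- function(tokens, table) {
  stopifnot(inherits(table, "EmbeddingTable"))
  if (length(tokens) == 0)
    return(matrix(0, 0L, table$dim))
  idx <- match(tokens, table$words)
  if (anyNA(idx))
    stop("embed_caption: token not in embedding table: '",
         tokens[which(is.na(idx))[1L]], "'")
  table$vectors[idx, , drop = FALSE]
}

#' Serialize a vocabulary as TSV (token, frequency)
#' @export
write_vocabulary <- function(vocabulary, path) {
  stopifnot(inherits(vocabulary, "CaptionVocabulary"))
  writeLines(paste(vocabulary$tokens,
                   vocabulary$frequencies[vocabulary$tokens], sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

# Snowball-style English stop-word list used by the word-level bridge.
# Fixed and packaged so that stop-word removal is deterministic.
.groundlex_stopwords <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
  "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
  "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
  "being", "have", "has", "had", "having", "do", "does", "did", "doing",
  "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
  "while", "of", "at", "by", "for", "with", "about", "against", "between",
  "into", "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "in", "out", "on", "off", "over", "under", "again",
  "further", "then", "once", "here", "there", "when", "where", "why", "how",
  "all", "any", "both", "each", "few", "more", "most", "other", "some",
  "such", "no", "nor", "not", "only", "own", "same", "so", "than", "too",
  "very", "s", "t", "can", "will", "just", "don", "should", "now")

#' Remove stop words from a normalized token sequence
#'
#' Uses the packaged English stop-word list (Snowball-style); order is
#' preserved. The word-level bridge applies this before regressing each
#' remaining token onto its image vector, so "there is a dog on the floor"
#' reduces to "dog floor".
#'
#' @param tokens normalized token vector.
#' @export
remove_stop_words <- function(tokens) {
  tokens[!(tokens %in% .groundlex_stopwords)]
}

#' The packaged stop-word list
#' @export
stop_word_list <- function() .groundlex_stopwords
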