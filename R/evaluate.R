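# Intrinsic evaluation: cosine/Spearman benchmark scoring, normalization
# and combination, concreteness merging with sigma-binning, SimLex-style
# category breakdowns, nearest neighbours, paired significance tests.

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length, both nonzero.
#' @return a scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("cosine_similarity: dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine_similarity: undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-rank vectors (ties share their mean rank).
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("spearman_rho: need two vectors of equal length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("spearman_rho: undefined for constant input")
  stats::cor(a, b, method = "spearman")
}

#' Score an embedding table on a word-pair benchmark
#'
#' Computes the cosine similarity for every pair whose two words are both in
#' the table, then the Spearman correlation (x 100) between those cosines
#' and the human scores. Pairs with an out-of-vocabulary word are skipped
#' and counted, never zero-filled.
#'
#' @param table an `EmbeddingTable`.
#' @param benchmark a `WordPairBenchmark`.
#' @return an `EvaluationReport`: list with `benchmark`, `rho_x100`,
#'   `n_pairs_scored`, `n_pairs_skipped`.
#' @export
evaluate_benchmark <- function(table, benchmark) {
  stopifnot(inherits(table, "EmbeddingTable"),
            inherits(benchmark, "WordPairBenchmark"))
  pr <- benchmark$pairs
  if (nrow(pr) == 0) stop("evaluate_benchmark: empty benchmark")
  i1 <- match(pr$word1, table$words)
  i2 <- match(pr$word2, table$words)
  ok <- !is.na(i1) & !is.na(i2)
  if (sum(ok) < 2L)
    stop("evaluate_benchmark: fewer than 2 scorable pairs (coverage ",
         sum(ok), "/", nrow(pr), ")")
  V <- table$vectors
  n1 <- sqrt(rowSums(V[i1[ok], , drop = FALSE]^2))
  n2 <- sqrt(rowSums(V[i2[ok], , drop = FALSE]^2))
  if (any(n1 == 0 | n2 == 0))
    stop("evaluate_benchmark: zero vector in table")
  cosines <- rowSums(V[i1[ok], , drop = FALSE] *
                     V[i2[ok], , drop = FALSE]) / (n1 * n2)
  rho <- spearman_rho(cosines, pr$score[ok])
  structure(list(benchmark = benchmark$name,
                 rho_x100 = 100 * rho,
                 n_pairs_scored = sum(ok),
                 n_pairs_skipped = sum(!ok)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("%s: rho x 100 = %.1f  (%d scored, %d skipped)\n",
              x$benchmark, x$rho_x100, x$n_pairs_scored, x$n_pairs_skipped))
  invisible(x)
}

#' Min-max normalize a benchmark's scores to \[0, 1\]
#'
#' `x_in = (x - min) / (max - min)` with the benchmark's observed bounds, so
#' each dataset's scale is removed before combination. Rank order — and
#' hence any Spearman evaluation — is unchanged.
#'
#' @param benchmark a `WordPairBenchmark`.
#' @export
minmax_normalize <- function(benchmark) {
  stopifnot(inherits(benchmark, "WordPairBenchmark"))
  if (benchmark$score_max <= benchmark$score_min)
    stop("minmax_normalize: degenerate score range in '", benchmark$name,
         "'")
  pr <- benchmark$pairs
  pr$score <- (pr$score - benchmark$score_min) /
    (benchmark$score_max - benchmark$score_min)
  word_pair_benchmark(pr, benchmark$name, normalized = TRUE)
}

#' Combine normalized benchmarks into one pair set
#'
#' Concatenates the pair lists of several min-max-normalized benchmarks.
#' Pairs occurring in more than one source are kept as distinct records;
#' each pair carries a `source` provenance tag.
#'
#' @param benchmarks list of normalized `WordPairBenchmark`s.
#' @param name label of the combined set.
#' @export
combine_benchmarks <- function(benchmarks, name = "combined") {
  if (length(benchmarks) == 0)
    stop("combine_benchmarks: empty benchmark list")
  for (b in benchmarks) {
    stopifnot(inherits(b, "WordPairBenchmark"))
    if (!b$normalized)
      stop("combine_benchmarks: benchmark '", b$name,
           "' is not normalized; call minmax_normalize() first")
  }
  dfs <- lapply(benchmarks, function(b) {
    df <- b$pairs[, c("word1", "word2", "score")]
    df$source <- b$name
    df
  })
  word_pair_benchmark(do.call(rbind, dfs), name, normalized = TRUE)
}

#' Merge a combined pair set with concreteness ratings
#'
#' Keeps only pairs whose BOTH words carry a concreteness rating (the
#' intersection with the rating lexicon); the pair's concreteness is the
#' arithmetic mean of its two word ratings. The result is the WCR (word
#' concreteness rating) pair set used for the sigma-bin analysis.
#'
#' @param benchmark a normalized `WordPairBenchmark` (e.g. the output of
#'   [combine_benchmarks()]).
#' @param ratings a `ConcretenessRatings` mapping.
#' @return data.frame with columns `word1`, `word2`, `x_in` (normalized
#'   relatedness), `concreteness` (pair mean) and any provenance column.
#' @export
merge_concreteness <- function(benchmark, ratings) {
  stopifnot(inherits(benchmark, "WordPairBenchmark"))
  if (length(ratings) == 0) stop("merge_concreteness: empty ratings")
  pr <- benchmark$pairs
  c1 <- unname(ratings[pr$word1])
  c2 <- unname(ratings[pr$word2])
  keep <- !is.na(c1) & !is.na(c2)
  if (!any(keep)) {
    warning("merge_concreteness: no pair has both words rated")
  }
  out <- data.frame(word1 = pr$word1[keep], word2 = pr$word2[keep],
                    x_in = pr$score[keep],
                    concreteness = (c1[keep] + c2[keep]) / 2,
                    stringsAsFactors = FALSE)
  if (!is.null(pr$source)) out$source <- pr$source[keep]
  out
}

#' Standardize values to zero mean and unit standard deviation
#'
#' Uses the population standard deviation by default (switchable), so the
#' standardized scores have mean 0 and SD 1 exactly.
#'
#' @param values numeric vector, length >= 2, nonzero spread.
#' @param population divide by the population SD (default) rather than the
#'   sample SD.
#' @export
standardize <- function(values, population = TRUE) {
  if (length(values) < 2L) stop("standardize: need at least 2 values")
  mu <- mean(values)
  s <- if (population) sqrt(mean((values - mu)^2)) else stats::sd(values)
  if (s == 0) stop("standardize: zero spread")
  (values - mu) / s
}

#' Bin WCR pairs into the four sigma segments
#'
#' Partitions standardized pair-concreteness scores at -sigma, the mean and
#' +sigma: `x <= -1` is highly abstract, `-1 < x <= 0` abstract,
#' `0 < x < 1` concrete, `x >= 1` highly concrete (the extreme bins include
#' their boundaries). The bins are disjoint and exhaustive.
#'
#' @param wcr data.frame from [merge_concreteness()]; if it has no `x_is`
#'   column the `concreteness` column is standardized first.
#' @return the input with columns `x_is` and `bin` (ordered factor).
#' @export
bin_by_sigma <- function(wcr) {
  stopifnot(is.data.frame(wcr))
  if (is.null(wcr$x_is)) {
    if (is.null(wcr$concreteness))
      stop("bin_by_sigma: need an x_is or concreteness column")
    wcr$x_is <- standardize(wcr$concreteness)
  }
  x <- wcr$x_is
  bin <- ifelse(x <= -1, "highly_abstract",
         ifelse(x <= 0, "abstract",
         ifelse(x < 1, "concrete", "highly_concrete")))
  wcr$bin <- factor(bin, levels = c("highly_abstract", "abstract",
                                    "concrete", "highly_concrete"),
                    ordered = TRUE)
  wcr
}

#' Evaluate an embedding table on each sigma bin of a WCR set
#'
#' @param table an `EmbeddingTable`.
#' @param wcr binned WCR data.frame (from [bin_by_sigma()]).
#' @return list of `EvaluationReport`s, one per bin (NULL where a bin has
#'   fewer than 2 scorable pairs).
#' @export
evaluate_wcr_bins <- function(table, wcr) {
  stopifnot(!is.null(wcr$bin))
  out <- list()
  for (b in levels(wcr$bin)) {
    sub <- wcr[wcr$bin == b, , drop = FALSE]
    out[[b]] <- if (nrow(sub) >= 2L) {
      bm <- word_pair_benchmark(
        data.frame(word1 = sub$word1, word2 = sub$word2,
                   score = sub$x_in, stringsAsFactors = FALSE),
        name = b, normalized = TRUE)
      tryCatch(evaluate_benchmark(table, bm), error = function(e) NULL)
    } else NULL
  }
  out
}

#' Per-category benchmark breakdown
#'
#' Evaluates each category subset of a benchmark separately — the
#' SimLex-style analysis by part of speech, concreteness quartile and hard
#' subset. A category with fewer than 2 scorable pairs is reported as
#' not-computable (`NULL`), not an error.
#'
#' @param table an `EmbeddingTable`.
#' @param benchmark a `WordPairBenchmark`.
#' @param category_map named list of logical or integer vectors selecting
#'   the pairs of each category; defaults to [simlex_categories()] applied
#'   to the benchmark's metadata columns.
#' @return named list of `EvaluationReport`s (or `NULL` entries).
#' @export
simlex_breakdown <- function(table, benchmark, category_map = NULL) {
  stopifnot(inherits(benchmark, "WordPairBenchmark"))
  if (is.null(category_map)) category_map <- simlex_categories(benchmark)
  out <- list()
  for (nm in names(category_map)) {
    sel <- category_map[[nm]]
    sub <- benchmark$pairs[sel, , drop = FALSE]
    out[[nm]] <- if (nrow(sub) >= 2L)
      tryCatch(evaluate_benchmark(
        table, word_pair_benchmark(sub, paste0(benchmark$name, ":", nm),
                                   normalized = benchmark$normalized)),
        error = function(e) NULL)
    else NULL
  }
  out
}

#' Build a category map from benchmark metadata columns
#'
#' Recognizes a part-of-speech column (`POS`, values A/N/V), a concreteness
#' quartile column (`conc_q`, values 1-4) and a hard-subset flag (`hard`,
#' values 0/1), alongside the always-present `All` category.
#'
#' @param benchmark a `WordPairBenchmark` whose pair table may carry the
#'   metadata columns.
#' @export
simlex_categories <- function(benchmark) {
  pr <- benchmark$pairs
  map <- list(All = rep(TRUE, nrow(pr)))
  if (!is.null(pr$POS)) {
    map$Adjs <- pr$POS %in% c("A", "ADJ")
    map$Nouns <- pr$POS %in% c("N", "NOUN")
    map$Verbs <- pr$POS %in% c("V", "VERB")
  }
  if (!is.null(pr$conc_q))
    for (q in 1:4)
      map[[paste0("Conc-q", q)]] <- pr$conc_q == as.character(q)
  if (!is.null(pr$hard)) map$Hard <- pr$hard %in% c("1", "TRUE", "yes")
  map
}

#' Nearest neighbours of a query word
#'
#' The k words with the highest cosine similarity to the query (query
#' excluded), ties broken lexicographically.
#'
#' @param table an `EmbeddingTable`.
#' @param word query word (must be in the table).
#' @param k number of neighbours, `k < V`.
#' @return data.frame with columns `word` and `cosine`, best first.
#' @export
nearest_neighbors <- function(table, word, k = 10L) {
  stopifnot(inherits(table, "EmbeddingTable"))
  qi <- match(word, table$words)
  if (is.na(qi)) stop("nearest_neighbors: word not in table: '", word, "'")
  if (k >= length(table$words))
    stop("nearest_neighbors: k must be smaller than the vocabulary")
  q <- table$vectors[qi, ]
  V <- table$vectors
  sims <- drop(V %*% q) / (sqrt(rowSums(V^2)) * sqrt(sum(q^2)))
  sims[qi] <- -Inf
  ord <- order(-sims, table$words)
  top <- ord[seq_len(k)]
  data.frame(word = table$words[top], cosine = sims[top],
             stringsAsFactors = FALSE)
}

#' Paired significance test between two embedding models
#'
#' For every pair scorable by BOTH tables, computes each model's per-pair
#' prediction error against the normalized human score (absolute error of
#' the cosine by default, squared error via `operand`), then a two-sided
#' paired t test on the per-pair error differences.
#'
#' @param table_a,table_b two `EmbeddingTable`s.
#' @param benchmark a normalized `WordPairBenchmark` (scores in \[0, 1\]).
#' @param operand `"abs_error"` (default) or `"sq_error"`.
#' @return list with `t`, `p_value`, `df`, `mean_diff` (error A minus
#'   error B; negative favours A) and `n`.
#' @export
paired_model_test <- function(table_a, table_b, benchmark,
                              operand = c("abs_error", "sq_error")) {
  operand <- match.arg(operand)
  stopifnot(inherits(benchmark, "WordPairBenchmark"))
  pr <- benchmark$pairs
  scores <- pr$score
  if (!benchmark$normalized) {
    rng <- benchmark$score_max - benchmark$score_min
    if (rng <= 0) stop("paired_model_test: degenerate score range")
    scores <- (scores - benchmark$score_min) / rng
  }
  pair_cos <- function(tab) {
    i1 <- match(pr$word1, tab$words); i2 <- match(pr$word2, tab$words)
    ok <- !is.na(i1) & !is.na(i2)
    cs <- rep(NA_real_, nrow(pr))
    V <- tab$vectors
    cs[ok] <- rowSums(V[i1[ok], , drop = FALSE] *
                      V[i2[ok], , drop = FALSE]) /
      (sqrt(rowSums(V[i1[ok], , drop = FALSE]^2)) *
       sqrt(rowSums(V[i2[ok], , drop = FALSE]^2)))
    cs
  }
  ca <- pair_cos(table_a); cb <- pair_cos(table_b)
  ok <- !is.na(ca) & !is.na(cb)
  if (sum(ok) < 2L)
    stop("paired_model_test: fewer than 2 pairs scorable by both tables")
  err <- function(cs) switch(operand,
                             abs_error = abs(cs - scores),
                             sq_error = (cs - scores)^2)
  d <- err(ca)[ok] - err(cb)[ok]
  if (stats::sd(d) == 0)
    return(list(t = 0, p_value = 1, df = sum(ok) - 1L,
                mean_diff = mean(d), n = sum(ok)))
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), n = sum(ok))
}
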