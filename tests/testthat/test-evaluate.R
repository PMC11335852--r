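# Evaluation machinery against independent brute-force oracles.

test_that("cosine similarity follows the direct formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 0.70710678,
               tolerance = 1e-8)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero")
  expect_error(cosine_similarity(1:2, 1:3), "mismatch")
})

test_that("spearman rho equals a hand-computed rank correlation", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # brute-force oracle: Pearson on average ranks, random data with ties
  set.seed(41)
  for (i in 1:10) {
    a <- sample(1:6, 12, replace = TRUE)
    b <- a + rnorm(12, sd = 2)
    ra <- rank(a); rb <- rank(b)
    oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(spearman_rho(a, b), oracle, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 4), 1:4), "constant")
  expect_error(spearman_rho(1, 1), "length")
})

test_that("benchmark evaluation scores coverage and skips OOV pairs", {
  set.seed(42)
  tab <- tiny_table(V = 8, d = 5, seed = 42)
  # construction: human scores = exact cosines => rho x 100 = 100
  pairs <- t(combn(tab$words[1:6], 2))
  score <- apply(pairs, 1, function(p)
    cosine_similarity(lookup(tab, p[1]), lookup(tab, p[2])))
  bm <- word_pair_benchmark(data.frame(word1 = pairs[, 1],
                                       word2 = pairs[, 2], score = score))
  rep1 <- evaluate_benchmark(tab, bm)
  expect_equal(rep1$rho_x100, 100)
  expect_equal(rep1$n_pairs_scored + rep1$n_pairs_skipped, nrow(pairs))
  # an OOV word moves its pairs to the skipped count
  bm2 <- word_pair_benchmark(rbind(bm$pairs,
                                   data.frame(word1 = "zzz", word2 = "t01",
                                              score = 0.5)))
  rep2 <- evaluate_benchmark(tab, bm2)
  expect_equal(rep2$n_pairs_skipped, 1L)
  expect_equal(rep2$n_pairs_scored, nrow(pairs))
  # cosine scale invariance: rescaling every vector keeps the report
  tab_scaled <- embedding_table(tab$words, tab$vectors * 7.3)
  expect_equal(evaluate_benchmark(tab_scaled, bm)$rho_x100, rep1$rho_x100)
})

test_that("min-max normalization maps bounds to [0,1] and keeps ranks", {
  bm <- word_pair_benchmark(data.frame(word1 = c("a", "b", "c"),
                                       word2 = c("x", "y", "z"),
                                       score = c(0, 5, 10)))
  nb <- minmax_normalize(bm)
  expect_equal(nb$pairs$score, c(0, 0.5, 1))
  expect_true(nb$normalized)
  # already-[0,1] scores are unchanged
  expect_equal(minmax_normalize(nb)$pairs$score, nb$pairs$score)
  const <- word_pair_benchmark(data.frame(word1 = c("a", "b"),
                                          word2 = c("x", "y"),
                                          score = c(2, 2)))
  expect_error(minmax_normalize(const), "degenerate")
  # rank invariance: any embedding's Spearman score is unchanged
  set.seed(43)
  tab <- tiny_table(V = 10, d = 4, seed = 43)
  pairs <- t(combn(tab$words, 2))[1:20, ]
  bm2 <- word_pair_benchmark(data.frame(word1 = pairs[, 1],
                                        word2 = pairs[, 2],
                                        score = runif(20, 0, 50)))
  expect_equal(evaluate_benchmark(tab, minmax_normalize(bm2))$rho_x100,
               evaluate_benchmark(tab, bm2)$rho_x100, tolerance = 1e-12)
})

test_that("benchmark combination concatenates with provenance", {
  b1 <- minmax_normalize(word_pair_benchmark(
    data.frame(word1 = c("a", "b", "c"), word2 = c("d", "e", "f"),
               score = c(1, 2, 3)), name = "one"))
  b2 <- minmax_normalize(word_pair_benchmark(
    data.frame(word1 = c("a", "g", "h", "i"), word2 = c("d", "j", "k", "l"),
               score = c(0, 3, 6, 9)), name = "two"))
  comb <- combine_benchmarks(list(b1, b2))
  expect_equal(nrow(comb$pairs), 7L)
  expect_equal(as.vector(table(comb$pairs$source)[c("one", "two")]),
               c(3L, 4L))
  # duplicate (a, d) pair across sources is retained twice
  expect_equal(sum(comb$pairs$word1 == "a" & comb$pairs$word2 == "d"), 2L)
  expect_error(combine_benchmarks(list()), "empty")
  raw <- word_pair_benchmark(data.frame(word1 = "a", word2 = "b",
                                        score = 2))
  expect_error(combine_benchmarks(list(b1, raw)), "not normalized")
})

test_that("concreteness merging keeps the rated intersection with means", {
  bm <- minmax_normalize(word_pair_benchmark(
    data.frame(word1 = c("a", "b", "c"), word2 = c("b", "c", "zzz"),
               score = c(1, 2, 3))))
  ratings <- structure(c(a = 2, b = 4, c = 1),
                       class = "ConcretenessRatings")
  wcr <- merge_concreteness(bm, ratings)
  expect_equal(nrow(wcr), 2L)                      # (c, zzz) dropped
  expect_equal(wcr$concreteness, c(3, 2.5))        # pair means
  # counting oracle on random data
  set.seed(44)
  words <- sprintf("w%02d", 1:30)
  prs <- data.frame(word1 = sample(words, 50, TRUE),
                    word2 = sample(words, 50, TRUE),
                    score = runif(50))
  bmr <- word_pair_benchmark(prs, normalized = TRUE)
  rated <- sample(words, 18)
  rr <- structure(stats::setNames(runif(18, 1, 5), rated),
                  class = "ConcretenessRatings")
  expect_equal(nrow(merge_concreteness(bmr, rr)),
               sum(prs$word1 %in% rated & prs$word2 %in% rated))
})

test_that("standardization yields exact zero mean and unit spread", {
  expect_equal(standardize(c(0, 2)), c(-1, 1))
  set.seed(45)
  x <- rnorm(10000, 3, 7)
  s <- standardize(x)
  expect_lt(abs(mean(s)), 1e-10)
  expect_lt(abs(sqrt(mean((s - mean(s))^2)) - 1), 1e-10)
  expect_equal(standardize(s), s, tolerance = 1e-10)   # idempotent
  expect_error(standardize(rep(4, 5)), "zero spread")
  expect_error(standardize(3), "at least 2")
})

test_that("sigma bins are disjoint, exhaustive and boundary-correct", {
  wcr <- data.frame(word1 = letters[1:5], word2 = letters[6:10],
                    x_in = runif(5),
                    x_is = c(-1, -0.5, 0, 0.5, 1))
  binned <- bin_by_sigma(wcr)
  expect_equal(as.character(binned$bin),
               c("highly_abstract",   # x = -1 inclusive (x <= -sigma)
                 "abstract", "abstract", "concrete", "highly_concrete"))
  set.seed(46)
  big <- data.frame(word1 = "a", word2 = "b", x_in = 0.5,
                    x_is = rnorm(5000))
  bb <- bin_by_sigma(big)
  expect_equal(sum(table(bb$bin)), 5000L)           # partition
  expect_false(any(is.na(bb$bin)))
})

test_that("category breakdown equals direct evaluation on each subset", {
  set.seed(47)
  tab <- tiny_table(V = 12, d = 5, seed = 47)
  pairs <- t(combn(tab$words, 2))[1:30, ]
  bm <- word_pair_benchmark(data.frame(
    word1 = pairs[, 1], word2 = pairs[, 2], score = runif(30),
    POS = sample(c("A", "N", "V"), 30, TRUE), stringsAsFactors = FALSE))
  reports <- simlex_breakdown(tab, bm)
  expect_equal(reports$All$rho_x100, evaluate_benchmark(tab, bm)$rho_x100)
  sizes <- 0L
  for (pos in c("Adjs", "Nouns", "Verbs")) {
    sel <- switch(pos, Adjs = "A", Nouns = "N", Verbs = "V")
    sub <- bm$pairs[bm$pairs$POS == sel, ]
    sizes <- sizes + nrow(sub)
    if (nrow(sub) >= 2) {
      oracle <- evaluate_benchmark(tab, word_pair_benchmark(sub))
      expect_equal(reports[[pos]]$rho_x100, oracle$rho_x100)
    }
  }
  expect_equal(sizes, 30L)                          # POS classes partition
  # a one-pair category is reported as not computable, not an error
  bm1 <- bm
  bm1$pairs$POS[1] <- "A"
  bm1$pairs$POS[-1] <- "N"
  r1 <- simlex_breakdown(tab, word_pair_benchmark(bm1$pairs))
  expect_null(r1$Adjs)
})

test_that("nearest neighbours match an exhaustive scan with lexical ties", {
  set.seed(48)
  V <- 200
  tab <- embedding_table(sprintf("w%03d", 1:V), matrix(rnorm(V * 6), V, 6))
  nn <- nearest_neighbors(tab, "w001", k = 10)
  q <- lookup(tab, "w001")
  sims <- vapply(tab$words, function(w)
    cosine_similarity(lookup(tab, w), q), numeric(1))
  sims["w001"] <- -Inf
  oracle <- names(sort(sims, decreasing = TRUE))[1:10]
  expect_equal(nn$word, oracle)
  # duplicate vector of the query ranks first
  tab2 <- embedding_table(c(tab$words, "clone"), rbind(tab$vectors, q))
  expect_equal(nearest_neighbors(tab2, "w001", 1)$word, "clone")
  expect_equal(nrow(nearest_neighbors(tab, "w001", V - 1L)), V - 1L)
  expect_error(nearest_neighbors(tab, "nope", 5), "nope")
  expect_error(nearest_neighbors(tab, "w001", V), "smaller")
})

test_that("paired model test matches the closed-form paired t oracle", {
  set.seed(49)
  tab_a <- tiny_table(V = 15, d = 6, seed = 49)
  tab_b <- embedding_table(tab_a$words,
                           tab_a$vectors + matrix(rnorm(15 * 6, sd = 0.5),
                                                  15, 6))
  pairs <- t(combn(tab_a$words, 2))[1:40, ]
  bm <- minmax_normalize(word_pair_benchmark(
    data.frame(word1 = pairs[, 1], word2 = pairs[, 2],
               score = runif(40))))
  res <- paired_model_test(tab_a, tab_b, bm)
  # textbook oracle: t = mean(d) / (sd(d)/sqrt(n))
  cosv <- function(tab, p) cosine_similarity(lookup(tab, p[1]),
                                             lookup(tab, p[2]))
  ea <- abs(apply(pairs, 1, cosv, tab = tab_a) - bm$pairs$score)
  eb <- abs(apply(pairs, 1, cosv, tab = tab_b) - bm$pairs$score)
  d <- ea - eb
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p_value,
               2 * stats::pt(-abs(t_oracle), length(d) - 1),
               tolerance = 1e-10)
  # identical models: t = 0, p = 1
  same <- paired_model_test(tab_a, tab_a, bm)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # swapping the models negates t
  rev_res <- paired_model_test(tab_b, tab_a, bm)
  expect_equal(rev_res$t, -res$t, tolerance = 1e-10)
})
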