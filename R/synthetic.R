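# Seedable synthetic worlds with planted ground truth: a Gaussian embedding
# table, a full-rank planted alignment M*, a mean-of-grounded-tokens
# composition rule and a planted projection to image space. Every external
# input of the pipeline (embeddings, caption-image pairs, benchmarks,
# concreteness ratings) can be emulated with known recovery targets.

#' Create a synthetic grounding world
#'
#' Draws a V x d textual embedding table with iid standard-normal entries,
#' a planted alignment `M*` (d x c, entries N(0, 1/d), full rank
#' min(d, c)), and a planted projection `P` from grounded to image space.
#' `P` is the identity when `c == D_img` (so single-token image vectors
#' equal `t %*% M*` exactly) and Gaussian `N(0, 1/c)` otherwise. Words are
#' named `w0000`, `w0001`, ... Fully reproducible from `seed`.
#'
#' @param V vocabulary size.
#' @param d textual dimension.
#' @param c grounded dimension.
#' @param D_img image-vector dimension.
#' @param seed RNG seed.
#' @return a `SyntheticWorld`.
#' @export
make_world <- function(V = 300L, d = 16L, c = 8L, D_img = 32L, seed = 1L) {
  stopifnot(V >= 1L, d >= 1L, c >= 1L, D_img >= 1L)
  set.seed(seed)
  words <- sprintf("w%04d", seq_len(V) - 1L)
  tab <- embedding_table(words, matrix(stats::rnorm(V * d), V, d))
  repeat {
    M_star <- matrix(stats::rnorm(d * c, sd = 1 / sqrt(d)), d, c)
    if (qr(M_star)$rank == min(d, c)) break  # measure-zero regeneration
  }
  P <- if (c == D_img) diag(c)
       else matrix(stats::rnorm(c * D_img, sd = 1 / sqrt(c)), c, D_img)
  structure(list(table = tab, M_star = M_star, P = P, V = V, d = d, c = c,
                 D_img = D_img, seed = seed),
            class = "SyntheticWorld")
}

#' @export
print.SyntheticWorld <- function(x, ...) {
  cat("SyntheticWorld: V=", x$V, " d=", x$d, " c=", x$c, " D_img=",
      x$D_img, " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' The planted grounded table of a world
#'
#' `t %*% M*` for every word — the ground-truth grounded embeddings against
#' which recovery is measured.
#' @param world a `SyntheticWorld`.
#' @export
planted_grounded_table <- function(world) {
  stopifnot(inherits(world, "SyntheticWorld"))
  embedding_table(world$table$words, world$table$vectors %*% world$M_star)
}

#' Generate a synthetic caption--image dataset
#'
#' Captions are uniform random token sequences over the world vocabulary
#' with lengths drawn from `len_range`; the image vector of caption S is
#' `mean_i(t_i %*% M*) %*% P + noise`, i.e. the planted composition is the
#' mean of the planted grounded token vectors, projected to image space,
#' plus isotropic Gaussian noise of standard deviation `noise_sd`. Records
#' are split 90/10 train/validation under the seed.
#'
#' @param world a `SyntheticWorld`.
#' @param n_samples number of caption-image records.
#' @param len_range integer range of caption lengths (inclusive).
#' @param noise_sd image-noise standard deviation.
#' @param val_fraction validation share of records.
#' @param seed RNG seed (defaults to `world$seed + 1`).
#' @return a `CaptionImageDataset`.
#' @export
make_caption_dataset <- function(world, n_samples = 2000L,
                                 len_range = c(3L, 8L), noise_sd = 0.05,
                                 val_fraction = 0.1,
                                 seed = world$seed + 1L) {
  stopifnot(inherits(world, "SyntheticWorld"), n_samples >= 1L)
  set.seed(seed)
  lens <- sample(seq.int(len_range[1L], len_range[2L]), n_samples,
                 replace = TRUE)
  tokens <- lapply(lens, function(n)
    world$table$words[sample.int(world$V, n, replace = TRUE)])
  G_star <- world$table$vectors %*% world$M_star
  images <- t(vapply(tokens, function(tk) {
    idx <- match(tk, world$table$words)
    drop(colMeans(G_star[idx, , drop = FALSE]) %*% world$P)
  }, numeric(world$D_img)))
  if (noise_sd > 0)
    images <- images + matrix(stats::rnorm(length(images), sd = noise_sd),
                              nrow(images))
  n_val <- floor(val_fraction * n_samples)
  split <- rep("train", n_samples)
  if (n_val > 0) split[sample.int(n_samples, n_val)] <- "validation"
  ids <- sprintf("img%05d", seq_len(n_samples))
  caption_image_dataset(tokens, ids, images, split)
}

#' Generate a synthetic word-pair benchmark
#'
#' Samples `n_pairs` distinct unordered word pairs; the "human" score of a
#' pair is the cosine of the two words' planted grounded vectors
#' `t %*% M*` plus Gaussian noise. At noise 0 the planted grounded table
#' therefore scores a perfect Spearman correlation by construction, while
#' a generic textual table does not.
#'
#' @param world a `SyntheticWorld` with `V >= 2`.
#' @param n_pairs number of pairs (at most `choose(V, 2)`).
#' @param noise_sd score-noise standard deviation.
#' @param seed RNG seed (defaults to `world$seed + 2`).
#' @return a `WordPairBenchmark`.
#' @export
make_benchmark <- function(world, n_pairs = 500L, noise_sd = 0.05,
                           seed = world$seed + 2L) {
  stopifnot(inherits(world, "SyntheticWorld"), n_pairs >= 2L,
            world$V >= 2L)
  n_all <- choose(world$V, 2)
  if (n_pairs > n_all)
    stop("make_benchmark: n_pairs exceeds the ", n_all, " distinct pairs")
  set.seed(seed)
  # sample unordered pairs without replacement via linear pair codes
  codes <- sample(n_all, n_pairs)
  i <- ceiling((sqrt(8 * codes + 1) - 1) / 2) + 1  # row index of code
  j <- codes - (i - 1) * (i - 2) / 2
  G_star <- world$table$vectors %*% world$M_star
  cosv <- vapply(seq_len(n_pairs), function(k)
    cosine_similarity(G_star[i[k], ], G_star[j[k], ]), numeric(1))
  score <- cosv + if (noise_sd > 0)
    stats::rnorm(n_pairs, sd = noise_sd) else 0
  word_pair_benchmark(
    data.frame(word1 = world$table$words[i],
               word2 = world$table$words[j],
               score = score, stringsAsFactors = FALSE),
    name = sprintf("synthetic-%d", seed))
}

#' Generate synthetic concreteness ratings
#'
#' Each word's rating is a fixed linear functional of its textual vector
#' plus Gaussian noise, shifted to a 1-5-like rating scale. Linear in the
#' embedding by construction, so a linear regressor recovers it perfectly
#' at noise 0.
#'
#' @param world a `SyntheticWorld`.
#' @param noise_sd rating-noise standard deviation (on the unit-signal
#'   scale; the linear signal has unit variance in expectation).
#' @param seed RNG seed (defaults to `world$seed + 3`).
#' @return a `ConcretenessRatings` vector.
#' @export
make_concreteness <- function(world, noise_sd = 0, seed = world$seed + 3L) {
  stopifnot(inherits(world, "SyntheticWorld"))
  set.seed(seed)
  w <- stats::rnorm(world$d, sd = 1 / sqrt(world$d))
  signal <- drop(world$table$vectors %*% w)
  noise <- if (noise_sd > 0)
    stats::rnorm(world$V, sd = noise_sd) else 0
  structure(stats::setNames(3 + signal + noise, world$table$words),
            class = "ConcretenessRatings")
}

#' Write every fixture file of a world in the package's file dialects
#'
#' Emits the textual embeddings (whitespace text), captions (JSON), image
#' vectors (TSV), a benchmark (TSV) and concreteness ratings (TSV) into a
#' directory.
#'
#' @param world a `SyntheticWorld`.
#' @param dir output directory (created if missing).
#' @param n_samples,len_range,noise_sd,n_pairs generator knobs passed on.
#' @return named character vector of the written paths.
#' @export
write_world_fixtures <- function(world, dir, n_samples = 500L,
                                 len_range = c(3L, 8L), noise_sd = 0.05,
                                 n_pairs = 200L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- make_caption_dataset(world, n_samples, len_range, noise_sd)
  bm <- make_benchmark(world, n_pairs, noise_sd)
  cr <- make_concreteness(world, noise_sd)
  paths <- c(embeddings = file.path(dir, "embeddings.txt"),
             captions = file.path(dir, "captions.json"),
             vectors = file.path(dir, "image_vectors.tsv"),
             benchmark = file.path(dir, "benchmark.tsv"),
             concreteness = file.path(dir, "concreteness.tsv"))
  write_embeddings(world$table, paths["embeddings"])
  # one vector per distinct image id
  first <- !duplicated(ds$image_ids)
  store <- ds$images[first, , drop = FALSE]
  rownames(store) <- ds$image_ids[first]
  write_image_vectors(store, paths["vectors"])
  write_captions_json(ds$tokens, ds$image_ids, paths["captions"])
  write_benchmark(bm, paths["benchmark"])
  write_concreteness(cr, paths["concreteness"])
  paths
}
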