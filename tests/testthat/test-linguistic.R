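test_that("tokenizer lowercases, strips punctuation and splits on whitespace", {
  expect_equal(tokenize("Hello, WORLD."), c("hello", "world"))
  expect_equal(tokenize("it's  a   test!"), c("its", "a", "test"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize(c("two", "parts")), c("two", "parts"))
})

test_that("halves split at the session midpoint by turn start time", {
  # session spans [0, 100); midpoint 50: start 49.9 -> half 1, 50.0 -> half 2
  tr <- transcript(data.frame(
    speaker_id = c("A", "B", "A", "B"),
    start = c(0, 49.9, 50.0, 80),
    end = c(10, 50.5, 60, 100),
    text = c("first bit", "late one", "second half", "closing words")))
  halves <- split_halves(tr)
  expect_equal(halves[[1]]$tokens_a, c("first", "bit"))
  expect_equal(halves[[1]]$tokens_b, c("late", "one"))
  expect_equal(halves[[2]]$tokens_a, c("second", "half"))
  expect_equal(halves[[2]]$tokens_b, c("closing", "words"))
})

test_that("split_halves matches hand enumeration and flags empty halves", {
  tr <- transcript(data.frame(
    speaker_id = c("A", "B", "A", "B"),
    start = c(0, 2, 4, 6), end = c(2, 4, 6, 8),
    text = c("a b c", "d e", "f", "g h i j")))
  halves <- split_halves(tr)
  expect_length(halves[[1]]$tokens_a, 3L)
  expect_length(halves[[1]]$tokens_b, 2L)
  expect_length(halves[[2]]$tokens_a, 1L)
  expect_length(halves[[2]]$tokens_b, 4L)
  tr2 <- transcript(data.frame(speaker_id = c("A", "B", "A"),
                               start = c(0, 2, 6), end = c(2, 4, 8),
                               text = c("a", "b", "c")))
  expect_warning(split_halves(tr2), "zero tokens for speaker 'B'")
})

test_that("word usage similarity matches the worked example and its bounds", {
  a <- c("the", "tap", "is", "nice"); b <- c("the", "tap", "drips")
  expect_equal(word_usage_similarity(a, b), 4 / 3.5)
  expect_equal(word_usage_similarity(a, b), 1.1429, tolerance = 1e-4)
  expect_equal(word_usage_similarity(c("x", "y"), c("p", "q")), 0)
  expect_equal(word_usage_similarity(a, a), 2)
  expect_error(word_usage_similarity(character(0), a), "empty")
})

test_that("usage similarity is symmetric, order-invariant and within [0, 2]", {
  expect_equal(word_usage_similarity(c("a", "b"), c("b", "c", "c")),
               word_usage_similarity(c("c", "c", "b"), c("b", "a")))
  set.seed(13)
  vocab <- sprintf("w%02d", 1:30)
  for (rep in 1:200) {
    a <- sample(vocab, sample(1:40, 1), replace = TRUE)
    b <- sample(vocab, sample(1:40, 1), replace = TRUE)
    s <- word_usage_similarity(a, b)
    expect_gte(s, 0); expect_lte(s, 2)
    expect_equal(s, word_usage_similarity(b, a))
    expect_equal(s, word_usage_similarity(sample(a), b))
  }
  # alternative scores stay available but differ
  expect_equal(word_usage_similarity(c("a", "b"), c("a", "c"), method = "jaccard"),
               1 / 3)
  expect_equal(word_usage_similarity(c("a", "a", "b"), c("a", "c"),
                                     method = "min_count"), 1 / 2.5)
})

test_that("mean embeddings average in-lexicon tokens and track coverage", {
  lex <- embedding_lexicon(rbind(c(1, 0), c(0, 1)), c("sun", "moon"))
  expect_equal(unname(mean_embedding("sun", lex)), c(1, 0), ignore_attr = TRUE)
  v <- mean_embedding(c("sun", "moon"), lex)
  expect_equal(unname(v), c(0.5, 0.5), ignore_attr = TRUE)
  v2 <- mean_embedding(c("sun", "comet"), lex)
  expect_equal(attr(v2, "coverage"), 0.5)
  expect_error(mean_embedding(c("comet", "star"), lex), "coverage")
})

test_that("cosine similarity matches hand values and scale invariance", {
  expect_equal(cosine_similarity(c(2, 5, 1), c(2, 5, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  set.seed(14)
  u <- rnorm(10); v <- rnorm(10)
  expect_equal(cosine_similarity(3.7 * u, v), cosine_similarity(u, v),
               tolerance = 1e-12)
  expect_equal(cosine_similarity(u, v),
               sum(u * v) / sqrt(sum(u^2) * sum(v^2)), tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:2, 1:3), "equal dimension")
})

test_that("word2vec text lexicons round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 4",
               "Apple 1 0 0 0",
               "pear 0 1 0 0",
               "plum 0 0 0.6 0.8"), path)
  lex <- read_word2vec(path, language = "en")
  expect_equal(nrow(lex), 3L)
  expect_equal(ncol(lex), 4L)
  expect_true("apple" %in% rownames(lex))  # case-folded
  expect_equal(unname(mean_embedding("plum", lex)), c(0, 0, 0.6, 0.8),
               ignore_attr = TRUE)
  expect_equal(attr(lex, "language"), "en")
  writeLines(c("not a header", "x 1 2"), path)
  expect_error(read_word2vec(path), "header")
})

test_that("identical transcripts hit the usage and embedding maxima", {
  text <- "we like the tap quite a lot"
  tr <- transcript(data.frame(speaker_id = c("A", "B", "A", "B"),
                              start = c(0, 1, 2, 3), end = c(1, 2, 3, 4),
                              text = rep(text, 4)))
  lex <- generate_lexicon(tokenize(text), dim = 8, seed = 2)
  rep1 <- linguistic_report(list(tr), "g1", lex)
  expect_equal(rep1$usage_half1, 2)
  expect_equal(rep1$usage_half2, 2)
  expect_equal(rep1$embedding_half1, 1, tolerance = 1e-12)
  expect_equal(rep1$embedding_half2, 1, tolerance = 1e-12)
})

test_that("groups without a lexicon get em-dash embedding cells on disk", {
  tr <- toy_transcript(texts = c("one two", "two three", "four five", "five six"))
  rep1 <- linguistic_report(list(tr, tr), c("g1", "g2"),
                            lexicons = list(g1 = generate_lexicon(
                              c("one", "two", "three", "four", "five", "six"),
                              dim = 4, seed = 3)))
  expect_false(is.na(rep1$embedding_half1[rep1$group == "g1"]))
  expect_true(is.na(rep1$embedding_half1[rep1$group == "g2"]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_linguistic_report(rep1, path)
  lines <- readLines(path, encoding = "UTF-8")
  expect_true(any(grepl("—", lines)))
})

test_that("raising second-half vocabulary overlap raises half-2 usage similarity", {
  hits <- 0L
  for (s in 1:10) {
    g <- generate_dyad(dyad_generator_config(shared_vocab_half1 = 0.2,
                                             shared_vocab_half2 = 0.8,
                                             seed = 60 + s))
    rep1 <- linguistic_report(list(g$transcript), "g")
    hits <- hits + (rep1$usage_half2 > rep1$usage_half1)
  }
  expect_gte(hits, 9L)
})
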