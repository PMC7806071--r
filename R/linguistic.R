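#' Minimal language-agnostic tokenizer
#'
#' Lowercases, strips punctuation (anything that is neither a letter, digit
#' nor whitespace), and splits on whitespace. Deliberately minimal: no
#' stemming, no stop-word removal, so it behaves the same across languages.
#'
#' @param text Character vector.
#' @return Character vector of tokens (zero length for empty input).
#' @export
#' @examples
#' tokenize("Hello, WORLD.")
tokenize <- function(text) {
  text <- tolower(paste(text, collapse = " "))
  text <- gsub("[^[:alnum:][:space:]']", " ", text)
  text <- gsub("'", "", text)
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

#' Split a transcript into conversation halves
#'
#' Splits the session at the midpoint of its time span (from the first
#' turn's start to the last turn's end) and pools each speaker's tokens per
#' half; a turn belongs to the half containing its *start* time, with the
#' boundary itself (`t = T/2`) opening the second half. Comparing lexical
#' similarity between the first and second half is how lexical
#' entrainment over the course of the conversation is measured.
#'
#' @param tr A [transcript()].
#' @return List of two `half_session_tokens` objects (fields `half_index`,
#'   `tokens_a`, `tokens_b`, `speakers`); a warning flags any half in which
#'   a speaker has no tokens.
#' @export
split_halves <- function(tr) {
  stopifnot(inherits(tr, "transcript"))
  t0 <- min(tr$start); t1 <- max(tr$end)
  if (t1 <= t0) stop("transcript has no positive time span", call. = FALSE)
  mid <- t0 + (t1 - t0) / 2
  speakers <- transcript_speakers(tr)
  half_of <- ifelse(tr$start < mid, 1L, 2L)
  build <- function(h) {
    sub <- tr[half_of == h, , drop = FALSE]
    toks <- lapply(speakers, function(sp) tokenize(sub$text[sub$speaker_id == sp]))
    if (any(lengths(toks) == 0L)) {
      warning(sprintf("half %d has zero tokens for speaker '%s': similarity undefined",
                      h, speakers[which(lengths(toks) == 0L)[1L]]))
    }
    structure(list(half_index = h, tokens_a = toks[[1L]], tokens_b = toks[[2L]],
                   speakers = speakers),
              class = "half_session_tokens")
  }
  list(build(1L), build(2L))
}

#' Shared word-usage similarity between two speakers
#'
#' Counts how often word types used by *both* speakers occur, normalized by
#' the mean number of tokens per speaker: with per-type counts `c_A(w)`,
#' `c_B(w)` and totals `N_A`, `N_B`,
#' `S = sum over shared types of (c_A(w) + c_B(w)) / ((N_A + N_B) / 2)`.
#' `S` ranges over `[0, 2]`: 0 for disjoint vocabularies, 2 exactly when
#' every token on both sides belongs to a shared type. Values above 1 are
#' common in real conversations where frequent words are shared.
#'
#' Two alternative (non-default) scores are available: `"min_count"`
#' (`sum min(c_A, c_B)` over shared types, same normalization) and
#' `"jaccard"` (type-level Jaccard index, range `[0, 1]`).
#'
#' @param tokens_a,tokens_b Non-empty token vectors (see [tokenize()]).
#' @param method `"shared_count"` (default), `"min_count"`, or `"jaccard"`.
#' @return A single similarity value.
#' @export
#' @examples
#' word_usage_similarity(c("the", "tap", "is", "nice"), c("the", "tap", "drips"))
word_usage_similarity <- function(tokens_a, tokens_b,
                                  method = c("shared_count", "min_count", "jaccard")) {
  method <- match.arg(method)
  if (length(tokens_a) == 0L || length(tokens_b) == 0L) {
    stop("undefined similarity: empty token list", call. = FALSE)
  }
  ca <- table(tokens_a); cb <- table(tokens_b)
  shared <- intersect(names(ca), names(cb))
  switch(method,
    shared_count = sum(ca[shared] + cb[shared]) /
      ((length(tokens_a) + length(tokens_b)) / 2),
    min_count = sum(pmin(as.numeric(ca[shared]), as.numeric(cb[shared]))) /
      ((length(tokens_a) + length(tokens_b)) / 2),
    jaccard = length(shared) / length(union(names(ca), names(cb))))
}

#' Read a word-embedding lexicon in word2vec text format
#'
#' First line: `"<vocab_size> <dim>"`; each following line: a word and its
#' `dim` vector components, space-separated. (Binary word2vec files must be
#' converted to the text variant externally.) Lookups are case-normalized
#' when `lowercase = TRUE` (default), matching [tokenize()].
#'
#' @param path Path to the lexicon file.
#' @param lowercase Lowercase words on load (default `TRUE`).
#' @param language Optional language tag stored on the object.
#' @return An `embedding_lexicon`: numeric matrix (rows = words) with
#'   attributes `language` and `lowercase`.
#' @export
read_word2vec <- function(path, lowercase = TRUE, language = "und") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  header <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(header) != 2L || anyNA(header)) {
    stop("malformed word2vec header (expected '<vocab_size> <dim>')", call. = FALSE)
  }
  dim_d <- header[2L]
  fields <- strsplit(trimws(lines[-1L]), "\\s+")
  words <- vapply(fields, `[`, "", 1L)
  if (lowercase) words <- tolower(words)
  vecs <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(dim_d)))
  if (anyNA(vecs)) stop("non-numeric embedding component in lexicon", call. = FALSE)
  keep <- !duplicated(words)  # first occurrence wins after case folding
  embedding_lexicon(vecs[keep, , drop = FALSE], words[keep],
                    language = language, lowercase = lowercase)
}

#' Construct an embedding lexicon from a matrix
#'
#' @param vectors Numeric matrix, one row per word.
#' @param words Character vector of words (no duplicates).
#' @param language Language tag.
#' @param lowercase Whether lookups case-fold.
#' @return An `embedding_lexicon`.
#' @export
embedding_lexicon <- function(vectors, words, language = "und", lowercase = TRUE) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(words)) stop("one vector per word required", call. = FALSE)
  if (anyDuplicated(words)) stop("duplicate words in lexicon", call. = FALSE)
  rownames(vectors) <- words
  structure(vectors, language = language, lowercase = lowercase,
            class = c("embedding_lexicon", "matrix", "array"))
}

#' @export
print.embedding_lexicon <- function(x, ...) {
  cat(sprintf("<embedding_lexicon> %d words x %d dims (language %s)\n",
              nrow(x), ncol(x), attr(x, "language")))
  invisible(x)
}

#' Mean word embedding of a token list
#'
#' Arithmetic mean of the embedding vectors of in-lexicon tokens
#' (token-level, so repeated words weigh by use). Out-of-vocabulary tokens
#' are skipped and reported through the `coverage` attribute (fraction of
#' tokens found).
#'
#' @param tokens Token vector.
#' @param lexicon An [embedding_lexicon()].
#' @return Numeric vector of the lexicon's dimensionality, with attribute
#'   `coverage`.
#' @export
mean_embedding <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "embedding_lexicon"))
  if (isTRUE(attr(lexicon, "lowercase"))) tokens <- tolower(tokens)
  hit <- tokens %in% rownames(lexicon)
  if (!any(hit)) {
    stop("coverage error: no token found in the embedding lexicon", call. = FALSE)
  }
  v <- colMeans(unclass(lexicon)[tokens[hit], , drop = FALSE])
  attr(v, "coverage") <- mean(hit)
  v
}

#' Cosine similarity of two vectors
#'
#' `u . v / (|u| |v|)`, in `[-1, 1]`.
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return A single similarity value.
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("vectors must have equal dimension", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined: zero vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

# similarity measures for one transcript: usage + optional embedding, per half
session_linguistic <- function(tr, lexicon = NULL) {
  halves <- split_halves(tr)
  one <- function(h) {
    usage <- if (length(h$tokens_a) && length(h$tokens_b)) {
      word_usage_similarity(h$tokens_a, h$tokens_b)
    } else NA_real_
    emb <- if (!is.null(lexicon) && length(h$tokens_a) && length(h$tokens_b)) {
      tryCatch(cosine_similarity(mean_embedding(h$tokens_a, lexicon),
                                 mean_embedding(h$tokens_b, lexicon)),
               error = function(e) NA_real_)
    } else NA_real_
    c(usage = usage, embedding = emb)
  }
  rbind(half1 = one(halves[[1L]]), half2 = one(halves[[2L]]))
}

#' Half-session lexical similarity report per group
#'
#' For every group, averages the per-session shared word-usage similarity
#' and (when a lexicon is available) the cosine similarity between the two
#' speakers' mean word embeddings, separately for the first and second half
#' of each conversation. Rising similarity from half 1 to half 2 indicates
#' lexical entrainment.
#'
#' @param transcripts List of [transcript()]s.
#' @param group_ids Character vector of group labels, one per transcript.
#' @param lexicons Either `NULL` (no embedding columns), a single
#'   [embedding_lexicon()] used for all groups, or a named list mapping
#'   group id to lexicon (groups without an entry get `NA` embedding
#'   cells, rendered as em dashes in the written report).
#' @return `data.frame` with columns `group`, `usage_half1`, `usage_half2`,
#'   `embedding_half1`, `embedding_half2`, `n_sessions`.
#' @export
linguistic_report <- function(transcripts, group_ids, lexicons = NULL) {
  stopifnot(length(transcripts) == length(group_ids))
  lex_for <- function(g) {
    if (is.null(lexicons)) NULL
    else if (inherits(lexicons, "embedding_lexicon")) lexicons
    else lexicons[[g]]
  }
  groups <- unique(group_ids)
  rows <- lapply(groups, function(g) {
    idx <- which(group_ids == g)
    per <- lapply(transcripts[idx], session_linguistic, lexicon = lex_for(g))
    m <- Reduce(`+`, lapply(per, function(p) ifelse(is.na(p), 0, p))) /
      Reduce(`+`, lapply(per, function(p) !is.na(p) * 1))
    data.frame(group = g,
               usage_half1 = m["half1", "usage"],
               usage_half2 = m["half2", "usage"],
               embedding_half1 = m["half1", "embedding"],
               embedding_half2 = m["half2", "embedding"],
               n_sessions = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a linguistic report with em-dash placeholders
#'
#' Serializes a [linguistic_report()] table as tab-separated text, printing
#' missing embedding cells (groups without a lexicon) as an em dash.
#'
#' @param report Data frame from [linguistic_report()].
#' @param path Output path.
#' @param digits Digits for similarity values (default 3).
#' @return `path`, invisibly.
#' @export
write_linguistic_report <- function(report, path, digits = 3) {
  fmt <- report
  for (col in c("usage_half1", "usage_half2", "embedding_half1", "embedding_half2")) {
    v <- report[[col]]
    fmt[[col]] <- ifelse(is.na(v) | is.nan(v), "—",
                         formatC(v, digits = digits, format = "f"))
  }
  utils::write.table(fmt, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
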