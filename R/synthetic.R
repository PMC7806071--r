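#' Configuration for the synthetic dyad generator
#'
#' Defines the generative model used to validate the pipeline end to end
#' without access to a real conversation corpus. Two speakers alternate
#' turns of `turn_seconds` over a `session_seconds` session sampled every
#' `frame_step` seconds. Speaker A's frames are drawn from
#' `Normal(mean_a, noise_scale^2 I)` throughout; speaker B starts at
#' `mean_b0` and, at session-normalized time `t`, is drawn from
#' `Normal(mean_b0 + kappa * t * (mean_a - mean_b0), noise_scale^2 I)` —
#' i.e. `kappa` is the fraction of the initial mean gap closed, linearly,
#' by session end. `kappa = 0` is the static (null) dyad; `kappa = 1` full
#' convergence. With `symmetric = TRUE` both speakers drift toward the
#' midpoint, each closing `kappa/2` of the gap.
#'
#' Transcript tokens are drawn per turn: with probability
#' `shared_vocab_half1` (first half) or `shared_vocab_half2` (second half)
#' from a pool shared by both speakers, otherwise from the speaker's
#' private pool, so lexical overlap between halves is controllable.
#'
#' @param n_dims Feature dimensionality (default 16).
#' @param frame_step Seconds per frame (default 0.010).
#' @param session_seconds Session length (default 60).
#' @param turn_seconds Turn length (default 5; must satisfy
#'   `session_seconds > 2 * turn_seconds`).
#' @param mean_a,mean_b0 Initial speaker means; scalars are recycled over
#'   `n_dims` (defaults 0 and 2).
#' @param noise_scale Per-dimension standard deviation (default 1).
#' @param kappa Convergence rate in `[0, 1]` (default 0).
#' @param symmetric Both speakers converge toward the midpoint (default
#'   `FALSE`: only B moves).
#' @param vocab_size Words per pool — one shared plus one private pool per
#'   speaker, each of this size (default 50).
#' @param shared_vocab_half1,shared_vocab_half2 Probability that a token is
#'   drawn from the shared pool in each half (defaults 0.2, 0.2).
#' @param tokens_per_turn Tokens per turn (default 12).
#' @param seed Integer seed (default 1).
#' @return A `dyad_generator_config` list.
#' @export
dyad_generator_config <- function(n_dims = 16L, frame_step = 0.010,
                                  session_seconds = 60, turn_seconds = 5,
                                  mean_a = 0, mean_b0 = 2, noise_scale = 1,
                                  kappa = 0, symmetric = FALSE,
                                  vocab_size = 50L,
                                  shared_vocab_half1 = 0.2,
                                  shared_vocab_half2 = 0.2,
                                  tokens_per_turn = 12L, seed = 1L) {
  if (!(session_seconds > 2 * turn_seconds)) {
    stop("invalid config: need session_seconds > 2 * turn_seconds", call. = FALSE)
  }
  if (noise_scale <= 0) stop("invalid config: noise_scale must be > 0", call. = FALSE)
  if (kappa < 0 || kappa > 1) stop("invalid config: kappa must be in [0, 1]", call. = FALSE)
  if (shared_vocab_half1 < 0 || shared_vocab_half1 > 1 ||
      shared_vocab_half2 < 0 || shared_vocab_half2 > 1) {
    stop("invalid config: shared_vocab proportions must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_dims = as.integer(n_dims), frame_step = frame_step,
                 session_seconds = session_seconds, turn_seconds = turn_seconds,
                 mean_a = rep_len(mean_a, n_dims),
                 mean_b0 = rep_len(mean_b0, n_dims),
                 noise_scale = noise_scale, kappa = kappa, symmetric = symmetric,
                 vocab_size = as.integer(vocab_size),
                 shared_vocab_half1 = shared_vocab_half1,
                 shared_vocab_half2 = shared_vocab_half2,
                 tokens_per_turn = as.integer(tokens_per_turn),
                 seed = as.integer(seed)),
            class = "dyad_generator_config")
}

# noiseless speaker means at normalized time t (used by tests and docs)
speaker_means_at <- function(cfg, t) {
  gap <- cfg$mean_a - cfg$mean_b0
  if (cfg$symmetric) {
    list(a = cfg$mean_a - cfg$kappa / 2 * t * gap,
         b = cfg$mean_b0 + cfg$kappa / 2 * t * gap)
  } else {
    list(a = cfg$mean_a,
         b = cfg$mean_b0 + cfg$kappa * t * gap)
  }
}

#' Generate one synthetic dyadic session
#'
#' Draws the whole-recording frame stream and turn transcript described in
#' [dyad_generator_config()], then segments it with [split_by_speaker()].
#' Fully reproducible per `cfg$seed`.
#'
#' @param cfg A [dyad_generator_config()].
#' @param session_id,group_id Labels for the session.
#' @return List with `session` (a [dyad_session()]), `transcript`, and
#'   `features` (the unsegmented whole-recording [feature_sequence()]).
#' @export
#' @examples
#' g <- generate_dyad(dyad_generator_config(kappa = 0.8, seed = 7))
#' g$session
generate_dyad <- function(cfg, session_id = "synthetic", group_id = "all") {
  stopifnot(inherits(cfg, "dyad_generator_config"))
  with_seed(cfg$seed, {
    n_turns <- floor(cfg$session_seconds / cfg$turn_seconds)
    starts <- (seq_len(n_turns) - 1) * cfg$turn_seconds
    speakers <- rep(c("A", "B"), length.out = n_turns)
    n_frames <- floor(cfg$session_seconds / cfg$frame_step)
    times <- (seq_len(n_frames) - 1) * cfg$frame_step
    t_norm <- times / cfg$session_seconds
    turn_of <- pmin(floor(times / cfg$turn_seconds) + 1, n_turns)
    is_a <- speakers[turn_of] == "A"
    gap <- cfg$mean_a - cfg$mean_b0
    rate_a <- if (cfg$symmetric) -cfg$kappa / 2 else 0
    rate_b <- if (cfg$symmetric) cfg$kappa / 2 else cfg$kappa
    mu_a <- matrix(cfg$mean_a, n_frames, cfg$n_dims, byrow = TRUE) +
      (rate_a * t_norm) %o% gap
    mu_b <- matrix(cfg$mean_b0, n_frames, cfg$n_dims, byrow = TRUE) +
      (rate_b * t_norm) %o% gap
    mu <- matrix(NA_real_, n_frames, cfg$n_dims)
    mu[is_a, ] <- mu_a[is_a, ]
    mu[!is_a, ] <- mu_b[!is_a, ]
    values <- mu + matrix(stats::rnorm(n_frames * cfg$n_dims, sd = cfg$noise_scale),
                          n_frames, cfg$n_dims)
    colnames(values) <- sprintf("f%02d", seq_len(cfg$n_dims))
    feats <- feature_sequence(values, frame_step = cfg$frame_step,
                              feature_set = "synthetic")

    shared <- sprintf("shared%03d", seq_len(cfg$vocab_size))
    priv <- list(A = sprintf("alpha%03d", seq_len(cfg$vocab_size)),
                 B = sprintf("beta%03d", seq_len(cfg$vocab_size)))
    mid <- cfg$session_seconds / 2
    draw_tokens <- function(sp, start) {
      p_shared <- if (start < mid) cfg$shared_vocab_half1 else cfg$shared_vocab_half2
      from_shared <- stats::runif(cfg$tokens_per_turn) < p_shared
      toks <- character(cfg$tokens_per_turn)
      toks[from_shared] <- sample(shared, sum(from_shared), replace = TRUE)
      toks[!from_shared] <- sample(priv[[sp]], sum(!from_shared), replace = TRUE)
      paste(toks, collapse = " ")
    }
    turns <- data.frame(speaker_id = speakers, start = starts,
                        end = starts + cfg$turn_seconds,
                        text = mapply(draw_tokens, speakers, starts),
                        stringsAsFactors = FALSE)
    tr <- transcript(turns, session_id = session_id)
    split <- split_by_speaker(feats, tr)
    session <- dyad_session(split[[1L]], split[[2L]], tr, group_id = group_id)
    list(session = session, transcript = tr, features = feats)
  })
}

#' Generate a synthetic corpus on disk
#'
#' Writes one feature table and one transcript per session plus a manifest
#' (`manifest.tsv`: `session_id`, `group_id`, `features_path`,
#' `transcript_path`) linking them, the on-disk layout consumed by
#' [run_acoustic_pipeline()] and [run_linguistic_pipeline()]. Per-session
#' seeds are derived deterministically from `seed`, so the corpus is
#' reproducible byte for byte.
#'
#' @param n_sessions_per_group Sessions per group.
#' @param group_configs Named list mapping group id to a
#'   [dyad_generator_config()] (the config's own `seed` is overridden).
#' @param out_dir Output directory (created if needed).
#' @param seed Corpus master seed.
#' @return Path to the manifest file, invisibly; the manifest data frame is
#'   attached as attribute `manifest`.
#' @export
generate_corpus <- function(n_sessions_per_group, group_configs, out_dir,
                            seed = 1L) {
  stopifnot(length(group_configs) >= 1L, !is.null(names(group_configs)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0L
  for (g in names(group_configs)) {
    cfg <- group_configs[[g]]
    stopifnot(inherits(cfg, "dyad_generator_config"))
    for (i in seq_len(n_sessions_per_group)) {
      k <- k + 1L
      cfg$seed <- as.integer((seed * 1000L + k) %% .Machine$integer.max)
      sid <- sprintf("%s_s%02d", g, i)
      gen <- generate_dyad(cfg, session_id = sid, group_id = g)
      fpath <- file.path(out_dir, paste0(sid, "_features.csv"))
      tpath <- file.path(out_dir, paste0(sid, "_transcript.tsv"))
      write_feature_table(gen$features, fpath)
      write_transcript(gen$transcript, tpath)
      rows[[k]] <- data.frame(session_id = sid, group_id = g,
                              features_path = basename(fpath),
                              transcript_path = basename(tpath),
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  out <- invisible(mpath)
  attr(out, "manifest") <- manifest
  out
}

#' Generate a synthetic word-embedding lexicon
#'
#' Unit-norm random vectors per word. Words sharing a topic label are
#' placed inside a fixed angular cone around a random topic centroid:
#' each vector is `cos(cone) * centroid + sin(cone) * u` with `u` a random
#' unit vector orthogonal to the centroid, which guarantees the cosine
#' similarity of two same-topic words is at least `cos(2 * cone)`.
#'
#' @param vocab Character vector of distinct words.
#' @param dim Embedding dimensionality (>= 2, default 50).
#' @param topics Optional character vector (same length as `vocab`) of
#'   topic labels; `NA` entries get independent directions.
#' @param cone_angle Half-angle of the topic cone in radians (default
#'   `pi / 9`, i.e. 20 degrees).
#' @param seed Integer seed.
#' @return An [embedding_lexicon()] of unit-norm vectors.
#' @export
generate_lexicon <- function(vocab, dim = 50L, topics = NULL,
                             cone_angle = pi / 9, seed = 1L) {
  if (anyDuplicated(vocab)) stop("duplicate words in vocab", call. = FALSE)
  if (dim < 2L) stop("dim must be >= 2", call. = FALSE)
  if (!is.null(topics)) stopifnot(length(topics) == length(vocab))
  with_seed(seed, {
    unit <- function(v) v / sqrt(sum(v^2))
    rand_unit <- function() unit(stats::rnorm(dim))
    centroids <- list()
    vecs <- matrix(NA_real_, length(vocab), dim)
    for (i in seq_along(vocab)) {
      topic <- if (!is.null(topics)) topics[i] else NA
      if (is.na(topic)) {
        vecs[i, ] <- rand_unit()
      } else {
        if (is.null(centroids[[topic]])) centroids[[topic]] <- rand_unit()
        c0 <- centroids[[topic]]
        u <- stats::rnorm(dim)
        u <- unit(u - sum(u * c0) * c0)  # orthogonal complement direction
        vecs[i, ] <- cos(cone_angle) * c0 + sin(cone_angle) * u
      }
    }
    embedding_lexicon(vecs, vocab, language = "synthetic")
  })
}
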