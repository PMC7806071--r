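test_that("turn and frame arithmetic matches the generative design", {
  # 60 s session, 5 s turns, 10 ms step: 12 turns, 6 per speaker,
  # 500 frames per turn -> 3000 frames per speaker
  g <- generate_dyad(dyad_generator_config(session_seconds = 60,
                                           turn_seconds = 5, seed = 1))
  expect_equal(nrow(g$transcript), 12L)
  expect_equal(sum(g$transcript$speaker_id == "A"), 6L)
  expect_equal(nrow(g$session$features_a), 3000L)
  expect_equal(nrow(g$session$features_b), 3000L)
  expect_equal(nrow(g$features), 6000L)
})

test_that("generation is deterministic per seed", {
  cfg <- quick_dyad_config(kappa = 0.3, seed = 123)
  g1 <- generate_dyad(cfg); g2 <- generate_dyad(cfg)
  expect_identical(as_matrix_test(g1$features), as_matrix_test(g2$features))
  expect_identical(g1$transcript$text, g2$transcript$text)
  g3 <- generate_dyad(quick_dyad_config(kappa = 0.3, seed = 124))
  expect_false(identical(as_matrix_test(g1$features), as_matrix_test(g3$features)))
})

test_that("full convergence brings B's final turn onto A's mean", {
  cfg <- dyad_generator_config(kappa = 1, seed = 5, n_dims = 8,
                               session_seconds = 60, turn_seconds = 5)
  g <- generate_dyad(cfg)
  tmB <- frame_times(g$session$features_b)
  last_turn <- tmB >= max(g$transcript$start[g$transcript$speaker_id == "B"])
  mb <- colMeans(as_matrix_test(g$session$features_b)[last_turn, ])
  n <- sum(last_turn)
  # B's closing mean within 3 sigma/sqrt(n) of A's mean, per dimension
  expect_true(all(abs(mb - cfg$mean_a) < 3 * cfg$noise_scale / sqrt(n) +
                    cfg$kappa * cfg$turn_seconds / cfg$session_seconds *
                      abs(cfg$mean_a - cfg$mean_b0)))
})

test_that("a static dyad shows no first-vs-last turn shift", {
  pvals <- sapply(1:8, function(s) {
    g <- generate_dyad(dyad_generator_config(kappa = 0, seed = 200 + s,
                                             n_dims = 4))
    xb <- as_matrix_test(g$session$features_b)
    tmB <- frame_times(g$session$features_b)
    first <- tmB < sort(unique(g$transcript$start[g$transcript$speaker_id == "B"]))[2]
    t.test(rowMeans(xb[first, ]), rowMeans(xb[!first, ]))$p.value
  })
  expect_gte(sum(pvals > 0.01), 6L)
})

test_that("expected partner distance decreases in time exactly on the means", {
  for (sym in c(FALSE, TRUE)) {
    cfg <- dyad_generator_config(kappa = 0.6, symmetric = sym)
    d <- sapply(seq(0, 1, by = 0.1), function(t) {
      m <- dyadsync:::speaker_means_at(cfg, t)
      sqrt(sum((m$a - m$b)^2))
    })
    expect_true(all(diff(d) < 0))
  }
  # kappa = 0: distance constant
  cfg0 <- dyad_generator_config(kappa = 0)
  d0 <- sapply(c(0, 0.5, 1), function(t) {
    m <- dyadsync:::speaker_means_at(cfg0, t)
    sqrt(sum((m$a - m$b)^2))
  })
  expect_equal(diff(d0), c(0, 0))
})

test_that("generated corpora land on disk with a consistent manifest", {
  out <- withr::local_tempdir()
  cfgs <- list(g1 = quick_dyad_config(kappa = 0.8),
               g2 = quick_dyad_config(kappa = 0))
  mpath <- generate_corpus(3, cfgs, out, seed = 11)
  mf <- read.delim(mpath)
  expect_equal(nrow(mf), 6L)
  expect_equal(sort(unique(mf$group_id)), c("g1", "g2"))
  expect_true(all(file.exists(file.path(out, mf$features_path))))
  expect_true(all(file.exists(file.path(out, mf$transcript_path))))
  # feature tables round-trip through the reader
  fs <- read_feature_table(file.path(out, mf$features_path[1]))
  expect_equal(nrow(fs), 1200L)  # 12 s at 10 ms
  # same seed -> byte-identical corpus
  out2 <- withr::local_tempdir()
  generate_corpus(3, cfgs, out2, seed = 11)
  for (f in c(mf$features_path, mf$transcript_path, "manifest.tsv")) {
    expect_identical(readLines(file.path(out, f)), readLines(file.path(out2, f)))
  }
})

test_that("synthetic lexicons are unit-norm, deterministic and topic-coherent", {
  vocab <- sprintf("w%02d", 1:20)
  topics <- rep(c("t1", "t2", NA), length.out = 20)
  cone <- pi / 9
  lex <- generate_lexicon(vocab, dim = 16, topics = topics, cone_angle = cone,
                          seed = 9)
  norms <- sqrt(rowSums(unclass(lex)^2))
  expect_equal(norms, rep(1, 20), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(unclass(generate_lexicon(vocab, dim = 16, topics = topics,
                                            cone_angle = cone, seed = 9)),
                   unclass(lex))
  # same-topic pairs sit inside the guaranteed cone: cosine >= cos(2 * cone)
  idx <- which(topics == "t1")
  for (i in idx) for (j in idx) if (i < j) {
    expect_gte(cosine_similarity(lex[i, ], lex[j, ]), cos(2 * cone) - 1e-12)
  }
  expect_error(generate_lexicon(c("a", "a"), dim = 4), "duplicate")
  expect_error(generate_lexicon("a", dim = 1), "dim")
})

test_that("invalid generator configs are rejected", {
  expect_error(dyad_generator_config(session_seconds = 8, turn_seconds = 5),
               "session_seconds")
  expect_error(dyad_generator_config(kappa = 1.2), "kappa")
  expect_error(dyad_generator_config(noise_scale = 0), "noise_scale")
  expect_error(dyad_generator_config(shared_vocab_half1 = 2), "shared_vocab")
})
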