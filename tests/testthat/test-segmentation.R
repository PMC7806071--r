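test_that("frames are assigned to speakers by start time over [start, end)", {
  # 10 frames at 10 ms over [0, 0.1); A owns [0, 0.05), B owns [0.05, 0.1)
  fs <- feature_sequence(matrix(1:10, ncol = 1), frame_step = 0.01)
  tr <- transcript(data.frame(speaker_id = c("A", "B"),
                              start = c(0, 0.05), end = c(0.05, 0.1),
                              text = c("", "")))
  split <- split_by_speaker(fs, tr)
  expect_equal(nrow(split$A), 5L)
  expect_equal(nrow(split$B), 5L)
  expect_equal(as.numeric(split$A), 1:5, ignore_attr = TRUE)
  expect_equal(frame_times(split$B), seq(0.05, 0.09, by = 0.01))
})

test_that("frames in transcript gaps belong to nobody", {
  fs <- feature_sequence(matrix(1:10, ncol = 1), frame_step = 0.01)
  tr <- transcript(data.frame(speaker_id = c("A", "B"),
                              start = c(0, 0.06), end = c(0.04, 0.1),
                              text = c("", "")))
  split <- split_by_speaker(fs, tr)
  counts <- attr(split, "frame_assignment")
  expect_equal(unname(counts["dropped"]), 2L)  # frames at 0.04, 0.05
  expect_equal(nrow(split$A) + nrow(split$B), 8L)
})

test_that("overlapping speech is dropped by default or duplicated on request", {
  fs <- feature_sequence(matrix(1:10, ncol = 1), frame_step = 0.01)
  tr <- transcript(data.frame(speaker_id = c("A", "B"),
                              start = c(0, 0.05), end = c(0.07, 0.1),
                              text = c("", "")))
  dropped <- split_by_speaker(fs, tr, overlap = "drop")
  expect_equal(frame_times(dropped$A), seq(0, 0.04, by = 0.01))   # [0.05, 0.07) cut
  expect_equal(frame_times(dropped$B), seq(0.07, 0.09, by = 0.01))
  both <- split_by_speaker(fs, tr, overlap = "both")
  expect_equal(nrow(both$A), 7L)
  expect_equal(nrow(both$B), 5L)
  # full containment: the overlapped speaker loses every frame -> error
  tr2 <- transcript(data.frame(speaker_id = c("A", "B"),
                               start = c(0, 0.05), end = c(0.1, 0.1),
                               text = c("", "")))
  expect_error(split_by_speaker(fs, tr2, overlap = "drop"), "empty subsequence")
})

test_that("frame conservation holds under the drop policy", {
  set.seed(11)
  for (rep in 1:5) {
    n_turns <- sample(3:7, 1)
    starts <- sort(runif(n_turns, 0, 0.8))
    ends <- starts + runif(n_turns, 0.02, 0.2)
    tr <- transcript(data.frame(speaker_id = rep(c("A", "B"), length.out = n_turns),
                                start = starts, end = ends,
                                text = ""))
    fs <- feature_sequence(matrix(rnorm(100), ncol = 1), frame_step = 0.01)
    split <- tryCatch(split_by_speaker(fs, tr), error = function(e) NULL)
    if (is.null(split)) next  # a speaker may end up with zero frames
    counts <- attr(split, "frame_assignment")
    expect_equal(sum(counts), nrow(fs))
    # indices recovered from times are a duplicate-free subsequence
    idx <- sort(c(round(frame_times(split$A) / 0.01),
                  round(frame_times(split$B) / 0.01)))
    expect_true(!anyDuplicated(idx))
  }
})

test_that("degenerate transcripts are rejected", {
  fs <- feature_sequence(matrix(1:10, ncol = 1), frame_step = 0.01)
  expect_error(transcript(data.frame(speaker_id = "A", start = 0, end = 1,
                                     text = "")), "exactly 2 speakers")
  expect_error(transcript(data.frame(speaker_id = c("A", "B", "C"),
                                     start = c(0, 1, 2), end = c(1, 2, 3),
                                     text = "")), "exactly 2 speakers")
  tr <- transcript(data.frame(speaker_id = c("A", "B"),
                              start = c(0.5, 0), end = c(1, 0.05),
                              text = c("", "")))
  # sorted by start on construction
  expect_equal(tr$speaker_id, c("B", "A"))
  # speaker A owns [0.5, 1) but frames stop at 0.09 -> empty subsequence
  expect_error(split_by_speaker(fs, tr), "empty subsequence.*'A'")
})

test_that("transcripts round-trip through the tab-delimited format", {
  tr <- toy_transcript(texts = c("hello there", "well, hi!", "good good", "yes"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transcript(tr, path)
  back <- read_transcript(path)
  expect_equal(back$speaker_id, tr$speaker_id)
  expect_equal(back$start, tr$start)
  expect_equal(back$text, tr$text)
  expect_equal(attr(back, "session_id"), "toy")
})
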