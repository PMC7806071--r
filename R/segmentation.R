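#' Construct a conversation transcript
#'
#' A transcript is an ordered set of speaker-labelled, time-stamped turns
#' for one dyadic session. Exactly two distinct speakers must appear.
#'
#' @param turns `data.frame` with columns `speaker_id`, `start`, `end`
#'   (seconds) and `text` (token string; may be empty).
#' @param session_id Session label.
#' @return A `transcript` object (the data frame, sorted by `start`, with a
#'   `session_id` attribute).
#' @export
transcript <- function(turns, session_id = "session") {
  need <- c("speaker_id", "start", "end", "text")
  if (!all(need %in% names(turns))) {
    stop("turns must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  turns$speaker_id <- as.character(turns$speaker_id)
  turns$text <- as.character(turns$text)
  if (any(!(turns$start >= 0 & turns$start < turns$end))) {
    stop("every turn needs 0 <= start < end", call. = FALSE)
  }
  sp <- unique(turns$speaker_id)
  if (length(sp) != 2L) {
    stop(sprintf("format error: transcript must contain exactly 2 speakers, found %d (%s)",
                 length(sp), paste(sp, collapse = ", ")), call. = FALSE)
  }
  turns <- turns[order(turns$start), , drop = FALSE]
  rownames(turns) <- NULL
  structure(turns, session_id = session_id, class = c("transcript", "data.frame"))
}

#' @export
print.transcript <- function(x, ...) {
  sp <- transcript_speakers(x)
  cat(sprintf("<transcript> session '%s': %d turns, speakers %s / %s, span [%.2f, %.2f] s\n",
              attr(x, "session_id"), nrow(x), sp[1L], sp[2L],
              min(x$start), max(x$end)))
  invisible(x)
}

#' Speakers of a transcript, in order of first appearance
#'
#' The first speaker to talk is conventionally "A" for slope pairing.
#'
#' @param tr A [transcript()].
#' @return Character vector of length 2.
#' @export
transcript_speakers <- function(tr) {
  stopifnot(inherits(tr, "transcript"))
  unique(tr$speaker_id)
}

#' Read a tab-delimited transcript file
#'
#' Expects columns `session_id`, `speaker_id`, `start`, `end`, `text`
#' (header optional, tab-separated; times in seconds). A minimal
#' diarization-style interchange format.
#'
#' @param path Path to the transcript file.
#' @return A [transcript()].
#' @export
read_transcript <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("speaker_id", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!has_header) {
    names(df) <- c("session_id", "speaker_id", "start", "end", "text")[seq_len(ncol(df))]
  }
  transcript(df[, c("speaker_id", "start", "end", "text")],
             session_id = as.character(df$session_id[1L]))
}

#' Write a transcript to a tab-delimited file
#'
#' @param tr A [transcript()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(tr, path) {
  stopifnot(inherits(tr, "transcript"))
  df <- data.frame(session_id = attr(tr, "session_id"),
                   speaker_id = tr$speaker_id,
                   start = tr$start, end = tr$end, text = tr$text,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a recording's frames into per-speaker subsequences
#'
#' Assigns each frame of a whole-recording [feature_sequence()] to a speaker
#' when the frame's *start* time falls inside one of that speaker's turn
#' intervals `[start, end)`. Frames covered by neither speaker (silence,
#' gaps) are dropped; frames inside overlapping turns of both speakers are
#' dropped under the default `"drop"` policy or duplicated into both
#' subsequences under `"both"`. Within-speaker frame order is preserved and
#' original frame times are retained on the subsequences.
#'
#' @param seq A [feature_sequence()] covering the recording.
#' @param tr The session's [transcript()].
#' @param overlap One of `"drop"` (default) or `"both"`.
#' @return Named list of two `feature_sequence`s (names = speaker ids, in
#'   order of first appearance), with attribute `frame_assignment` (an
#'   integer vector of per-speaker frame counts plus dropped count).
#' @export
split_by_speaker <- function(seq, tr, overlap = c("drop", "both")) {
  stopifnot(inherits(seq, "feature_sequence"), inherits(tr, "transcript"))
  overlap <- match.arg(overlap)
  speakers <- transcript_speakers(tr)
  tm <- frame_times(seq)
  in_speaker <- function(sp) {
    turns <- tr[tr$speaker_id == sp, , drop = FALSE]
    hit <- rep(FALSE, length(tm))
    for (k in seq_len(nrow(turns))) {
      hit <- hit | (tm >= turns$start[k] & tm < turns$end[k])
    }
    hit
  }
  in_a <- in_speaker(speakers[1L])
  in_b <- in_speaker(speakers[2L])
  both <- in_a & in_b
  if (overlap == "drop") {
    in_a <- in_a & !both
    in_b <- in_b & !both
  }
  take <- function(keep, sp) {
    if (!any(keep)) {
      stop(sprintf("empty subsequence: no frames assigned to speaker '%s'", sp),
           call. = FALSE)
    }
    feature_sequence(as_matrix(seq)[keep, , drop = FALSE],
                     frame_step = attr(seq, "frame_step"),
                     start_time = tm[keep][1L],
                     feature_set = attr(seq, "feature_set"),
                     times = tm[keep])
  }
  out <- stats::setNames(list(take(in_a, speakers[1L]), take(in_b, speakers[2L])),
                         speakers)
  attr(out, "frame_assignment") <- c(
    stats::setNames(c(sum(in_a), sum(in_b)), speakers),
    dropped = if (overlap == "drop") sum(!in_a & !in_b) else sum(!in_a & !in_b & !both))
  out
}

#' Construct a dyadic session
#'
#' Bundles one recording: the two speakers' feature subsequences (typically
#' from [split_by_speaker()]), the transcript, and the group the session
#' belongs to (e.g. a culture in a cross-cultural corpus).
#'
#' @param features_a,features_b Per-speaker [feature_sequence()]s, in
#'   transcript speaker order (A = first speaker to talk).
#' @param tr The session [transcript()], or `NULL` when only features exist.
#' @param session_id Session label.
#' @param group_id Group label (default `"all"`).
#' @param speaker_a_id,speaker_b_id Speaker labels; taken from the
#'   transcript when given.
#' @return A `dyad_session` object.
#' @export
dyad_session <- function(features_a, features_b, tr = NULL,
                         session_id = "session", group_id = "all",
                         speaker_a_id = "A", speaker_b_id = "B") {
  stopifnot(inherits(features_a, "feature_sequence"),
            inherits(features_b, "feature_sequence"))
  if (!is.null(tr)) {
    sp <- transcript_speakers(tr)
    speaker_a_id <- sp[1L]; speaker_b_id <- sp[2L]
    session_id <- attr(tr, "session_id")
  }
  structure(list(session_id = session_id, group_id = group_id,
                 speaker_a_id = speaker_a_id, speaker_b_id = speaker_b_id,
                 features_a = features_a, features_b = features_b,
                 transcript = tr),
            class = "dyad_session")
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf("<dyad_session> '%s' (group %s): %s %d frames / %s %d frames, %d dims\n",
              x$session_id, x$group_id,
              x$speaker_a_id, nrow(x$features_a),
              x$speaker_b_id, nrow(x$features_b), ncol(x$features_a)))
  invisible(x)
}
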