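#' Run configuration for the end-to-end pipelines
#'
#' Resolves and validates everything a corpus run needs; the resolved
#' config is serialized (YAML) next to the outputs so any run can be
#' reproduced exactly.
#'
#' @param manifest_path Path to a corpus manifest (tab-separated with
#'   columns `session_id`, `group_id`, `features_path`, `transcript_path`;
#'   relative paths are resolved against the manifest's directory).
#' @param output_dir Directory for reports, logs and the resolved config.
#' @param feature_set_name Feature-set label; `"deep_spectrum"` forces
#'   `standardize = FALSE`.
#' @param standardize Standardize each recording before analysis (default
#'   `TRUE`; ignored with a message for Deep Spectrum features).
#' @param append_deltas Append first-order deltas after standardization
#'   (default `FALSE`; use for 65-dim LLD tables without precomputed
#'   deltas).
#' @param training A [training_config()].
#' @param slope_method `"ols"` or `"mean_first_difference"`.
#' @param overlap_policy Overlapping-speech policy for
#'   [split_by_speaker()].
#' @param lexicon_paths Optional named character vector (group id ->
#'   word2vec text file) for the linguistic pipeline.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest_path, output_dir,
                       feature_set_name = "compare_llds",
                       standardize = TRUE, append_deltas = FALSE,
                       training = training_config(),
                       slope_method = "ols",
                       overlap_policy = "drop",
                       lexicon_paths = NULL,
                       log_level = "info") {
  if (identical(feature_set_name, "deep_spectrum") && standardize) {
    standardize <- FALSE  # spectrogram embeddings are consumed raw
  }
  structure(list(manifest_path = manifest_path, output_dir = output_dir,
                 feature_set_name = feature_set_name,
                 standardize = standardize, append_deltas = append_deltas,
                 training = training, slope_method = slope_method,
                 overlap_policy = overlap_policy,
                 lexicon_paths = lexicon_paths,
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; the `training` key is a
#' nested map passed to [training_config()].
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. from CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$training)) raw$training <- do.call(training_config, raw$training)
  over <- list(...)
  raw[names(over)] <- over
  do.call(run_config, raw)
}

read_manifest <- function(manifest_path) {
  mf <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("session_id", "group_id", "features_path", "transcript_path")
  if (!all(need %in% names(mf))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  base <- dirname(manifest_path)
  for (col in c("features_path", "transcript_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", mf[[col]])
    mf[[col]][rel] <- file.path(base, mf[[col]][rel])
  }
  mf
}

pipeline_log <- function(cfg, con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  if (!identical(cfg$log_level, "quiet")) message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

write_resolved_config <- function(cfg, out_dir) {
  resolved <- unclass(cfg)
  resolved$training <- unclass(resolved$training)
  yaml::write_yaml(resolved, file.path(out_dir, "run_config.yaml"))
}

#' Run the acoustic synchrony pipeline over a corpus
#'
#' For every session in the manifest: read the feature table, standardize
#' per recording (unless disabled or Deep Spectrum), optionally append
#' deltas, segment by speaker using the transcript, fit the cross-partner
#' synchrony model ([dyad_synchrony()]), then aggregate per group
#' ([summarize_group()]). Failing sessions are logged and skipped; the
#' remaining sessions still produce a report.
#'
#' Outputs written to `cfg$output_dir`: `session_slopes.tsv` (one row per
#' speaker), `group_report.tsv` (average slope and pcc-of-pairs rows per
#' group), `run_config.yaml`, `pipeline.log`.
#'
#' @param cfg A [run_config()].
#' @return List with `session_slopes` (data frame), `group_report` (data
#'   frame), `summaries`, `failed` (character vector of failed session
#'   ids), invisibly.
#' @export
run_acoustic_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$output_dir, "pipeline.log"), "w")
  on.exit(close(log_con))
  mf <- read_manifest(cfg$manifest_path)
  pipeline_log(cfg, log_con, "acoustic pipeline: %d sessions, %d groups",
               nrow(mf), length(unique(mf$group_id)))
  fits <- list()
  failed <- character(0)
  for (i in seq_len(nrow(mf))) {
    sid <- mf$session_id[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      feats <- read_feature_table(mf$features_path[i],
                                  feature_set = cfg$feature_set_name)
      if (cfg$standardize) feats <- standardize_per_recording(feats)
      if (cfg$append_deltas) feats <- append_deltas(feats)
      tr <- read_transcript(mf$transcript_path[i])
      split <- split_by_speaker(feats, tr, overlap = cfg$overlap_policy)
      session <- dyad_session(split[[1L]], split[[2L]], tr,
                              group_id = mf$group_id[i])
      dyad_synchrony(session, config = cfg$training,
                     slope_method = cfg$slope_method, keep_models = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sid)
      pipeline_log(cfg, log_con, "session %s FAILED: %s", sid, conditionMessage(res))
    } else {
      fits[[sid]] <- res
      pipeline_log(cfg, log_con, "session %s done in %.1f s (slopes %+.4f / %+.4f)",
                   sid, proc.time()[["elapsed"]] - t0,
                   res$slope_a$slope, res$slope_b$slope)
    }
  }
  if (length(fits) == 0L) stop("all sessions failed", call. = FALSE)
  session_slopes <- do.call(rbind, lapply(fits, summary))
  rownames(session_slopes) <- NULL
  groups <- unique(session_slopes$group_id)
  summaries <- lapply(groups, function(g) {
    gf <- fits[vapply(fits, function(f) f$group_id == g, NA)]
    suppressWarnings(summarize_group(g, gf))
  })
  report <- group_report(summaries, feature_set = cfg$feature_set_name)
  utils::write.table(session_slopes, file.path(cfg$output_dir, "session_slopes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report, file.path(cfg$output_dir, "group_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_resolved_config(cfg, cfg$output_dir)
  pipeline_log(cfg, log_con, "wrote group_report.tsv (%d groups), %d sessions failed",
               length(groups), length(failed))
  invisible(list(session_slopes = session_slopes, group_report = report,
                 summaries = summaries, failed = failed))
}

#' Run the half-session linguistic pipeline over a corpus
#'
#' Reads every transcript in the manifest and writes the per-group
#' half-session lexical similarity table ([linguistic_report()]):
#' word-usage similarity always, embedding cosine similarity for groups
#' with a lexicon in `cfg$lexicon_paths`, an em dash otherwise.
#'
#' Outputs in `cfg$output_dir`: `linguistic_report.tsv`,
#' `run_config.yaml`, `pipeline.log`.
#'
#' @param cfg A [run_config()].
#' @return The report data frame, invisibly.
#' @export
run_linguistic_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$output_dir, "pipeline.log"), "w")
  on.exit(close(log_con))
  mf <- read_manifest(cfg$manifest_path)
  transcripts <- lapply(mf$transcript_path, read_transcript)
  lexicons <- NULL
  if (!is.null(cfg$lexicon_paths)) {
    lexicons <- lapply(cfg$lexicon_paths, read_word2vec)
    names(lexicons) <- names(cfg$lexicon_paths)
  }
  pipeline_log(cfg, log_con, "linguistic pipeline: %d transcripts, lexicons for: %s",
               nrow(mf),
               if (is.null(lexicons)) "none" else paste(names(lexicons), collapse = ", "))
  report <- suppressWarnings(linguistic_report(transcripts, mf$group_id, lexicons))
  write_linguistic_report(report, file.path(cfg$output_dir, "linguistic_report.tsv"))
  write_resolved_config(cfg, cfg$output_dir)
  pipeline_log(cfg, log_con, "wrote linguistic_report.tsv (%d groups)", nrow(report))
  invisible(report)
}
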