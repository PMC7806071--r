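#' Per-frame reconstruction RMSE trace
#'
#' For each frame `i`, computes the root-mean-square error across feature
#' dimensions between the original and reconstructed frame:
#' `rmse[i] = sqrt(mean_j (orig[i,j] - recon[i,j])^2)`. The resulting
#' ordered scalar sequence is the reconstruction-error trace whose temporal
#' trend carries the synchrony signal.
#'
#' @param original,reconstructed [feature_sequence()]s or matrices of
#'   identical shape and frame order.
#' @param times Optional frame times in seconds; defaults to the original's
#'   [frame_times()] when it is a `feature_sequence`, else frame index.
#' @param test_speaker_id,model_speaker_id Labels recorded on the trace:
#'   whose frames were tested, and whose autoencoder reconstructed them.
#' @return A `reconstruction_trace`: list with `rmse`, `times`,
#'   `test_speaker_id`, `model_speaker_id`.
#' @export
frame_rmse <- function(original, reconstructed, times = NULL,
                       test_speaker_id = "test", model_speaker_id = "model") {
  o <- if (inherits(original, "feature_sequence")) as_matrix(original) else as.matrix(original)
  r <- if (inherits(reconstructed, "feature_sequence")) as_matrix(reconstructed) else as.matrix(reconstructed)
  if (!identical(dim(o), dim(r))) {
    stop(sprintf("shape error: original is %dx%d, reconstructed is %dx%d",
                 nrow(o), ncol(o), nrow(r), ncol(r)), call. = FALSE)
  }
  if (is.null(times)) {
    times <- if (inherits(original, "feature_sequence")) frame_times(original)
             else seq_len(nrow(o)) - 1
  }
  rmse <- sqrt(rowMeans((o - r)^2))
  structure(list(rmse = rmse, times = as.numeric(times),
                 test_speaker_id = test_speaker_id,
                 model_speaker_id = model_speaker_id),
            class = "reconstruction_trace")
}

#' @export
print.reconstruction_trace <- function(x, ...) {
  cat(sprintf("<reconstruction_trace> %d frames: speaker '%s' under '%s'-trained AE\n",
              length(x$rmse), x$test_speaker_id, x$model_speaker_id))
  cat(sprintf("  RMSE mean %.4f, first/last %.4f / %.4f\n",
              mean(x$rmse), x$rmse[1L], x$rmse[length(x$rmse)]))
  invisible(x)
}

# session-normalized time in [0, 1]
normalize_times <- function(times) {
  span <- times[length(times)] - times[1L]
  if (span <= 0) stop("degenerate regression: constant time axis", call. = FALSE)
  (times - times[1L]) / span
}

#' Fit the slope of a reconstruction-error trace
#'
#' The synchrony statistic: the linear trend of the per-frame RMSE trace
#' over *session-normalized* time `t in [0, 1]` (so slopes are comparable
#' across sessions of different length; units are RMSE change over the full
#' session). A negative slope means the tested speaker's frames are
#' reconstructed increasingly well by the partner-trained autoencoder,
#' i.e. the partners are converging.
#'
#' Two estimators are available: `"ols"` (ordinary least squares, the
#' default) and `"mean_first_difference"`, the average of consecutive RMSE
#' differences. The latter telescopes to
#' `(rmse[n] - rmse[1]) / (n - 1)` per frame step for evenly spaced frames
#' and is computed in that closed form (exact, and identical to averaging
#' the first differences); it is rescaled onto the same normalized-time
#' axis as the OLS slope.
#'
#' @param trace A [frame_rmse()] trace, or a numeric vector of RMSE values
#'   (then taken as evenly spaced).
#' @param method `"ols"` or `"mean_first_difference"`.
#' @param smooth_window Optional odd integer; when given, a centered moving
#'   average of that width is applied to the trace before fitting (off by
#'   default; exploratory only).
#' @return A `slope_result`: list with `slope` (per unit normalized time),
#'   `intercept` (OLS only, `NA` otherwise), `method`, `n`, and
#'   `slope_per_step` (the per-frame-step trend).
#' @export
#' @examples
#' tr <- frame_rmse(matrix(0, 4, 1), matrix(c(0, 1, 2, 3), 4, 1))
#' fit_slope(tr)$slope  # 3: RMSE rises by 3 over the session
fit_slope <- function(trace, method = c("ols", "mean_first_difference"),
                      smooth_window = NULL) {
  method <- match.arg(method)
  if (inherits(trace, "reconstruction_trace")) {
    y <- trace$rmse; times <- trace$times
  } else {
    y <- as.numeric(trace); times <- seq_along(y) - 1
  }
  n <- length(y)
  if (n < 2L) stop("insufficient data: slope needs at least 2 frames", call. = FALSE)
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    stopifnot(w >= 1L, w %% 2L == 1L)
    if (w > 1L) {
      y <- stats::filter(y, rep(1 / w, w), sides = 2)
      keep <- !is.na(y)
      y <- as.numeric(y[keep]); times <- times[keep]; n <- length(y)
    }
  }
  t_norm <- normalize_times(times)
  if (method == "ols") {
    fit <- stats::lm.fit(cbind(intercept = 1, t = t_norm), y)
    slope <- unname(fit$coefficients["t"])
    intercept <- unname(fit$coefficients["intercept"])
  } else {
    # telescoped mean first difference, on the normalized axis
    slope <- (y[n] - y[1L]) / (t_norm[n] - t_norm[1L])
    intercept <- NA_real_
  }
  structure(list(slope = slope, intercept = intercept, method = method,
                 n = n, slope_per_step = (y[n] - y[1L]) / (n - 1)),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("<slope_result> %s slope %.5f over normalized session time (n = %d)\n",
              x$method, x$slope, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper around [stats::cor()]: equal-length inputs with
#' nonzero variance, returns the correlation in `[-1, 1]`. Used for the
#' per-group correlation of paired partner slopes.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single correlation value.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("correlation needs at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Cross-partner synchrony analysis of one dyadic session
#'
#' The package's core fit. For a session with speakers A and B it:
#' \enumerate{
#'   \item trains one bottleneck [autoencoder()] per speaker on that
#'     speaker's own frames (frames as independent instances);
#'   \item reconstructs each speaker's frames, *in order*, with the
#'     autoencoder trained on the partner;
#'   \item computes the two per-frame RMSE traces ([frame_rmse()]) and
#'     their linear slopes over normalized session time ([fit_slope()]).
#' }
#' A speaker's reconstruction error under the partner's model measures how
#' far their current frames sit from the partner's feature distribution, so
#' a negative slope indicates growing acoustic similarity (synchrony) and a
#' positive slope divergence.
#'
#' @param session A [dyad_session()].
#' @param config A [training_config()]; both autoencoders share it (the
#'   second uses `seed + 1` so the fits are independent).
#' @param architecture Optional shared architecture; default
#'   [default_architecture()] of the feature dimensionality.
#' @param slope_method Passed to [fit_slope()].
#' @param keep_models Keep the two fitted autoencoders on the object
#'   (default `TRUE`; set `FALSE` to save memory in corpus runs).
#' @return An object of class `dyad_synchrony` with the two traces
#'   (`trace_a` = A tested under B's model, `trace_b` = B under A's), the
#'   two `slope_result`s, speaker/session/group ids and (optionally) the
#'   fitted models. Methods: `print`, `summary`, `coef` (named slope pair),
#'   `plot` (traces with fitted lines), `residuals` (detrended traces).
#' @export
dyad_synchrony <- function(session, config = training_config(),
                           architecture = NULL,
                           slope_method = c("ols", "mean_first_difference"),
                           keep_models = TRUE) {
  stopifnot(inherits(session, "dyad_session"))
  slope_method <- match.arg(slope_method)
  fa <- session$features_a; fb <- session$features_b
  if (nrow(fa) < 2L || nrow(fb) < 2L) {
    stop("empty subsequence: both speakers need at least 2 frames", call. = FALSE)
  }
  if (ncol(fa) != ncol(fb)) {
    stop("shape error: speakers have different feature dimensionality", call. = FALSE)
  }
  if (is.null(architecture)) architecture <- default_architecture(ncol(fa))
  cfg_b <- config
  cfg_b$seed <- config$seed + 1L
  ae_a <- autoencoder(fa, architecture, config)   # trained on A
  ae_b <- autoencoder(fb, architecture, cfg_b)    # trained on B
  # cross-partner testing, frame order preserved
  trace_b <- frame_rmse(fb, predict(ae_a, fb),
                        test_speaker_id = session$speaker_b_id,
                        model_speaker_id = session$speaker_a_id)
  trace_a <- frame_rmse(fa, predict(ae_b, fa),
                        test_speaker_id = session$speaker_a_id,
                        model_speaker_id = session$speaker_b_id)
  structure(list(session_id = session$session_id,
                 group_id = session$group_id,
                 speaker_a_id = session$speaker_a_id,
                 speaker_b_id = session$speaker_b_id,
                 trace_a = trace_a, trace_b = trace_b,
                 slope_a = fit_slope(trace_a, slope_method),
                 slope_b = fit_slope(trace_b, slope_method),
                 slope_method = slope_method,
                 config = config,
                 models = if (keep_models) list(a = ae_a, b = ae_b)),
            class = "dyad_synchrony")
}

#' @export
print.dyad_synchrony <- function(x, ...) {
  cat(sprintf("<dyad_synchrony> session '%s' (group %s)\n", x$session_id, x$group_id))
  cat(sprintf("  slope[%s under %s-AE] = %+.5f\n",
              x$speaker_a_id, x$speaker_b_id, x$slope_a$slope))
  cat(sprintf("  slope[%s under %s-AE] = %+.5f\n",
              x$speaker_b_id, x$speaker_a_id, x$slope_b$slope))
  cat(sprintf("  (%s fit over normalized session time; negative = converging)\n",
              x$slope_method))
  invisible(x)
}

#' @export
coef.dyad_synchrony <- function(object, ...) {
  stats::setNames(c(object$slope_a$slope, object$slope_b$slope),
                  c(object$speaker_a_id, object$speaker_b_id))
}

#' @export
summary.dyad_synchrony <- function(object, ...) {
  s <- coef(object)
  out <- data.frame(session_id = object$session_id,
                    group_id = object$group_id,
                    speaker = names(s),
                    slope = unname(s),
                    intercept = c(object$slope_a$intercept, object$slope_b$intercept),
                    mean_rmse = c(mean(object$trace_a$rmse), mean(object$trace_b$rmse)),
                    n_frames = c(object$slope_a$n, object$slope_b$n),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.dyad_synchrony", "data.frame")
  out
}

#' @export
residuals.dyad_synchrony <- function(object, ...) {
  detrend <- function(trace, slope) {
    t_norm <- normalize_times(trace$times)
    b0 <- if (is.na(slope$intercept)) mean(trace$rmse) - slope$slope * mean(t_norm)
          else slope$intercept
    trace$rmse - (b0 + slope$slope * t_norm)
  }
  list(a = detrend(object$trace_a, object$slope_a),
       b = detrend(object$trace_b, object$slope_b))
}

#' @export
plot.dyad_synchrony <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  panel <- function(trace, slope) {
    t_norm <- normalize_times(trace$times)
    graphics::plot(t_norm, trace$rmse, type = "l", col = "grey50",
                   xlab = "normalized session time", ylab = "frame RMSE",
                   main = sprintf("%s under %s-AE (slope %+.4f)",
                                  trace$test_speaker_id, trace$model_speaker_id,
                                  slope$slope), ...)
    b0 <- if (is.na(slope$intercept)) mean(trace$rmse) - slope$slope * mean(t_norm)
          else slope$intercept
    graphics::abline(b0, slope$slope, col = "red", lwd = 2)
  }
  panel(x$trace_a, x$slope_a)
  panel(x$trace_b, x$slope_b)
  invisible(x)
}

#' Group-level aggregation of paired session slopes
#'
#' For one group of sessions (e.g. a culture), computes the two summary
#' statistics of the synchrony analysis: the *average slope* over all
#' `2 n` individual speakers (overall tendency: negative = the group's
#' dyads converge) and the *Pearson correlation of pairs* — the correlation
#' between partner A's and partner B's slopes across the group's sessions
#' (positive = partners co-vary, both converging or both diverging;
#' negative = one partner dominates).
#'
#' @param group_id Group label.
#' @param slope_pairs Either a list of [dyad_synchrony()] fits or a 2-column
#'   matrix/data.frame of (slope A, slope B) per session.
#' @return A `group_summary`: list with `group_id`, `average_slope`,
#'   `pcc_of_pairs` (`NA` with a warning for a single session), `n_sessions`.
#' @export
#' @examples
#' summarize_group("C1", rbind(c(-0.1, -0.2), c(-0.3, -0.4)))
summarize_group <- function(group_id, slope_pairs) {
  if (is.list(slope_pairs) && !is.data.frame(slope_pairs) &&
      all(vapply(slope_pairs, inherits, NA, "dyad_synchrony"))) {
    slope_pairs <- do.call(rbind, lapply(slope_pairs, coef))
  }
  m <- as.matrix(slope_pairs)
  if (ncol(m) != 2L) stop("slope_pairs must have two columns (A, B)", call. = FALSE)
  if (nrow(m) < 1L) stop("need at least one session", call. = FALSE)
  n_sessions <- nrow(m)
  pcc <- if (n_sessions >= 2L) {
    tryCatch(pearson_correlation(m[, 1L], m[, 2L]),
             error = function(e) { warning(conditionMessage(e)); NA_real_ })
  } else {
    warning("pcc of pairs undefined for a single session")
    NA_real_
  }
  structure(list(group_id = group_id,
                 average_slope = mean(m),
                 pcc_of_pairs = pcc,
                 n_sessions = n_sessions),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: average slope %+.4f, pcc of pairs %s (%d sessions)\n",
              x$group_id, x$average_slope,
              if (is.na(x$pcc_of_pairs)) "--" else sprintf("%+.3f", x$pcc_of_pairs),
              x$n_sessions))
  invisible(x)
}

#' Assemble the per-group synchrony report table
#'
#' Lays out group summaries in the standard report shape: one row per
#' (feature set, statistic), one column per group.
#'
#' @param summaries List of [summarize_group()] results.
#' @param feature_set Feature-set label for the row block.
#' @return `data.frame` with columns `feature_set`, `statistic`, then one
#'   column per group.
#' @export
group_report <- function(summaries, feature_set = "acoustic") {
  stopifnot(length(summaries) >= 1L)
  ids <- vapply(summaries, `[[`, "", "group_id")
  avg <- vapply(summaries, `[[`, 0, "average_slope")
  pcc <- vapply(summaries, function(s) s$pcc_of_pairs, 0)
  out <- data.frame(feature_set = feature_set,
                    statistic = c("average_slope", "pcc_of_pairs"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) out[[ids[i]]] <- c(avg[i], pcc[i])
  out
}
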