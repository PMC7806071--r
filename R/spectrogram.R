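#' Spectrogram configuration
#'
#' Settings for [mel_spectrogram()]. The defaults mirror the Deep-Spectrum
#' style front end: 500 ms Hann analysis window hopped every 10 ms (matching
#' the frame-level descriptor step so the two feature streams stay frame
#' aligned) and 128 triangular mel bands. A literal 10 ms *overlap*
#' (490 ms hop) can be requested instead via `hop_seconds = 0.49`.
#'
#' @param window_seconds Analysis window length in seconds (default 0.5).
#' @param hop_seconds Hop between window starts in seconds (default 0.010).
#' @param n_mel_bands Number of mel filterbank bands (default 128).
#' @param window_function `"hann"` (default) or `"rectangular"`.
#' @return A `spectrogram_config` list.
#' @export
spectrogram_config <- function(window_seconds = 0.5, hop_seconds = 0.010,
                               n_mel_bands = 128L, window_function = "hann") {
  if (!(window_seconds > hop_seconds && hop_seconds > 0)) {
    stop("need window_seconds > hop_seconds > 0", call. = FALSE)
  }
  if (n_mel_bands < 1L) stop("n_mel_bands must be >= 1", call. = FALSE)
  window_function <- match.arg(window_function, c("hann", "rectangular"))
  structure(list(window_seconds = window_seconds, hop_seconds = hop_seconds,
                 n_mel_bands = as.integer(n_mel_bands),
                 window_function = window_function),
            class = "spectrogram_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank over FFT bins (rows: bands, cols: n_fft/2 + 1 bins)
mel_filterbank <- function(n_bands, n_fft, sample_rate, fmin = 0,
                           fmax = sample_rate / 2) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_bands + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (0:(n_fft %/% 2)) * sample_rate / n_fft
  fb <- matrix(0, n_bands, length(bin_freqs))
  for (b in seq_len(n_bands)) {
    lo <- hz_pts[b]; ctr <- hz_pts[b + 1L]; hi <- hz_pts[b + 2L]
    up <- (bin_freqs - lo) / (ctr - lo)
    down <- (hi - bin_freqs) / (hi - ctr)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-mel spectrogram of an audio signal
#'
#' Short-time windowed power spectra mapped onto a triangular mel
#' filterbank, log10-scaled: the spectrogram representation fed to
#' image-CNN embedding back ends. Windows are placed every
#' `cfg$hop_seconds` starting at sample 1; only full windows are used, so
#' the number of rows is `floor((n_samples - window) / hop) + 1`.
#'
#' @param samples Numeric vector of audio samples (single channel).
#' @param sample_rate Sampling rate in Hz.
#' @param cfg A [spectrogram_config()].
#' @param log_floor Power floor before taking `log10` (default `1e-10`),
#'   so silence maps to a finite `log10(log_floor)`.
#' @return Numeric matrix `n_windows x n_mel_bands` of log10 mel power,
#'   with attributes `hop_seconds`, `window_seconds` and `band_centers_hz`.
#' @export
mel_spectrogram <- function(samples, sample_rate, cfg = spectrogram_config(),
                            log_floor = 1e-10) {
  stopifnot(inherits(cfg, "spectrogram_config"))
  samples <- as.numeric(samples)
  win <- round(cfg$window_seconds * sample_rate)
  hop <- round(cfg$hop_seconds * sample_rate)
  if (hop < 1L) stop("hop shorter than one sample", call. = FALSE)
  if (length(samples) < win) {
    stop("insufficient data: signal shorter than one analysis window", call. = FALSE)
  }
  n_windows <- (length(samples) - win) %/% hop + 1L
  w <- switch(cfg$window_function,
              hann = 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1) / (win - 1)),
              rectangular = rep(1, win))
  n_keep <- win %/% 2 + 1L
  fb <- mel_filterbank(cfg$n_mel_bands, win, sample_rate)
  # frame the signal into a win x n_windows matrix, window, FFT columns at once
  idx <- outer(seq_len(win), (seq_len(n_windows) - 1L) * hop, `+`)
  frames <- matrix(samples[idx], nrow = win) * w
  spec <- stats::mvfft(frames)[seq_len(n_keep), , drop = FALSE]
  power <- Mod(spec)^2 / win
  melp <- t(fb %*% power)  # n_windows x n_bands
  out <- log10(pmax(melp, log_floor))
  centers <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                           length.out = cfg$n_mel_bands + 2L))[2:(cfg$n_mel_bands + 1L)]
  structure(out, hop_seconds = cfg$hop_seconds,
            window_seconds = cfg$window_seconds, band_centers_hz = centers)
}

#' Read a single-channel PCM WAV file
#'
#' Minimal RIFF/WAVE reader for mono integer PCM (8/16/32 bit) and 32-bit
#' float audio, sufficient to feed [mel_spectrogram()]. Samples are scaled
#' to `[-1, 1]`.
#'
#' @param path Path to a WAV file.
#' @return List with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little"),
        n_channels = readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little"),
        sample_rate = readBin(con, "integer", 1L, 4L, endian = "little"))
      invisible(readBin(con, "integer", 1L, 4L, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1L, 2L, endian = "little"))  # block align
      fmt$bits <- readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little")
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: missing fmt/data chunk", call. = FALSE)
  if (fmt$n_channels != 1L) stop("only single-channel WAV is supported", call. = FALSE)
  samples <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1L,
                               signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                   signed = TRUE, endian = "little") / 32768,
    "32" = if (fmt$audio_format == 3L) {
             readBin(data_raw, "double", length(data_raw) %/% 4L, 4L, endian = "little")
           } else {
             readBin(data_raw, "integer", length(data_raw) %/% 4L, 4L,
                     endian = "little") / 2147483648
           },
    stop("unsupported WAV bit depth: ", fmt$bits, call. = FALSE))
  list(samples = as.numeric(samples), sample_rate = fmt$sample_rate)
}

#' Define a spectrogram embedding back end
#'
#' Contract for Deep-Spectrum-style feature extractors: a deterministic
#' function mapping a (log-mel) spectrogram excerpt to a fixed-length
#' numeric vector, e.g. the 4096-dim penultimate-layer activations of a
#' pretrained image CNN. No network weights ship with this package;
#' precomputed embedding tables are normally read with
#' [read_feature_table()] instead, and this hook exists so such a model can
#' be plugged in.
#'
#' @param embed Function taking a spectrogram matrix and returning a numeric
#'   vector of length `output_dim`.
#' @param output_dim Declared embedding dimensionality (4096 for the CNN
#'   back end this emulates).
#' @param name Back-end label.
#' @return An `embedding_backend` object; call it on a spectrogram via
#'   [apply_backend()].
#' @export
embedding_backend <- function(embed, output_dim, name = "custom") {
  stopifnot(is.function(embed), output_dim >= 1L)
  structure(list(embed = embed, output_dim = as.integer(output_dim), name = name),
            class = "embedding_backend")
}

#' Apply an embedding back end to a spectrogram
#'
#' @param backend An [embedding_backend()].
#' @param spectrogram Numeric matrix (e.g. from [mel_spectrogram()]).
#' @return Numeric vector of length `backend$output_dim`.
#' @export
apply_backend <- function(backend, spectrogram) {
  stopifnot(inherits(backend, "embedding_backend"))
  out <- backend$embed(spectrogram)
  if (length(out) != backend$output_dim || !is.numeric(out)) {
    stop(sprintf("back end '%s' returned length %d, declared output_dim %d",
                 backend$name, length(out), backend$output_dim), call. = FALSE)
  }
  as.numeric(out)
}
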