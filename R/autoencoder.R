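# run code with a locally seeded RNG, restoring caller state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default bottleneck architecture for a feature dimensionality
#'
#' The symmetric halving rule: each encoder layer halves the previous size
#' down to the bottleneck, the decoder mirrors it back up. The two
#' dimensionalities used for speech features get their canonical shapes:
#' 130-dim acoustic descriptor vectors map to `130-64-32-12-32-64-130` and
#' 4096-dim spectrogram embeddings to `4096-2048-1024-512-1024-2048-4096`.
#' Any other input dimension `d >= 8` uses three encoder layers of sizes
#' `floor(d/2)`, `floor(d/4)`, `floor(d/8)`, mirrored.
#'
#' @param input_dim Feature dimensionality (>= 8).
#' @return Integer vector of layer sizes, input through bottleneck to
#'   output, of class `ae_architecture`.
#' @export
#' @examples
#' default_architecture(130)
#' default_architecture(64)
default_architecture <- function(input_dim) {
  input_dim <- as.integer(input_dim)
  if (input_dim < 8L) {
    stop("input_dim too small: the bottleneck floor(d/8) would be below 1", call. = FALSE)
  }
  sizes <- if (input_dim == 130L) {
    c(130L, 64L, 32L, 12L, 32L, 64L, 130L)
  } else if (input_dim == 4096L) {
    c(4096L, 2048L, 1024L, 512L, 1024L, 2048L, 4096L)
  } else {
    enc <- c(input_dim %/% 2L, input_dim %/% 4L, input_dim %/% 8L)
    c(input_dim, enc, rev(enc)[-1L], input_dim)
  }
  structure(sizes, class = "ae_architecture")
}

validate_architecture <- function(layer_sizes) {
  s <- as.integer(layer_sizes)
  n <- length(s)
  if (n < 3L || n %% 2L == 0L) {
    stop("architecture must have an odd number (>= 3) of layer sizes", call. = FALSE)
  }
  if (!identical(s, rev(s))) stop("architecture must be palindromic", call. = FALSE)
  bott <- (n + 1L) %/% 2L
  if (any(diff(s[1:bott]) >= 0L)) {
    stop("encoder layer sizes must strictly decrease to the bottleneck", call. = FALSE)
  }
  if (s[bott] < 1L) stop("bottleneck must have at least 1 unit", call. = FALSE)
  s
}

#' Training configuration for the bottleneck autoencoder
#'
#' Defaults follow the reference training recipe: minibatches of 256 frames
#' for 512 epochs, Adagrad with learning rate 0.01, mean-squared
#' reconstruction-error loss. Frames are reshuffled every epoch under
#' `seed`; the last partial batch is kept. Test suites and quick runs
#' typically lower `epochs` (64 is plenty for the small architectures).
#'
#' @param batch_size Minibatch size (default 256).
#' @param epochs Training epochs (default 512).
#' @param learning_rate Adagrad learning rate (default 0.01).
#' @param optimizer Only `"adagrad"` is implemented.
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling (default 1).
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 256L, epochs = 512L,
                            learning_rate = 0.01, optimizer = "adagrad",
                            seed = 1L) {
  stopifnot(batch_size >= 1L, epochs >= 1L, learning_rate > 0)
  optimizer <- match.arg(optimizer, "adagrad")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 optimizer = optimizer,
                 loss = "mean_squared_error",
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Fit a bottleneck autoencoder on feature frames
#'
#' Trains a fully connected symmetric bottleneck autoencoder on the rows of
#' `x`, treating every frame as an independent instance. Hidden layers use
#' ReLU activations, the output layer is linear, and training minimizes the
#' mean squared reconstruction error with minibatch Adagrad. Reconstruction
#' error of *unseen* frames under the fit is the package's novelty signal:
#' the further a test frame lies from the training distribution, the worse
#' its reconstruction, which is what the cross-partner synchrony statistic
#' exploits (see [dyad_synchrony()]).
#'
#' Weight initialization is He-normal (`sd = sqrt(2 / fan_in)`), biases
#' zero; initialization and the per-epoch shuffles are drawn from
#' `config$seed`, so runs are exactly reproducible for a fixed config.
#'
#' @param x A [feature_sequence()] or numeric matrix of training frames
#'   (rows = frames).
#' @param architecture Layer sizes from [default_architecture()] (the
#'   default) or any palindromic strictly-narrowing vector whose first size
#'   equals `ncol(x)`.
#' @param config A [training_config()].
#' @return An object of class `autoencoder` with elements `architecture`,
#'   `weights`, `biases`, `loss_curve` (length `epochs`, mean per-element
#'   squared error per epoch), `config`, `init` (initialization label) and
#'   `n_train`. Methods: [predict.autoencoder()], `print`, `plot`,
#'   `residuals`.
#' @export
#' @examples
#' x <- matrix(rnorm(200 * 16), 200, 16)
#' fit <- autoencoder(x, config = training_config(epochs = 8))
#' plot(fit)
autoencoder <- function(x, architecture = default_architecture(ncol(x)),
                        config = training_config()) {
  if (inherits(x, "feature_sequence")) x <- as_matrix(x)
  x <- as.matrix(x)
  stopifnot(inherits(config, "training_config"))
  arch <- validate_architecture(architecture)
  if (nrow(x) < 1L) stop("empty input: no training frames", call. = FALSE)
  if (ncol(x) != arch[1L]) {
    stop(sprintf("shape error: frames have %d dims but architecture expects %d",
                 ncol(x), arch[1L]), call. = FALSE)
  }
  n <- nrow(x)
  L <- length(arch) - 1L
  init <- with_seed(config$seed, {
    weights <- vector("list", L)
    biases <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- arch[l]
      weights[[l]] <- matrix(stats::rnorm(fan_in * arch[l + 1L], sd = sqrt(2 / fan_in)),
                             fan_in, arch[l + 1L])
      biases[[l]] <- rep(0, arch[l + 1L])
    }
    orders <- vapply(seq_len(config$epochs), function(e) sample.int(n),
                     integer(n))
    list(weights = weights, biases = biases, orders = orders)
  })
  fitted <- ae_train_cpp(x, init$weights, init$biases,
                         config$epochs, config$batch_size,
                         config$learning_rate,
                         matrix(init$orders - 1L, nrow = n), 1e-8)
  structure(list(architecture = arch,
                 weights = fitted$weights,
                 biases = lapply(fitted$biases, as.numeric),
                 loss_curve = as.numeric(fitted$loss_curve),
                 config = config,
                 init = "he_normal",
                 activation = "relu_hidden_linear_output",
                 n_train = n),
            class = "autoencoder")
}

#' Reconstruct frames with a fitted autoencoder
#'
#' Runs a forward pass only (no training). Row `i` of the output is the
#' network's reconstruction of row `i` of `newdata`; shape and frame order
#' are preserved, so the result can be compared frame-by-frame with the
#' input via [frame_rmse()].
#'
#' @param object A fitted [autoencoder()].
#' @param newdata A [feature_sequence()] or matrix with `ncol` equal to the
#'   fit's input dimensionality.
#' @param ... Unused.
#' @return Reconstructed frames; a `feature_sequence` when `newdata` was
#'   one, otherwise a matrix.
#' @export
predict.autoencoder <- function(object, newdata, ...) {
  is_fs <- inherits(newdata, "feature_sequence")
  x <- if (is_fs) as_matrix(newdata) else as.matrix(newdata)
  if (ncol(x) != object$architecture[1L]) {
    stop(sprintf("shape error: frames have %d dims but autoencoder expects %d",
                 ncol(x), object$architecture[1L]), call. = FALSE)
  }
  out <- ae_forward_cpp(x, object$weights, object$biases)
  dimnames(out) <- dimnames(x)
  if (is_fs) {
    feature_sequence(out,
                     frame_step = attr(newdata, "frame_step"),
                     start_time = attr(newdata, "start_time"),
                     feature_set = attr(newdata, "feature_set"),
                     times = attr(newdata, "times"))
  } else out
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("<autoencoder> %s\n", paste(x$architecture, collapse = "-")))
  cat(sprintf("  trained on %d frames, %d epochs (batch %d, %s lr %g, seed %d)\n",
              x$n_train, x$config$epochs, x$config$batch_size,
              x$config$optimizer, x$config$learning_rate, x$config$seed))
  cat(sprintf("  final training MSE %.6g (from %.6g)\n",
              x$loss_curve[length(x$loss_curve)], x$loss_curve[1L]))
  invisible(x)
}

#' @export
plot.autoencoder <- function(x, ...) {
  graphics::plot(seq_along(x$loss_curve), x$loss_curve, type = "l",
                 xlab = "epoch", ylab = "training MSE", log = "y",
                 main = paste("autoencoder", paste(x$architecture, collapse = "-")), ...)
  invisible(x)
}

#' @export
residuals.autoencoder <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_sequence")) as_matrix(newdata) else as.matrix(newdata)
  x - as_matrix(predict(object, newdata))
}

#' Save / load a fitted autoencoder
#'
#' The archive is a single JSON file holding the architecture, flattened
#' weights and biases, training configuration, initialization label and
#' loss curve at full double precision; [load_autoencoder()] restores an
#' object that reconstructs identically.
#'
#' @param object A fitted [autoencoder()].
#' @param path Output path (`.json`).
#' @return `save_autoencoder`: `path`, invisibly. `load_autoencoder`: the
#'   restored `autoencoder`.
#' @export
save_autoencoder <- function(object, path) {
  stopifnot(inherits(object, "autoencoder"))
  payload <- list(
    format = "dyadsync_autoencoder_v1",
    architecture = object$architecture,
    weights = lapply(object$weights, function(w) list(dim = dim(w), values = as.numeric(w))),
    biases = object$biases,
    loss_curve = object$loss_curve,
    config = unclass(object$config),
    init = object$init,
    activation = object$activation,
    n_train = object$n_train)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dyadsync_autoencoder_v1")) {
    stop("not a dyadsync autoencoder archive: ", path, call. = FALSE)
  }
  weights <- if (is.data.frame(p$weights)) {  # jsonlite simplifies to a data frame
    lapply(seq_len(nrow(p$weights)), function(i)
      matrix(p$weights$values[[i]], p$weights$dim[[i]][1L], p$weights$dim[[i]][2L]))
  } else {
    lapply(p$weights, function(w) matrix(w$values, w$dim[1L], w$dim[2L]))
  }
  cfg <- do.call(training_config,
                 p$config[c("batch_size", "epochs", "learning_rate", "optimizer", "seed")])
  structure(list(architecture = structure(as.integer(p$architecture),
                                          class = "ae_architecture"),
                 weights = weights,
                 biases = lapply(p$biases, as.numeric),
                 loss_curve = as.numeric(p$loss_curve),
                 config = cfg,
                 init = p$init,
                 activation = p$activation,
                 n_train = as.integer(p$n_train)),
            class = "autoencoder")
}
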