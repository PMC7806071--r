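# shared fixtures: all built in code, sized for speed

# small feature sequence with known values
toy_sequence <- function(values = matrix(c(1, 3, 6, 2, 4, 8), ncol = 2),
                         frame_step = 0.01) {
  feature_sequence(values, frame_step = frame_step)
}

# transcript with alternating 1 s turns over [0, n_turns) seconds
toy_transcript <- function(n_turns = 4, turn_seconds = 1,
                           texts = rep("uh huh", n_turns),
                           session_id = "toy") {
  starts <- (seq_len(n_turns) - 1) * turn_seconds
  transcript(data.frame(speaker_id = rep(c("A", "B"), length.out = n_turns),
                        start = starts, end = starts + turn_seconds,
                        text = texts, stringsAsFactors = FALSE),
             session_id = session_id)
}

# quick generator config: short sessions keep unit tests fast
quick_dyad_config <- function(...) {
  dyad_generator_config(session_seconds = 12, turn_seconds = 2,
                        tokens_per_turn = 8, ...)
}

quick_training <- function(epochs = 16L, seed = 1L) {
  training_config(epochs = epochs, seed = seed)
}

# hand-built linear "autoencoder" computing the identity via a ReLU pair:
# encode x -> (x+, x-), decode (x+, x-) -> x+ - x- = x. Exact for any sign.
identity_autoencoder <- function(d = 3L) {
  W1 <- cbind(diag(d), -diag(d))
  W2 <- rbind(diag(d), -diag(d))
  structure(list(architecture = c(d, 2L * d, d),
                 weights = list(W1, W2),
                 biases = list(rep(0, 2L * d), rep(0, d)),
                 loss_curve = 0, config = training_config(epochs = 1L),
                 init = "hand", activation = "relu_hidden_linear_output",
                 n_train = 0L),
            class = "autoencoder")
}

# brute-force normal-equations slope oracle (independent of fit_slope)
ols_slope_oracle <- function(y, t) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1L], slope = beta[2L])
}

# direct-formula Pearson correlation oracle
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}

# plain-matrix view of a feature_sequence for comparisons
as_matrix_test <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y), dimnames = dimnames(y))
  y
}
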