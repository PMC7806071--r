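test_that("frame_rmse matches hand evaluation", {
  expect_equal(frame_rmse(matrix(c(0, 0), 1, 2), matrix(c(3, 4), 1, 2))$rmse,
               sqrt((9 + 16) / 2))
  expect_equal(frame_rmse(matrix(1), matrix(0))$rmse, 1)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(frame_rmse(x, x)$rmse, rep(0, 5))
  expect_error(frame_rmse(matrix(0, 2, 2), matrix(0, 3, 2)), "shape error")
})

test_that("ols slope matches exact cases and the normal-equations oracle", {
  expect_equal(fit_slope(c(0, 1, 2, 3))$slope, 3)           # exact linear rise
  expect_equal(fit_slope(rep(2, 4))$slope, 0)
  expect_equal(fit_slope(c(3, 1, 2, 0))$slope, -2.4)        # hand-checked
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:1000, 1)
    y <- rnorm(n)
    tms <- sort(runif(n)); tms <- tms + seq(0, 1e-6, length.out = n)  # distinct
    tr <- structure(list(rmse = y, times = tms,
                         test_speaker_id = "x", model_speaker_id = "y"),
                    class = "reconstruction_trace")
    got <- fit_slope(tr)
    t_norm <- (tms - tms[1]) / (tms[n] - tms[1])
    want <- ols_slope_oracle(y, t_norm)
    expect_equal(got$slope, unname(want["slope"]), tolerance = 1e-10)
    expect_equal(got$intercept, unname(want["intercept"]), tolerance = 1e-10)
  }
})

test_that("mean-first-difference slope telescopes exactly for even spacing", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(2:500, 1)
    y <- rnorm(n)
    got <- fit_slope(y, method = "mean_first_difference")
    expect_identical(got$slope_per_step, (y[n] - y[1]) / (n - 1))  # exact
    expect_equal(got$slope_per_step, mean(diff(y)), tolerance = 1e-12)
    expect_equal(got$slope, y[n] - y[1])  # normalized-time axis
  }
  expect_equal(fit_slope(rep(5, 4), method = "mean_first_difference")$slope, 0)
})

test_that("adding a constant shifts the intercept but never the slope", {
  set.seed(9)
  y <- abs(rnorm(50))
  for (c0 in c(-2, 5, 100)) {
    expect_equal(fit_slope(y + c0)$slope, fit_slope(y)$slope, tolerance = 1e-9)
    expect_equal(fit_slope(y + c0)$intercept, fit_slope(y)$intercept + c0,
                 tolerance = 1e-9)
    expect_equal(fit_slope(y + c0, method = "mean_first_difference")$slope,
                 fit_slope(y, method = "mean_first_difference")$slope)
  }
})

test_that("degenerate traces are rejected", {
  expect_error(fit_slope(1), "insufficient")
  tr <- structure(list(rmse = c(1, 2), times = c(3, 3),
                       test_speaker_id = "x", model_speaker_id = "y"),
                  class = "reconstruction_trace")
  expect_error(fit_slope(tr), "degenerate")
})

test_that("pearson_correlation matches the direct formula and validates input", {
  expect_equal(pearson_correlation(1:3, 1:3), 1)
  expect_equal(pearson_correlation(1:3, 3:1), -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               pearson_oracle(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  set.seed(10)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson_correlation(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero variance")
})

test_that("summarize_group averages all individual slopes and correlates pairs", {
  s <- summarize_group("g", rbind(c(-0.1, -0.2), c(-0.3, -0.4)))
  expect_equal(s$average_slope, -0.25)
  expect_equal(s$pcc_of_pairs, 1)
  expect_equal(s$n_sessions, 2L)
  anti <- summarize_group("g", rbind(c(-0.1, 0.1), c(0.1, -0.1)))
  expect_equal(anti$average_slope, 0)
  expect_equal(anti$pcc_of_pairs, -1)
  expect_warning(single <- summarize_group("g", rbind(c(-0.1, -0.2))), "single")
  expect_equal(single$average_slope, -0.15)
  expect_true(is.na(single$pcc_of_pairs))
})

test_that("summarize_group is invariant to session ordering", {
  set.seed(12)
  pairs <- matrix(rnorm(20), 10, 2)
  a <- summarize_group("g", pairs)
  b <- summarize_group("g", pairs[sample(10), ])
  expect_equal(a$average_slope, b$average_slope)
  expect_equal(a$pcc_of_pairs, b$pcc_of_pairs)
})

test_that("dyad_synchrony recovers convergence direction on synthetic dyads", {
  # symmetric convergence: both partners move, so both slopes trend negative
  neg_a <- 0L; neg_b <- 0L
  for (s in 1:6) {
    g <- generate_dyad(dyad_generator_config(kappa = 0.8, symmetric = TRUE,
                                             seed = 20 + s))
    fit <- dyad_synchrony(g$session, quick_training(epochs = 32, seed = s),
                          keep_models = FALSE)
    neg_a <- neg_a + (fit$slope_a$slope < 0)
    neg_b <- neg_b + (fit$slope_b$slope < 0)
  }
  expect_gte(neg_a, 4L)
  expect_gte(neg_b, 4L)
})

test_that("static dyads produce near-zero mean slope", {
  slopes <- c()
  for (s in 1:6) {
    g <- generate_dyad(quick_dyad_config(kappa = 0, seed = 40 + s))
    fit <- dyad_synchrony(g$session, quick_training(seed = s), keep_models = FALSE)
    slopes <- c(slopes, coef(fit))
  }
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 3 * se + 0.02)
})

test_that("dyad_synchrony exposes traces, models and tabular summaries", {
  g <- generate_dyad(quick_dyad_config(kappa = 0.5, seed = 5))
  fit <- dyad_synchrony(g$session, quick_training(epochs = 8))
  expect_s3_class(fit$trace_a, "reconstruction_trace")
  expect_equal(fit$trace_b$test_speaker_id, "B")
  expect_equal(fit$trace_b$model_speaker_id, "A")
  expect_length(fit$trace_b$rmse, nrow(g$session$features_b))
  expect_s3_class(fit$models$a, "autoencoder")
  expect_named(coef(fit), c("A", "B"))
  sm <- summary(fit)
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$n_frames, c(nrow(g$session$features_a), nrow(g$session$features_b)))
  res <- residuals(fit)
  expect_equal(mean(res$a), 0, tolerance = 1e-8)  # OLS residuals center at 0
})

test_that("group_report lays out statistics by group", {
  sums <- list(summarize_group("C1", rbind(c(-0.1, -0.2), c(-0.3, -0.4))),
               summarize_group("C2", rbind(c(0.1, 0.2), c(0.2, 0.3))))
  rep <- group_report(sums, feature_set = "acoustic")
  expect_equal(names(rep), c("feature_set", "statistic", "C1", "C2"))
  expect_equal(rep$C1, c(-0.25, 1))
  expect_equal(rep$statistic, c("average_slope", "pcc_of_pairs"))
})
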