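# brute-force design-matrix oracle: nested loops, no shared code with
# lag_design()
brute_design <- function(data, lag_samps) {
  n <- nrow(data); C <- ncol(data); K <- length(lag_samps)
  Tv <- n - max(lag_samps)
  X <- matrix(0, Tv, C * K)
  for (t in seq_len(Tv)) for (k in seq_len(K)) for (c in seq_len(C))
    X[t, c + (k - 1) * C] <- data[t + lag_samps[k], c]
  X
}

test_that("training equals the closed-form ridge normal equations", {
  set.seed(21)
  tmpl <- make_templates(5, 100, 2)
  lags <- c(0, 0.01, 0.02)           # 0, 1, 2 samples at 100 Hz
  trials <- lapply(1:4, function(i)
    list(seg = cbl_eeg(matrix(rnorm(400), 200, 2), 100),
         label = c("face", "spiral")[1 + i %% 2], offset = 0L))
  lambda <- 0.05
  m <- train_backward_model(trials, tmpl, lags, lambda)
  # oracle: stack brute-force designs, solve (X'X + l I)^{-1} X'Y
  Xs <- lapply(trials, function(tr) brute_design(tr$seg$data, c(0, 1, 2)))
  Ys <- lapply(trials, function(tr) {
    y <- if (tr$label == "face") tmpl$y_face else tmpl$y_spiral
    y[1:nrow(Xs[[1]])]
  })
  X <- do.call(rbind, Xs); Y <- unlist(Ys)
  p <- ncol(X)
  lam_abs <- lambda * sum(diag(crossprod(X))) / p
  w <- solve(crossprod(X) + diag(lam_abs, p), crossprod(X, Y))
  expect_equal(c(m$weights), c(w), tolerance = 1e-8)
  # duplicating every trial leaves the weights unchanged (trace-normalized)
  m2 <- train_backward_model(c(trials, trials), tmpl, lags, lambda)
  expect_equal(m2$weights, m$weights, tolerance = 1e-8)
})

test_that("training rejects unbalanced labels and singular lambda-0 designs", {
  tmpl <- make_templates(5, 100, 2)
  trials <- lapply(1:4, function(i)
    list(seg = cbl_eeg(matrix(rnorm(400), 200, 2), 100), label = "face"))
  expect_error(train_backward_model(trials, tmpl, c(0, 0.01), 0.1),
               class = "cbl_error")
  # exactly collinear channels with lambda = 0 -> advice to regularize
  set.seed(3)
  sing <- lapply(1:4, function(i) {
    a <- rnorm(200)
    list(seg = cbl_eeg(cbind(a, 2 * a), 100),
         label = c("face", "spiral")[1 + i %% 2])
  })
  expect_error(train_backward_model(sing, tmpl, c(0, 0.01), 0),
               class = "cbl_singular")
})

test_that("reconstruction matches the per-sample double-sum oracle", {
  set.seed(31)
  for (rep in 1:20) {
    C <- sample(2:4, 1); K <- sample(1:3, 1); n <- 40
    ls <- sort(sample(0:5, K))
    model <- structure(list(weights = matrix(rnorm(C * K), C, K),
                            lags = ls / 64, lag_samps = as.integer(ls),
                            ridge_lambda = 0, fs = 64, training_meta = NULL),
                       class = "cbl_model")
    seg <- cbl_eeg(matrix(rnorm(n * C), n, C), 64)
    yhat <- reconstruct(model, seg)
    Tv <- n - max(ls)
    oracle <- numeric(Tv)
    for (t in seq_len(Tv)) for (c in seq_len(C)) for (k in seq_len(K))
      oracle[t] <- oracle[t] + model$weights[c, k] * seg$data[t + ls[k], c]
    expect_equal(as.numeric(yhat), oracle, tolerance = 1e-12)
  }
  # degenerate cases
  model0 <- structure(list(weights = matrix(0, 2, 2), lags = c(0, 1 / 64),
                           lag_samps = c(0L, 1L), ridge_lambda = 0, fs = 64,
                           training_meta = NULL), class = "cbl_model")
  seg <- cbl_eeg(matrix(rnorm(20), 10, 2), 64)
  expect_true(all(reconstruct(model0, seg) == 0))
  expect_error(reconstruct(model0, cbl_eeg(matrix(1, 1, 2), 64)),
               class = "cbl_error")
})

test_that("a single zero lag with an indicator weight copies that channel", {
  model <- structure(list(weights = matrix(c(0, 1), 2, 1), lags = 0,
                          lag_samps = 0L, ridge_lambda = 0, fs = 64,
                          training_meta = NULL), class = "cbl_model")
  seg <- cbl_eeg(matrix(rnorm(40), 20, 2), 64)
  expect_equal(as.numeric(reconstruct(model, seg)), seg$data[, 2],
               ignore_attr = TRUE)
})

test_that("window scores match the textbook Pearson correlation", {
  tmpl <- make_templates(1.875, 256, 4)
  model <- structure(list(weights = matrix(c(1, 0), 2, 1), lags = 0,
                          lag_samps = 0L, ridge_lambda = 0, fs = 256,
                          training_meta = NULL), class = "cbl_model")
  # channel 1 carries the face drive exactly
  seg <- cbl_eeg(cbind(tmpl$y_face[1:768], rnorm(768)), 256)
  sc <- score_window(model, seg, tmpl)
  expect_equal(sc$c_face, 1)
  expect_equal(sc$c_spiral, -1)
  # random reconstruction: textbook formula oracle
  set.seed(5)
  seg2 <- cbl_eeg(cbind(rnorm(768), rnorm(768)), 256)
  sc2 <- score_window(model, seg2, tmpl)
  x <- seg2$data[, 1]; y <- tmpl$y_face[1:768]
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(sc2$c_face, r_oracle, tolerance = 1e-12)
  # zero-variance reconstruction is flagged and scored 0
  segz <- cbl_eeg(cbind(rep(1, 768), rnorm(768)), 256)
  expect_message(scz <- score_window(model, segz, tmpl),
                 class = "cbl_degenerate")
  expect_equal(scz$c_face, 0)
  expect_error(score_window(model, cbl_eeg(matrix(1, 100, 2), 256), tmpl),
               class = "cbl_error")
})

test_that("streaming scores window arithmetic and oracle equivalence hold", {
  st <- small_trained()
  trial <- st$trials[[1]]
  stream <- stream_scores(st$model, trial$seg, st$templates,
                          offset = trial$offset)
  # 5 s trial -> 9 pairs with ends 3.00, 3.25, ..., 5.00
  expect_equal(nrow(stream), 9)
  expect_equal(stream$window_end, seq(3, 5, by = 0.25))
  # identical to applying score_window to each trailing 3 s independently
  for (i in c(1, 4, 9)) {
    e <- round(stream$window_end[i] * 256)
    seg_w <- cbl_eeg(trial$seg$data[(e - 767):e, , drop = FALSE], 256)
    sw <- score_window(st$model, seg_w, st$templates,
                       offset = trial$offset + e - 768L)
    expect_equal(stream$c_face[i], sw$c_face, tolerance = 1e-10)
    expect_equal(stream$c_spiral[i], sw$c_spiral, tolerance = 1e-10)
  }
  # Pearson scale invariance: rescaling all channels changes nothing
  seg_scaled <- cbl_eeg(trial$seg$data * 3.7, 256)
  stream2 <- stream_scores(st$model, seg_scaled, st$templates,
                           offset = trial$offset)
  expect_equal(stream2$c_face, stream$c_face, tolerance = 1e-12)
  expect_equal(stream2$c_spiral, stream$c_spiral, tolerance = 1e-12)
})

test_that("decide averages the last 6 pairs and breaks ties to face", {
  s <- fake_stream(rep(0.5, 9), rep(0.1, 9))
  expect_equal(decide(s), "face")
  # only the last n_last pairs matter
  s2 <- fake_stream(c(rep(-0.9, 3), rep(0.2, 6)), c(rep(0.9, 3), rep(0.1, 6)))
  expect_equal(decide(s2), "face")
  expect_message(tie <- decide(fake_stream(rep(0.3, 6), rep(0.3, 6))),
                 class = "cbl_tie")
  expect_equal(tie, "face")
  expect_error(decide(fake_stream(0.1, 0.2)), class = "cbl_error")
  # brute-force mean/argmax oracle on random streams
  set.seed(8)
  for (i in 1:50) {
    cf <- runif(10, -1, 1); cs <- runif(10, -1, 1)
    got <- quietly_cbl(decide(fake_stream(cf, cs)))
    want <- if (mean(tail(cf, 6)) >= mean(tail(cs, 6))) "face" else "spiral"
    expect_equal(got, want)
  }
})

test_that("cross-validated accuracy is perfect without noise, chance on noise", {
  tmpl <- make_templates(1.875, 256, 5)
  gen0 <- eeg_gen_params(n_channels = 8, noise_sd = 1e-6,
                         unattended_gain = 0, attention_strength = NULL,
                         lead_in_s = 1, mixing_seed = 2)
  ts0 <- simulate_training_set(gen0, tmpl, n_trials = 8, seed = 5)
  expect_equal(as.numeric(crossval_accuracy(ts0$trials, ts0$templates)), 1)
  # pure-noise EEG decodes at chance within binomial error
  set.seed(12)
  noise_trials <- lapply(1:60, function(i)
    list(seg = cbl_eeg(matrix(rnorm(1088 * 8), 1088, 8), 256),
         label = c("face", "spiral")[1 + i %% 2], offset = 0L))
  acc <- quietly_cbl(crossval_accuracy(noise_trials, tmpl,
                                       lags = c(0, 0.0625, 0.125)))
  expect_gt(as.numeric(acc), 0.30)
  expect_lt(as.numeric(acc), 0.70)
})

test_that("accuracy is monotone in the attended gain ratio and in SNR", {
  tmpl <- make_templates(1.875, 256, 5)
  ratios <- c(1.05, 1.5, 2.5, 4, 8)
  acc_g <- vapply(ratios, function(r) {
    gen <- eeg_gen_params(n_channels = 8, attended_gain = r,
                          unattended_gain = 1, noise_sd = 18,
                          attention_strength = NULL, lead_in_s = 1,
                          mixing_seed = 6)
    ts <- simulate_training_set(gen, tmpl, n_trials = 10, seed = 31)
    as.numeric(crossval_accuracy(ts$trials, ts$templates))
  }, numeric(1))
  expect_true(all(diff(acc_g) >= 0))
  # SNR monotonicity: accuracy non-decreasing as noise shrinks
  acc_n <- vapply(c(60, 25, 10, 3, 0.5), function(sd) {
    gen <- eeg_gen_params(n_channels = 8, noise_sd = sd,
                          attention_strength = NULL, lead_in_s = 1,
                          mixing_seed = 6)
    ts <- simulate_training_set(gen, tmpl, n_trials = 10, seed = 31)
    as.numeric(crossval_accuracy(ts$trials, ts$templates))
  }, numeric(1))
  expect_true(all(diff(acc_n) >= 0))
})
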