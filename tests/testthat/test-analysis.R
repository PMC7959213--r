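test_that("quartile binning matches an order-statistics oracle", {
  x <- c(10, 20, 30, 40, 50, 60, 70, 80)
  expect_equal(quartile_bin(x), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_message(q1 <- quartile_bin(rep(5, 6)), class = "cbl_degenerate")
  expect_equal(q1, rep(1L, 6))
  expect_error(quartile_bin(c(1, 2, 3)), class = "cbl_error")
  # oracle: for distinct values the bin is determined by the sorted position
  set.seed(6)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    x <- sample(seq_len(1000), n)       # distinct
    got <- quartile_bin(x)
    pos <- match(x, sort(x))
    want <- as.integer(ceiling(4 * pos / n))
    expect_equal(got, want)
  }
})

test_that("confidence split and normalization follow their definitions", {
  expect_equal(confidence_split(1:4), c("Low", "Low", "High", "High"))
  expect_error(confidence_split(5), class = "cbl_error")
  expect_error(confidence_split(0), class = "cbl_error")

  expect_equal(normalize_confidence(c(3, 3, 3)), c(0, 0, 0))
  # 3-trial toy, hand computed
  expect_equal(normalize_confidence(c(1, 2, 4)), c(-4, -1, 5) / 3)
  # per-participant centering
  conf <- c(1, 3, 2, 4)
  part <- c("a", "a", "b", "b")
  out <- normalize_confidence(conf, part)
  expect_equal(out, c(-1, 1, -1, 1))
  expect_equal(as.vector(tapply(out, part, mean)), c(0, 0))
})

toy_records <- function() {
  data.frame(
    participant = rep(c("p1", "p2"), each = 4),
    phase = "main",
    feedback_type = rep(c("informative", "informative", "deceptive",
                          "deceptive"), 2),
    report_requested = TRUE,
    decoded = "face",
    report = c("face", "face", "face", "spiral",
               "face", "spiral", "spiral", "spiral"),
    confidence = c(4, 3, 1, 2, 3, 1, 4, 2),
    ie = c(1, 2, 3, 4, 4, 3, 2, 1),
    consistency = c(5, 6, 7, 8, 8, 7, 6, 5),
    accuracy = c("correct", "correct", "correct", "incorrect",
                 "correct", "incorrect", "incorrect", "incorrect"),
    introspection = c("n/a", "n/a", "genuine", "confabulation",
                      "n/a", "n/a", "confabulation", "confabulation"))
}

test_that("summary tables match hand-tabulated cell fractions", {
  s <- quietly_cbl(summarize_session(toy_records(), n_boot = 50, seed = 1))
  t1 <- s$accuracy_by_feedback
  # p1: informative 2/2, deceptive 1/2; p2: informative 1/2, deceptive 0/2
  expect_equal(t1$mean[t1$feedback_type == "informative"], mean(c(1, 0.5)))
  expect_equal(t1$mean[t1$feedback_type == "deceptive"], mean(c(0.5, 0)))
  expect_equal(sum(t1$n_trials), 8)
  expect_true(all(t1$ci_lo <= t1$mean & t1$mean <= t1$ci_hi))
  # all-correct input: every accuracy cell is 1
  rec2 <- toy_records()
  rec2$accuracy <- "correct"
  s2 <- quietly_cbl(summarize_session(rec2, n_boot = 50, seed = 1))
  expect_true(all(s2$accuracy_by_feedback$mean == 1))
  expect_true(all(s2$accuracy_by_feedback_confidence$mean == 1))
})

test_that("participant-weighted summaries ignore trial order", {
  rec <- toy_records()
  perm <- rec[sample(nrow(rec)), ]
  a <- quietly_cbl(summarize_session(rec, n_boot = 50, seed = 2))
  b <- quietly_cbl(summarize_session(perm, n_boot = 50, seed = 2))
  for (nm in c("accuracy_by_feedback", "accuracy_by_feedback_confidence")) {
    ka <- a[[nm]][do.call(order, a[[nm]][1:2]), "mean"]
    kb <- b[[nm]][do.call(order, b[[nm]][1:2]), "mean"]
    expect_equal(ka, kb)
  }
})

test_that("the IRLS logistic fit matches stats::glm on clean data", {
  set.seed(30)
  n <- 600
  part <- rep(sprintf("p%d", 1:6), each = n / 6)
  ie <- abs(rnorm(n))
  fb <- sample(c("informative", "deceptive"), n, replace = TRUE)
  ie_std <- stats::ave(ie, part, FUN = function(x) (x - mean(x)) / sd(x))
  eta <- 0.4 + 0.8 * ie_std + 0.6 * (fb == "informative")
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  rec <- data.frame(participant = part, feedback_type = fb,
                    report = "face", decoded = "face", ie = ie,
                    accuracy = ifelse(y == 1, "correct", "incorrect"))
  fit <- fit_logistic_accuracy(rec)
  ref <- stats::glm(y ~ ie_std + I(fb == "informative"), family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_false(fit$ridge_used)
  expect_true(fit$converged)
  # parameter recovery within 3 Wald SEs
  expect_lt(abs(fit$coefficients["ie"] - 0.8), 3 * fit$se["ie"])
  expect_lt(abs(fit$coefficients["feedback_informative"] - 0.6),
            3 * fit$se["feedback_informative"])
})

test_that("with constant IE the feedback log-odds equals log(ad/bc)", {
  # balanced 2x2 table: informative 30/10, deceptive 20/20
  mk <- function(fb, acc, n) data.frame(
    participant = rep(c("p1", "p2"), length.out = n), feedback_type = fb,
    report = "face", decoded = "face", ie = 1,
    accuracy = acc)
  rec <- quietly_cbl(rbind(mk("informative", "correct", 30),
                           mk("informative", "incorrect", 10),
                           mk("deceptive", "correct", 20),
                           mk("deceptive", "incorrect", 20)))
  fit <- quietly_cbl(fit_logistic_accuracy(rec))
  # the constant-IE column engages the tiny ridge fallback, which perturbs
  # the feedback coefficient by O(1e-3) around the closed-form odds ratio
  expect_lt(abs(fit$coefficients["feedback_informative"] -
                  log((30 * 20) / (10 * 20))), 0.01)
})

test_that("permuted IE yields a null odds ratio whose CI covers 1", {
  set.seed(31)
  n <- 400
  part <- rep(c("p1", "p2", "p3", "p4"), each = 100)
  fb <- rep(c("informative", "deceptive"), 200)
  y <- rbinom(n, 1, 0.6)
  cover <- vapply(1:100, function(i) {
    rec <- data.frame(participant = part, feedback_type = fb,
                      report = "face", decoded = "face",
                      ie = sample(abs(rnorm(n))),
                      accuracy = ifelse(y == 1, "correct", "incorrect"))
    fit <- fit_logistic_accuracy(rec)
    fit$ci_lo["ie"] <= 1 && 1 <= fit$ci_hi["ie"]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("separation triggers the ridge fallback", {
  rec <- data.frame(participant = rep(c("p1", "p2"), each = 20),
                    feedback_type = rep(c("informative", "deceptive"), 20),
                    report = "face", decoded = "face",
                    ie = c(rep(10, 20), rep(0.1, 20)),
                    accuracy = rep(c("correct", "incorrect"), each = 20))
  expect_message(fit <- fit_logistic_accuracy(rec), class = "cbl_separation")
  expect_true(fit$ridge_used)
  expect_true(all(is.finite(fit$se)))
})
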