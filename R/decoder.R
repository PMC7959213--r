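#' Default decoder lag set
#'
#' Lags in seconds at which future EEG samples enter the backward model
#' (`Y_t` is reconstructed from EEG at `t + tau_k`).  The source of the
#' published decoder's lag set is not printed; 0-500 ms is the conventional
#' span for backward stimulus-reconstruction models and the default spacing
#' (62.5 ms, 9 lags) keeps the 64-channel design tractable.
#'
#' @param max_s largest lag in seconds.
#' @param step_s lag spacing in seconds.
#' @return numeric vector of lags (seconds).
#' @export
default_lags <- function(max_s = 0.5, step_s = 0.0625) seq(0, max_s, by = step_s)

lag_samples <- function(lags, fs) {
  ls <- round(lags * fs)
  if (is.unsorted(ls, strictly = TRUE)) cbl_stop("lags must be strictly increasing")
  as.integer(ls)
}

# valid stimulus-time range for a segment of length n with given lags
.valid_range <- function(n, ls) {
  t0 <- 1L + max(0L, -min(ls))
  t1 <- n - max(0L, max(ls))
  if (t1 < t0) cbl_stop("segment (%d samples) shorter than lag span", n)
  c(t0, t1)
}

# lagged design matrix: rows = valid stimulus times, columns = channel
# (fastest) within lag blocks, matching c(weights[C, K])
lag_design <- function(data, ls) {
  n <- nrow(data); C <- ncol(data); K <- length(ls)
  v <- .valid_range(n, ls)
  Tv <- v[2] - v[1] + 1L
  X <- matrix(0, Tv, C * K)
  for (k in seq_len(K)) {
    rows <- (v[1] + ls[k]):(v[2] + ls[k])
    X[, ((k - 1L) * C + 1L):(k * C)] <- data[rows, , drop = FALSE]
  }
  X
}

#' Train the backward stimulus-reconstruction model
#'
#' Solves the ridge-regularized least-squares regression of the attended
#' template on lagged multichannel EEG, pooling all training trials: face
#' trials regress on the face drive, spiral trials on the spiral drive.
#' The effective penalty is `ridge_lambda * trace(X'X) / p` (trace
#' normalization), so weights are invariant to duplicating trials.
#'
#' @param trials list of trials, each a list with elements `seg` (a
#'   processed [cbl_eeg()] at the model rate), `label` (`"face"` or
#'   `"spiral"`), and optional `offset` (template sample offset of the
#'   segment start, default 0, for segments cut from continuous
#'   stimulation).
#' @param templates a [make_templates()] object at the model rate.
#' @param lags lag set in seconds (default [default_lags()]).
#' @param ridge_lambda relative ridge penalty (>= 0; 0 requests plain least
#'   squares and errors if the design is singular).
#' @return object of class `cbl_model` with fields `weights`
#'   (channel x lag), `lags`, `ridge_lambda`, `fs`, `training_meta`.
#' @export
train_backward_model <- function(trials, templates, lags = default_lags(),
                                 ridge_lambda = 0.01) {
  stopifnot(inherits(templates, "cbl_templates"))
  labels <- vapply(trials, `[[`, "", "label")
  if (!all(labels %in% c("face", "spiral"))) cbl_stop("labels must be face/spiral")
  if (any(table(factor(labels, c("face", "spiral"))) < 2))
    cbl_stop("need at least 2 trials per label")
  if (ridge_lambda < 0) cbl_stop("ridge_lambda must be >= 0")
  fs <- templates$fs
  ls <- lag_samples(lags, fs)
  stats <- lapply(trials, .trial_design_stats, templates = templates, ls = ls)
  G <- Reduce(`+`, lapply(stats, `[[`, "G"))
  b <- Reduce(`+`, lapply(stats, `[[`, "b"))
  .solve_model(G, b, ridge_lambda, ls, lags, fs,
               n_channels = ncol(trials[[1]]$seg$data),
               meta = list(n_trials = length(trials),
                           n_face = sum(labels == "face"),
                           n_spiral = sum(labels == "spiral")))
}

.trial_design_stats <- function(trial, templates, ls) {
  seg <- trial$seg
  if (abs(seg$fs - templates$fs) > 1e-9)
    cbl_stop("trial at %g Hz but templates at %g Hz", seg$fs, templates$fs)
  off <- trial$offset %||% 0L
  X <- lag_design(seg$data, ls)
  v <- .valid_range(nrow(seg$data), ls)
  y_full <- if (trial$label == "face") templates$y_face else templates$y_spiral
  idx <- off + (v[1]:v[2])
  if (max(idx) > length(y_full))
    cbl_stop("templates too short for trial (need %d samples)", max(idx))
  y <- y_full[idx]
  list(G = crossprod(X), b = crossprod(X, y))
}

.solve_model <- function(G, b, ridge_lambda, ls, lags, fs, n_channels, meta) {
  p <- nrow(G)
  lam_abs <- ridge_lambda * sum(diag(G)) / p
  ch <- tryCatch(chol(G + diag(lam_abs, p)), error = function(e) NULL)
  if (is.null(ch)) {
    if (ridge_lambda == 0)
      cbl_stop("singular design with ridge_lambda = 0; use ridge_lambda > 0",
               class = "cbl_singular")
    cbl_stop("design factorization failed (lambda = %g)", ridge_lambda)
  }
  w <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  structure(list(weights = matrix(w, n_channels, length(ls)),
                 lags = lags, lag_samps = ls, ridge_lambda = ridge_lambda,
                 fs = fs, training_meta = meta), class = "cbl_model")
}

#' @export
print.cbl_model <- function(x, ...) {
  cat(sprintf("<cbl_model> %d channels x %d lags (0-%g ms), lambda = %g, fs = %g Hz\n",
              nrow(x$weights), ncol(x$weights), 1000 * max(x$lags),
              x$ridge_lambda, x$fs))
  invisible(x)
}

#' Reconstruct the attended 1-D stimulus signal
#'
#' Applies the backward model: `Yhat_t = sum_{c,k} w_ck R_{t + tau_k, c}`.
#' Only stimulus times for which every lagged sample exists are returned (no
#' zero padding beyond segment ends); the attribute `t_start` gives the
#' stimulus-time sample index of the first output value.
#'
#' @param model a [train_backward_model()] model.
#' @param seg processed [cbl_eeg()] at the model sampling rate.
#' @return numeric vector of reconstructed samples with attribute `t_start`.
#' @export
reconstruct <- function(model, seg) {
  stopifnot(inherits(model, "cbl_model"), inherits(seg, "cbl_eeg"))
  if (abs(seg$fs - model$fs) > 1e-9)
    cbl_stop("segment at %g Hz but model at %g Hz", seg$fs, model$fs)
  if (ncol(seg$data) != nrow(model$weights))
    cbl_stop("segment has %d channels but model expects %d",
             ncol(seg$data), nrow(model$weights))
  ls <- model$lag_samps
  v <- .valid_range(nrow(seg$data), ls)
  yhat <- numeric(v[2] - v[1] + 1L)
  for (k in seq_along(ls)) {
    rows <- (v[1] + ls[k]):(v[2] + ls[k])
    yhat <- yhat + drop(seg$data[rows, , drop = FALSE] %*% model$weights[, k])
  }
  attr(yhat, "t_start") <- v[1]
  yhat
}

#' Correlation scores for one analysis window
#'
#' Pearson correlations between the reconstructed signal of an exactly
#' window-length EEG segment and the face/spiral templates over the same
#' stimulus times.  A zero-variance reconstruction is logged and both scores
#' are defined as 0.
#'
#' @param model a backward model.
#' @param seg_3s processed segment of exactly `window_s` seconds.
#' @param templates templates at the model rate covering the window.
#' @param offset template sample offset of the segment start (default 0).
#' @param window_s window length in seconds (default 3).
#' @return list with `c_face`, `c_spiral`.
#' @export
score_window <- function(model, seg_3s, templates, offset = 0L, window_s = 3) {
  win_n <- round(window_s * model$fs)
  if (nrow(seg_3s$data) != win_n)
    cbl_stop("segment must be exactly %g s (%d samples), got %d",
             window_s, win_n, nrow(seg_3s$data))
  yhat <- reconstruct(model, seg_3s)
  t0 <- attr(yhat, "t_start")
  idx <- offset + (t0:(t0 + length(yhat) - 1L))
  if (sd(yhat) < 1e-14) {
    cbl_log("zero-variance reconstruction; scores set to 0",
            class = "cbl_degenerate")
    return(list(c_face = 0, c_spiral = 0))
  }
  list(c_face = cor(yhat, templates$y_face[idx]),
       c_spiral = cor(yhat, templates$y_spiral[idx]))
}

#' Stream correlation scores over a trial
#'
#' Emits one `(c_face, c_spiral)` pair per `hop` (default 250 ms), each
#' computed over the trailing `window` (default 3 s), exactly as the online
#' decoder does.  The full-trial reconstruction is computed once and
#' windowed, which is numerically identical to scoring each window
#' independently.
#'
#' @param model a backward model.
#' @param trial_seg processed trial segment (>= `window` seconds).
#' @param templates templates at the model rate covering the trial.
#' @param hop,window hop and window sizes in seconds.
#' @param offset template sample offset of the segment start.
#' @return data.frame of class `cbl_scorestream` with columns `window_end`
#'   (seconds from segment start), `c_face`, `c_spiral`.
#' @export
stream_scores <- function(model, trial_seg, templates, hop = 0.25, window = 3,
                          offset = 0L) {
  fs <- model$fs
  win_n <- round(window * fs); hop_n <- round(hop * fs)
  n <- nrow(trial_seg$data)
  if (n < win_n) cbl_stop("trial shorter than one window")
  yhat <- reconstruct(model, trial_seg)
  t0f <- attr(yhat, "t_start")
  ls <- model$lag_samps
  tail_cut <- max(0L, max(ls))
  head_cut <- max(0L, -min(ls))
  ends <- seq(win_n, n, by = hop_n)
  cf <- cs <- numeric(length(ends))
  zero_var <- FALSE
  for (i in seq_along(ends)) {
    e <- ends[i]
    ts <- (e - win_n + 1L + head_cut):(e - tail_cut)    # stimulus times
    yh <- yhat[ts - t0f + 1L]
    if (sd(yh) < 1e-14) {
      zero_var <- TRUE
      cf[i] <- 0; cs[i] <- 0
    } else {
      idx <- offset + ts
      cf[i] <- cor(yh, templates$y_face[idx])
      cs[i] <- cor(yh, templates$y_spiral[idx])
    }
  }
  if (zero_var) cbl_log("zero-variance reconstruction; scores set to 0",
                        class = "cbl_degenerate")
  structure(data.frame(window_end = ends / fs, c_face = cf, c_spiral = cs),
            class = c("cbl_scorestream", "data.frame"),
            hop = hop, window = window, fs = fs)
}

#' Decode the attended item from a score stream
#'
#' Averages the face and spiral correlation scores over the last `n_last`
#' pairs (default 6, i.e. the last 1.5 s at a 250 ms hop) and returns the
#' category with the higher mean.  An exact tie resolves to face and is
#' logged.
#'
#' @param stream a [stream_scores()] data.frame.
#' @param n_last number of trailing score pairs to average (default 6).
#' @return `"face"` or `"spiral"`.
#' @export
decide <- function(stream, n_last = 6) {
  if (nrow(stream) < n_last)
    cbl_stop("stream has %d pairs but n_last = %d", nrow(stream), n_last)
  idx <- (nrow(stream) - n_last + 1L):nrow(stream)
  mf <- mean(stream$c_face[idx]); ms <- mean(stream$c_spiral[idx])
  if (mf == ms) {
    cbl_log("decision tie; resolved to face", class = "cbl_tie")
    return("face")
  }
  if (mf > ms) "face" else "spiral"
}

#' Cross-validated decoding accuracy
#'
#' Leave-one-trial-out (default) accuracy of the full decoding chain
#' ([stream_scores()] + [decide()]) on held-out trials.  Per-trial Gram
#' matrices are cached so each fold is a rank-update solve rather than a
#' refit.  When `ridge_grid` has several values, the penalty for each outer
#' fold is chosen by inner leave-one-out accuracy on the remaining trials.
#'
#' @inheritParams train_backward_model
#' @param ridge_grid candidate relative ridge penalties (default the frozen
#'   single value used throughout the package).
#' @param folds `"loo"` (leave-one-trial-out) or an integer number of folds.
#' @param n_last passed to [decide()].
#' @return accuracy fraction in \[0, 1\], with attributes `correct`
#'   (per-trial logical) and `lambda` (penalty chosen per fold).
#' @export
crossval_accuracy <- function(trials, templates, lags = default_lags(),
                              ridge_grid = 0.01, folds = "loo", n_last = 6) {
  fs <- templates$fs
  ls <- lag_samples(lags, fs)
  n <- length(trials)
  stats <- lapply(trials, .trial_design_stats, templates = templates, ls = ls)
  G <- Reduce(`+`, lapply(stats, `[[`, "G"))
  b <- Reduce(`+`, lapply(stats, `[[`, "b"))
  C <- ncol(trials[[1]]$seg$data)
  fold_of <- if (identical(folds, "loo")) seq_len(n) else {
    k <- as.integer(folds)
    if (k < 2 || k > n) cbl_stop("folds must be 'loo' or in [2, n]")
    lab <- vapply(trials, `[[`, "", "label")
    fo <- integer(n)
    for (g in unique(lab)) fo[lab == g] <- rep_len(seq_len(k), sum(lab == g))
    fo
  }
  correct <- logical(n)
  lam_used <- numeric(n)
  for (f in unique(fold_of)) {
    hold <- which(fold_of == f)
    Gf <- G - Reduce(`+`, lapply(stats[hold], `[[`, "G"))
    bf <- b - Reduce(`+`, lapply(stats[hold], `[[`, "b"))
    lam <- if (length(ridge_grid) > 1)
      .inner_select(stats, setdiff(seq_len(n), hold), Gf, bf, ridge_grid,
                    trials, templates, ls, lags, fs, C, n_last)
    else ridge_grid
    model <- .solve_model(Gf, bf, lam, ls, lags, fs, C, meta = list(fold = f))
    for (i in hold) {
      st <- stream_scores(model, trials[[i]]$seg, templates,
                          offset = trials[[i]]$offset %||% 0L)
      correct[i] <- decide(st, n_last) == trials[[i]]$label
      lam_used[i] <- lam
    }
  }
  structure(mean(correct), correct = correct, lambda = lam_used)
}

.inner_select <- function(stats, train_idx, Gf, bf, grid, trials, templates,
                          ls, lags, fs, C, n_last) {
  acc <- vapply(grid, function(lam) {
    ok <- vapply(train_idx, function(j) {
      Gi <- Gf - stats[[j]]$G; bi <- bf - stats[[j]]$b
      m <- .solve_model(Gi, bi, lam, ls, lags, fs, C, meta = NULL)
      st <- stream_scores(m, trials[[j]]$seg, templates,
                          offset = trials[[j]]$offset %||% 0L)
      decide(st, n_last) == trials[[j]]$label
    }, logical(1))
    mean(ok)
  }, numeric(1))
  grid[which.max(acc)]
}
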