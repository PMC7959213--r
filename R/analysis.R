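#' Within-participant quartile bins
#'
#' Empirical-percentile quartiles (1-4) of a participant's values; ties are
#' broken by stable (first-occurrence) rank order.  If all values are equal
#' the binning is degenerate: everything goes to quartile 1 and a warning is
#' logged.
#'
#' @param values numeric vector (>= 4 values).
#' @return integer vector of quartile labels 1-4.
#' @export
quartile_bin <- function(values) {
  n <- length(values)
  if (n < 4) cbl_stop("need at least 4 values per participant")
  if (length(unique(values)) == 1) {
    cbl_log("all values equal; every trial assigned quartile 1",
            class = "cbl_degenerate")
    return(rep(1L, n))
  }
  r <- rank(values, ties.method = "first")
  as.integer(ceiling(4 * r / n))
}

#' Median split of confidence ratings
#'
#' Confidence 1-2 is `"Low"`, 3-4 is `"High"`.
#'
#' @param confidence integer vector in 1-4.
#' @return character vector `"Low"`/`"High"`.
#' @export
confidence_split <- function(confidence) {
  if (!all(confidence %in% 1:4))
    cbl_stop("confidence must be in 1..4")
  ifelse(confidence <= 2, "Low", "High")
}

#' Participant-mean-centered confidence
#'
#' @param confidence numeric ratings.
#' @param participant participant id per rating (default: one participant).
#' @return centered values (mean 0 within each participant).
#' @export
normalize_confidence <- function(confidence, participant = NULL) {
  if (is.null(participant)) participant <- rep(1L, length(confidence))
  stats::ave(confidence, participant, FUN = function(x) x - mean(x))
}

.reported <- function(records) {
  if (is.null(records$participant)) records$participant <- "p1"
  records[!is.na(records$report), , drop = FALSE]
}

.acc <- function(x) mean(x == "correct")

# across-participant mean + percentile bootstrap CI (resample participants)
.boot_ci <- function(per_participant_values, n_boot, seed, level = 0.95) {
  v <- per_participant_values[is.finite(per_participant_values)]
  k <- length(v)
  if (k == 0) return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bm <- colMeans(matrix(v[sample.int(k, k * n_boot, replace = TRUE)], nrow = k))
  a <- (1 - level) / 2
  c(mean = mean(v), lo = unname(quantile(bm, a)), hi = unname(quantile(bm, 1 - a)))
}

.cell_table <- function(df, keys, value, n_boot, seed, level) {
  per <- aggregate(df[[value]], by = df[c("participant", keys)],
                   FUN = function(x) mean(x))
  cells <- unique(per[keys])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(per))
    for (k in keys) sel <- sel & per[[k]] == cells[i, k]
    ci <- .boot_ci(per$x[sel], n_boot, derive_seed(seed, "cell", i), level)
    cnt <- rep(TRUE, nrow(df))
    for (k in keys) cnt <- cnt & df[[k]] == cells[i, k]
    cbind(cells[i, , drop = FALSE],
          data.frame(mean = ci["mean"], ci_lo = ci["lo"], ci_hi = ci["hi"],
                     n_participants = sum(sel), n_trials = sum(cnt)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary tables of a simulated experiment
#'
#' Reproduces the headline descriptive analyses over the reported trials:
#' participant-level means first, then across-participant means with
#' percentile bootstrap confidence intervals (participants resampled with
#' replacement, 1000 iterations by default).  Four tables are produced:
#' accuracy by feedback type; accuracy by feedback type and confidence
#' median split; accuracy by within-participant internal-evidence quartile;
#' and (deceptive trials only) participant-z-scored consistency by
#' introspection outcome and confidence split.
#'
#' @param records trial records from [run_session()], optionally stacked
#'   over participants with a `participant` column.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param level CI level (default 0.95).
#' @return list of class `cbl_summary` with elements
#'   `accuracy_by_feedback`, `accuracy_by_feedback_confidence`,
#'   `accuracy_by_ie_quartile`, `consistency_by_outcome_confidence`.
#' @export
summarize_session <- function(records, n_boot = 1000, seed = 1L, level = 0.95) {
  df <- .reported(records)
  if (nrow(df) == 0) cbl_stop("records contain no reports")
  df$correct <- as.numeric(df$accuracy == "correct")
  df$conf_split <- confidence_split(df$confidence)
  df$ie_quartile <- stats::ave(df$ie, df$participant, FUN = quartile_bin)
  df$cons_z <- stats::ave(df$consistency, df$participant,
                          FUN = function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
  t1 <- .cell_table(df, "feedback_type", "correct", n_boot,
                    derive_seed(seed, "t1"), level)
  t2 <- .cell_table(df, c("feedback_type", "conf_split"), "correct", n_boot,
                    derive_seed(seed, "t2"), level)
  t3 <- .cell_table(df, "ie_quartile", "correct", n_boot,
                    derive_seed(seed, "t3"), level)
  dec <- df[df$feedback_type == "deceptive", , drop = FALSE]
  t4 <- if (nrow(dec) > 0)
    .cell_table(dec, c("introspection", "conf_split"), "cons_z", n_boot,
                derive_seed(seed, "t4"), level)
  else NULL
  structure(list(accuracy_by_feedback = t1,
                 accuracy_by_feedback_confidence = t2,
                 accuracy_by_ie_quartile = t3,
                 consistency_by_outcome_confidence = t4),
            class = "cbl_summary")
}

#' @export
print.cbl_summary <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]], digits = 3)
    cat("\n")
  }
  invisible(x)
}
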