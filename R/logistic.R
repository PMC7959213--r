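#' Fixed-effects logistic regression of report accuracy
#'
#' Models the probability of a correct report from the internal evidence
#' (standardized within participant) and the feedback type (informative
#' coded 1, deceptive 0), fitted by iteratively reweighted least squares
#' (tolerance 1e-8, at most 100 iterations).  If separation is detected
#' (diverging coefficients or a failed factorization) a small ridge penalty
#' is added to the IRLS normal equations and the fit is flagged.  This is
#' the package's fixed-effects stand-in for the mixed-effects models of the
#' original analysis; the tidy records let users refit mixed models
#' externally.
#'
#' @param records trial records with reports (see [run_session()]); control
#'   trials (no feedback) are excluded.
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter maximum IRLS iterations.
#' @return list of class `cbl_logit`: `coefficients`, `se`, `odds_ratio`,
#'   `ci_lo`, `ci_hi` (Wald, 95%), `converged`, `ridge_used`, `n`,
#'   `iterations`.
#' @export
fit_logistic_accuracy <- function(records, tol = 1e-8, max_iter = 100) {
  df <- .reported(records)
  df <- df[df$feedback_type %in% c("informative", "deceptive"), , drop = FALSE]
  if (length(unique(df$participant)) < 2)
    cbl_stop("need at least 2 participants")
  if (length(unique(df$feedback_type)) < 2)
    cbl_stop("need both feedback types")
  ie_std <- stats::ave(df$ie, df$participant,
                       FUN = function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
  X <- cbind(intercept = 1, ie = ie_std,
             feedback_informative = as.numeric(df$feedback_type == "informative"))
  y <- as.numeric(df$accuracy == "correct")
  fit <- .irls_logit(X, y, tol, max_iter, ridge = 0)
  if (!fit$ok) {
    cbl_log("separation suspected; refitting with ridge penalty",
            class = "cbl_separation")
    fit <- .irls_logit(X, y, tol, max_iter, ridge = 1e-4 * nrow(X))
    fit$ridge_used <- TRUE
  }
  beta <- fit$beta; se <- fit$se
  zc <- qnorm(0.975)
  structure(list(coefficients = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 odds_ratio = setNames(exp(beta), colnames(X)),
                 ci_lo = setNames(exp(beta - zc * se), colnames(X)),
                 ci_hi = setNames(exp(beta + zc * se), colnames(X)),
                 converged = fit$converged, ridge_used = isTRUE(fit$ridge_used),
                 n = nrow(X), iterations = fit$iter),
            class = "cbl_logit")
}

.irls_logit <- function(X, y, tol, max_iter, ridge = 0) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(ridge, p); pen[1, 1] <- 0   # never penalize the intercept
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(list(ok = FALSE))
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  if (max(abs(beta)) > 15) return(list(ok = FALSE))
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  H <- crossprod(X, X * (mu * (1 - mu))) + pen
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov)) return(list(ok = FALSE))
  list(ok = TRUE, beta = beta, se = sqrt(diag(cov)), converged = converged,
       iter = iter)
}

#' @export
print.cbl_logit <- function(x, ...) {
  cat(sprintf("<cbl_logit> n = %d, converged = %s%s\n", x$n, x$converged,
              if (x$ridge_used) " (ridge fallback)" else ""))
  print(data.frame(coef = x$coefficients, se = x$se, OR = x$odds_ratio,
                   ci_lo = x$ci_lo, ci_hi = x$ci_hi), digits = 3)
  invisible(x)
}
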