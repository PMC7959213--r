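#' Derive a reproducible integer seed from a base seed and tags
#'
#' Every random stage of the pipeline draws its seed deterministically from
#' one global seed plus a stage tag, so that a single `--seed` reproduces the
#' whole run.  The hash stays below 2^31 - 1 and is exact in double
#' arithmetic.
#'
#' @param seed integer base seed.
#' @param ... further integer or character tags (stage names, trial indices).
#' @return a positive integer seed.
#' @export
#' @examples
#' derive_seed(42, "session", 3)
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else as.numeric(x)
  })))
  h <- 104729
  for (p in parts) {
    h <- (h * 69069 + (as.numeric(p) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Signalled (not printed) log events: conditions with class cbl_log so tests
# and callers can muffle or record them.
cbl_log <- function(..., class = "cbl_log") {
  message(structure(
    class = c(class, "cbl_log", "message", "condition"),
    list(message = paste0("[cbloop] ", sprintf(...), "\n"), call = NULL)
  ))
}

cbl_stop <- function(..., class = "cbl_error") {
  stop(structure(
    class = c(class, "cbl_error", "error", "condition"),
    list(message = sprintf(...), call = sys.call(-1))
  ))
}

is_count <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
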