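#' Write an EEG segment to a flat binary container with JSON sidecar
#'
#' The container is raw little-endian float64, column-major (all samples of
#' channel 1, then channel 2, ...), with a `<path>.json` sidecar holding the
#' sampling rate, dimensions and channel names.
#'
#' @param seg a [cbl_eeg()] segment.
#' @param path output path for the binary payload.
#' @return invisibly, `path`.
#' @export
write_eeg <- function(seg, path) {
  stopifnot(inherits(seg, "cbl_eeg"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(seg$data), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(fs = seg$fs, n_samples = nrow(seg$data), n_channels = ncol(seg$data),
         channel_names = colnames(seg$data), dtype = "float64",
         order = "column-major"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EEG segment written by [write_eeg()]
#'
#' @param path path to the binary payload (sidecar `<path>.json` required).
#' @return a [cbl_eeg()] segment.
#' @export
read_eeg <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n_samples * meta$n_channels,
               size = 8, endian = "little")
  cbl_eeg(matrix(x, meta$n_samples, meta$n_channels), meta$fs,
          meta$channel_names)
}

#' Serialize a backward model to JSON
#'
#' Weights are stored row-major (channel rows, lag columns) together with
#' the lag set, penalty and sampling rate, so the file is auditable and
#' re-loadable anywhere.
#'
#' @param model a [train_backward_model()] model.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "cbl_model"))
  jsonlite::write_json(
    list(lags_s = model$lags, ridge_lambda = model$ridge_lambda, fs = model$fs,
         n_channels = nrow(model$weights), n_lags = ncol(model$weights),
         weights_row_major = as.vector(t(model$weights)),
         training_meta = model$training_meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a backward model written by [write_model_json()]
#' @param path JSON path.
#' @return a `cbl_model`.
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = matrix(m$weights_row_major, m$n_channels,
                                  m$n_lags, byrow = TRUE),
                 lags = m$lags_s, lag_samps = lag_samples(m$lags_s, m$fs),
                 ridge_lambda = m$ridge_lambda, fs = m$fs,
                 training_meta = m$training_meta),
            class = "cbl_model")
}
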