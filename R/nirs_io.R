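#' Write / read an fNIRS recording as CSV plus JSON event sidecar
#'
#' The CSV holds a `time` column (seconds) followed by one column per
#' channel; the sidecar (`<path>.events.json`) stores the chromophore,
#' sampling rate, subject id and the block-event schedule.
#'
#' @param recording An `nirs_recording`.
#' @param path CSV output path.
#' @return `write_nirs_recording()` returns `path` invisibly;
#'   `read_nirs_recording()` returns an `nirs_recording`.
#' @export
write_nirs_recording <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  n <- ncol(recording$data)
  df <- data.frame(time = (seq_len(n) - 1) / recording$sampling_rate,
                   t(recording$data), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(subject_id = recording$subject_id,
                  chromophore = recording$chromophore,
                  sampling_rate = recording$sampling_rate,
                  events = as.data.frame(recording$events))
  jsonlite::write_json(sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nirs_recording
#' @export
read_nirs_recording <- function(path) {
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ev <- as.data.frame(side$events)
  class(ev) <- c("block_schedule", "data.frame")
  df <- utils::read.csv(path, check.names = FALSE)
  data <- t(as.matrix(df[, setdiff(names(df), "time"), drop = FALSE]))
  nirs_recording(side$subject_id, side$chromophore, data,
                 side$sampling_rate, ev)
}

sidecar_path <- function(path) sub("\\.csv$", "", path) |> paste0(".events.json")
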