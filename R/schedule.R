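#' The standard N-back block stimulation schedule
#'
#' Builds the fixed 13-segment block schedule of the visuospatial N-back
#' working-memory protocol: rest-C-1B-2B-rest-1B-C-2B-rest-2B-1B-C-rest.
#' The first rest lasts 60 s, the remaining rests 30 s. Every task block
#' opens with an instruction screen (2 s for the control task C, 3 s for
#' 1-back and 2-back) followed by 32 stimuli of 0.5 s separated by 1.5 s
#' interstimulus intervals, i.e. a 64 s stimulation period.
#'
#' @return A data.frame of class `block_schedule` with one row per segment
#'   and columns:
#'   \describe{
#'     \item{condition}{`"rest"`, `"C"`, `"1B"` or `"2B"`.}
#'     \item{onset}{segment onset in seconds from the start of recording.}
#'     \item{duration}{segment duration in seconds (instruction included
#'       for task blocks).}
#'     \item{instruction}{instruction-screen duration in seconds (0 for rest).}
#'     \item{stim_onset}{onset of the first stimulus (`onset + instruction`;
#'       `NA` for rest).}
#'     \item{stim_duration}{duration of the stimulation period (64 s for
#'       task blocks, `NA` for rest).}
#'   }
#' @examples
#' sched <- make_schedule()
#' sum(sched$condition != "rest")     # 9 task blocks
#' schedule_duration(sched)           # 750 s
#' @export
make_schedule <- function() {
  order <- c("rest", "C", "1B", "2B", "rest", "1B", "C", "2B",
             "rest", "2B", "1B", "C", "rest")
  n_stim <- 32L
  stim_dur <- n_stim * (0.5 + 1.5)   # 64 s of stimulation per task block
  instr <- c(rest = 0, C = 2, `1B` = 3, `2B` = 3)

  duration <- numeric(length(order))
  first_rest_seen <- FALSE
  for (i in seq_along(order)) {
    if (order[i] == "rest") {
      duration[i] <- if (!first_rest_seen) 60 else 30
      first_rest_seen <- TRUE
    } else {
      duration[i] <- instr[[order[i]]] + stim_dur
    }
  }
  onset <- cumsum(c(0, duration[-length(duration)]))
  is_task <- order != "rest"
  sched <- data.frame(
    condition = order,
    onset = onset,
    duration = duration,
    instruction = unname(instr[order]),
    stim_onset = ifelse(is_task, onset + unname(instr[order]), NA_real_),
    stim_duration = ifelse(is_task, stim_dur, NA_real_),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("block_schedule", "data.frame")
  sched
}

#' Total duration of a block schedule
#'
#' @param schedule A `block_schedule` from [make_schedule()].
#' @return Total duration in seconds (750 for the standard protocol).
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "block_schedule"))
  with(schedule, onset[nrow(schedule)] + duration[nrow(schedule)])
}

#' Task blocks of a schedule
#'
#' @param schedule A `block_schedule`.
#' @return The task-block rows (condition C, 1B or 2B), in temporal order.
#' @export
task_blocks <- function(schedule) {
  schedule[schedule$condition != "rest", , drop = FALSE]
}
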