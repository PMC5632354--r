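#' Zero-phase low-pass filtering of an fNIRS recording
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase, so the block response is not lagged) to every channel of
#' the continuous recording. The default 0.3 Hz cutoff keeps the task/rest
#' frequency of the block protocol while removing cardiac and fast
#' physiological components.
#'
#' @param recording An `nirs_recording`.
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @return The filtered `nirs_recording`.
#' @export
lowpass <- function(recording, cutoff = 0.3) {
  stopifnot(inherits(recording, "nirs_recording"))
  nyq <- recording$sampling_rate / 2
  if (cutoff >= nyq)
    stop("cutoff (", cutoff, " Hz) must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(4, cutoff / nyq, type = "low")
  out <- recording
  out$data <- t(apply(recording$data, 1,
                      function(ch) signal::filtfilt(bf, ch)))
  rownames(out$data) <- rownames(recording$data)
  out
}

#' Extract stimulus-aligned epochs around every task block
#'
#' Cuts the continuous (already filtered) recording into one epoch per task
#' block, anchored at the first stimulus of the block: from `pre_window`
#' seconds before the first stimulus to `post_window` seconds after the end
#' of the 64 s stimulation period. With the standard schedule this yields 9
#' epochs of 14 + 64 + 14 = 92 s each (the instruction screen falls inside
#' the pre-window).
#'
#' @param recording An `nirs_recording` carrying a full block schedule.
#' @param pre_window,post_window Margins in seconds (default 14 each).
#' @param baseline_window Length in seconds of the baseline used later by
#'   [baseline_zscore()] (default 3; stored on the epoch set).
#' @return An object of class `epoch_set`: list with `data` (array
#'   epochs x channels x samples), `condition` (per-epoch label),
#'   `sampling_rate`, the window lengths, and `standardized = FALSE`.
#' @export
extract_epochs <- function(recording, pre_window = 14, post_window = 14,
                           baseline_window = 3) {
  stopifnot(inherits(recording, "nirs_recording"))
  fs <- recording$sampling_rate
  tb <- task_blocks(recording$events)
  if (nrow(tb) == 0) stop("schedule contains no task blocks")
  n_samp <- round((pre_window + tb$stim_duration[1] + post_window) * fs)
  n_total <- ncol(recording$data)
  data <- array(NA_real_, dim = c(nrow(tb), nrow(recording$data), n_samp),
                dimnames = list(NULL, rownames(recording$data), NULL))
  for (i in seq_len(nrow(tb))) {
    start <- round((tb$stim_onset[i] - pre_window) * fs) + 1L
    end <- start + n_samp - 1L
    if (start < 1 || end > n_total)
      stop("epoch ", i, " (", tb$condition[i], ") exceeds recording bounds [",
           start, ", ", end, "] vs ", n_total, " samples")
    data[i, , ] <- recording$data[, start:end]
  }
  structure(list(data = data, condition = tb$condition, sampling_rate = fs,
                 pre_window = pre_window, post_window = post_window,
                 baseline_window = baseline_window, standardized = FALSE),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", dim(x$data)[1], "epochs x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "samples",
      if (x$standardized) "(baseline-standardized)" else "(raw)", "\n")
  invisible(x)
}

baseline_indices <- function(epochs) {
  fs <- epochs$sampling_rate
  pre <- round(epochs$pre_window * fs)
  nb <- round(epochs$baseline_window * fs)
  (pre - nb + 1L):pre
}

#' Baseline z-scoring of epoched fNIRS data
#'
#' Standardizes every sample of each epoch/channel by the mean and SD of
#' that epoch/channel's own baseline: the `baseline_window` seconds (3 by
#' default) immediately preceding the first stimulus,
#' `z = (x_task - m_baseline) / s_baseline`. Raw fNIRS values are relative
#' and not comparable across subjects or channels; this puts every epoch on
#' a common scale of baseline SDs. A channel/epoch whose baseline SD is zero
#' cannot be standardized and is excluded (set to `NA`) with a warning.
#'
#' @param epochs An `epoch_set` from [extract_epochs()].
#' @return The standardized `epoch_set` (`standardized = TRUE`), with an
#'   `excluded` logical matrix (epochs x channels) marking zero-SD cells.
#' @export
baseline_zscore <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$standardized) stop("epochs are already standardized")
  idx <- baseline_indices(epochs)
  d <- dim(epochs$data)
  excluded <- matrix(FALSE, d[1], d[2])
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      b <- epochs$data[e, ch, idx]
      m <- mean(b)
      s <- stats::sd(b)
      if (!is.finite(s) || s == 0) {
        excluded[e, ch] <- TRUE
        epochs$data[e, ch, ] <- NA_real_
      } else {
        epochs$data[e, ch, ] <- (epochs$data[e, ch, ] - m) / s
      }
    }
  }
  if (any(excluded))
    warning(sum(excluded), " epoch/channel cell(s) had zero baseline SD ",
            "and were excluded")
  epochs$excluded <- excluded
  epochs$standardized <- TRUE
  epochs
}

#' Condition averages and grand average
#'
#' Averages epochs within each stimulation condition (C, 1B, 2B), then
#' averages the three condition curves into a grand average, per channel.
#'
#' @param epochs An `epoch_set` (normally baseline-standardized).
#' @return A list of class `nirs_averages`: `condition` (named list of
#'   channels x samples matrices for C, 1B, 2B), `grand` (channels x
#'   samples), and `sampling_rate`.
#' @export
average_conditions <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  conds <- c("C", "1B", "2B")
  missing <- setdiff(conds, unique(epochs$condition))
  if (length(missing))
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  cond_avg <- lapply(conds, function(cc) {
    sel <- which(epochs$condition == cc)
    apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
  })
  names(cond_avg) <- conds
  grand <- Reduce(`+`, cond_avg) / length(cond_avg)
  structure(list(condition = cond_avg, grand = grand,
                 sampling_rate = epochs$sampling_rate),
            class = "nirs_averages")
}

#' Flatten averaged fNIRS responses into a subject feature vector
#'
#' Concatenates, channel by channel in montage order, the (optionally
#' downsampled) grand-average standardized time course — or the three
#' condition averages when `mode = "condition"` — into one deterministic
#' numeric vector per subject.
#'
#' @param averages An `nirs_averages` from [average_conditions()].
#' @param downsample Keep every `downsample`-th sample (default 1 = all).
#' @param mode `"grand"` (default) or `"condition"`.
#' @return Numeric feature vector; length `channels * ceiling(samples /
#'   downsample)` (times 3 in condition mode).
#' @export
vectorize_response <- function(averages, downsample = 1L,
                               mode = c("grand", "condition")) {
  mode <- match.arg(mode)
  stopifnot(inherits(averages, "nirs_averages"), downsample >= 1)
  keep <- seq(1L, ncol(averages$grand), by = as.integer(downsample))
  mats <- if (mode == "grand") list(averages$grand) else averages$condition
  unlist(lapply(mats, function(m) as.vector(t(m[, keep, drop = FALSE]))),
         use.names = FALSE)
}

#' Full preprocessing chain: recordings to an fNIRS feature table
#'
#' Runs, per subject: zero-phase low-pass filtering, stimulus-aligned
#' epoching, baseline z-scoring, condition/grand averaging, and
#' vectorization, and assembles the per-subject vectors into a
#' [feature_table()] for the corresponding NIRS domain.
#'
#' By default each epoch is standardized before averaging
#' (`order = "zscore_then_average"`); the alternate order standardizes the
#' condition-average curves by their own baseline windows instead.
#'
#' @param recordings List of `nirs_recording`s (one chromophore).
#' @param labels ADHD/TD labels, one per recording.
#' @param cutoff Low-pass cutoff in Hz.
#' @param downsample Downsampling factor for [vectorize_response()].
#' @param mode Averaging mode passed to [vectorize_response()].
#' @param order Whether z-scoring precedes or follows condition averaging.
#' @return A `feature_table` with domain `NIRS_OXY` or `NIRS_DEOXY`.
#' @export
nirs_feature_table <- function(recordings, labels, cutoff = 0.3,
                               downsample = 10L,
                               mode = c("grand", "condition"),
                               order = c("zscore_then_average",
                                         "average_then_zscore")) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  stopifnot(length(recordings) == length(labels))
  chrom <- unique(vapply(recordings, `[[`, "", "chromophore"))
  if (length(chrom) != 1)
    stop("all recordings must share one chromophore, got: ",
         paste(chrom, collapse = ", "))
  vecs <- lapply(recordings, function(rec) {
    ep <- extract_epochs(lowpass(rec, cutoff = cutoff))
    if (order == "zscore_then_average") {
      avg <- average_conditions(baseline_zscore(ep))
    } else {
      avg <- zscore_condition_averages(ep)
    }
    vectorize_response(avg, downsample = downsample, mode = mode)
  })
  len <- unique(lengths(vecs))
  if (length(len) != 1)
    stop("feature-vector length mismatch across subjects: ",
         paste(len, collapse = ", "))
  x <- do.call(rbind, vecs)
  colnames(x) <- paste0("nirs_", seq_len(ncol(x)))
  feature_table(x, labels,
                domain = if (chrom == "OXY") "NIRS_OXY" else "NIRS_DEOXY",
                subject_id = vapply(recordings, `[[`, "", "subject_id"))
}

# Alternate pipeline order: average raw epochs per condition first, then
# standardize each condition-average curve by its own baseline window.
zscore_condition_averages <- function(epochs) {
  avg <- average_conditions(epochs)
  idx <- baseline_indices(epochs)
  std <- lapply(avg$condition, function(m) {
    t(apply(m, 1, function(ch) {
      s <- stats::sd(ch[idx])
      if (!is.finite(s) || s == 0) rep(NA_real_, length(ch))
      else (ch - mean(ch[idx])) / s
    }))
  })
  grand <- Reduce(`+`, std) / length(std)
  structure(list(condition = std, grand = grand,
                 sampling_rate = epochs$sampling_rate),
            class = "nirs_averages")
}
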