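# Stimulation-artifact rejection and normalization.
#
# Hardware blanking leaves exactly constant spans in the recording; they are
# found from runs of zero first differences, excised together with a fixed
# number of post-blank samples covering the amplifier-recovery artifact, and
# the surviving segments are concatenated and z-scored.

#' Detect flat (blanked) portions of a signal
#'
#' Scans the first difference of the signal for runs of exact zeros. A run
#' of `m >= min_run - 1` consecutive zero differences marks `m + 1`
#' constant samples.
#'
#' @param signal numeric vector, length >= 2.
#' @param min_run minimum length, in samples, of a constant run to report
#'   (default 3, i.e. 12 ms at 250 Hz — just above the shortest 10 ms
#'   stimulation burst).
#' @return a data.frame with integer columns `start`, `end`: 1-based,
#'   inclusive sample indices of each maximal constant run, sorted and
#'   non-overlapping. Zero rows when the signal has no flat portion.
#' @export
detect_blanking <- function(signal, min_run = 3) {
  if (length(signal) < 2) stop("signal must have length >= 2", call. = FALSE)
  if (min_run < 2) stop("min_run must be >= 2", call. = FALSE)
  d0 <- diff(signal) == 0
  r <- rle(d0)
  ends_d <- cumsum(r$lengths)
  starts_d <- ends_d - r$lengths + 1
  keep <- r$values & r$lengths >= (min_run - 1)
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # diff index i spans samples i..i+1
  data.frame(
    start = as.integer(starts_d[keep]),
    end = as.integer(ends_d[keep] + 1L)
  )
}

validate_intervals <- function(intervals, n) {
  if (!is.data.frame(intervals) ||
      !all(c("start", "end") %in% names(intervals))) {
    stop("intervals must be a data.frame with `start` and `end`",
         call. = FALSE)
  }
  if (nrow(intervals) == 0) return(invisible(NULL))
  if (any(intervals$end <= intervals$start)) {
    stop("intervals must satisfy end > start", call. = FALSE)
  }
  if (any(intervals$start < 1) || any(intervals$end > n)) {
    stop("intervals out of signal range", call. = FALSE)
  }
  if (is.unsorted(intervals$start, strictly = TRUE)) {
    stop("intervals must be sorted by start", call. = FALSE)
  }
  if (nrow(intervals) > 1 &&
      any(intervals$start[-1] <= intervals$end[-nrow(intervals)])) {
    stop("intervals must be non-overlapping", call. = FALSE)
  }
  invisible(NULL)
}

#' Excise blanked spans plus the amplifier-recovery window
#'
#' For each detected interval, samples from its start through
#' `recovery_samples` past its end are deleted (clipped at the signal end;
#' deletions that run into each other are merged), and the remaining
#' segments are concatenated in order.
#'
#' @param signal numeric vector.
#' @param intervals data.frame from [detect_blanking()].
#' @param recovery_samples extra samples removed after each interval
#'   (default 125, i.e. 500 ms at 250 Hz).
#' @return a list of class `clean_channel`: `samples` (the concatenated
#'   survivor), `removed_intervals` (the merged deleted spans, same
#'   1-based inclusive convention) and `original_length`.
#' @export
remove_artifacts <- function(signal, intervals, recovery_samples = 125) {
  n <- length(signal)
  validate_intervals(intervals, n)
  if (recovery_samples < 0) {
    stop("recovery_samples must be >= 0", call. = FALSE)
  }
  if (nrow(intervals) == 0) {
    return(structure(
      list(samples = signal,
           removed_intervals = intervals,
           original_length = n),
      class = "clean_channel"
    ))
  }
  del_start <- intervals$start
  del_end <- pmin(intervals$end + recovery_samples, n)
  # merge deletions that touch or overlap
  ms <- del_start[1]; me <- del_end[1]
  merged <- list()
  if (nrow(intervals) > 1) {
    for (i in 2:nrow(intervals)) {
      if (del_start[i] <= me + 1) {
        me <- max(me, del_end[i])
      } else {
        merged[[length(merged) + 1]] <- c(ms, me)
        ms <- del_start[i]; me <- del_end[i]
      }
    }
  }
  merged[[length(merged) + 1]] <- c(ms, me)
  m <- do.call(rbind, merged)
  drop <- logical(n)
  for (i in seq_len(nrow(m))) drop[m[i, 1]:m[i, 2]] <- TRUE
  structure(
    list(
      samples = signal[!drop],
      removed_intervals = data.frame(start = as.integer(m[, 1]),
                                     end = as.integer(m[, 2])),
      original_length = n
    ),
    class = "clean_channel"
  )
}

#' Z-score normalize a signal
#'
#' Centers to mean 0 and scales to unit standard deviation. The population
#' (n-denominator) convention is used by default.
#'
#' @param signal numeric vector of length >= 2.
#' @param population logical; population (`TRUE`, default) or sample SD.
#' @return the normalized vector.
#' @export
zscore_normalize <- function(signal, population = TRUE) {
  if (length(signal) < 2) stop("signal must have length >= 2", call. = FALSE)
  mu <- mean(signal)
  s <- stats::sd(signal)
  if (population) s <- s * sqrt((length(signal) - 1) / length(signal))
  if (!is.finite(s) || s == 0) {
    stop("degenerate signal: zero standard deviation", call. = FALSE)
  }
  (signal - mu) / s
}

#' Preprocess every channel of a record
#'
#' Runs blank detection, artifact excision and z-scoring per channel,
#' independently (channels of one record may in principle differ in their
#' flat spans). Channels whose excised signal is degenerate (zero variance)
#' are dropped with a warning.
#'
#' @param record a `ts_record`.
#' @param min_run,recovery_samples passed to [detect_blanking()] and
#'   [remove_artifacts()].
#' @return a list of class `clean_record`: `channels` (named list of
#'   `clean_channel` objects with normalized samples), `sampling_rate`,
#'   `record_id`.
#' @export
preprocess_record <- function(record, min_run = 3, recovery_samples = 125) {
  if (!inherits(record, "ts_record")) {
    stop("`record` must be a ts_record", call. = FALSE)
  }
  chans <- list()
  for (ch in seq_len(ncol(record$samples))) {
    sig <- record$samples[, ch]
    iv <- detect_blanking(sig, min_run = min_run)
    cleaned <- remove_artifacts(sig, iv, recovery_samples = recovery_samples)
    normed <- tryCatch(zscore_normalize(cleaned$samples), error = function(e) NULL)
    if (is.null(normed)) {
      warning(sprintf("record %s channel %d degenerate after excision; skipped",
                      record$record_id, ch), call. = FALSE)
      next
    }
    cleaned$samples <- normed
    chans[[colnames(record$samples)[ch]]] <- cleaned
  }
  structure(
    list(channels = chans,
         sampling_rate = record$sampling_rate,
         record_id = record$record_id),
    class = "clean_record"
  )
}
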