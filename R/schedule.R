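#' Dual-time-resolution DCE acquisition schedule
#'
#' Describes the timing of a dual-time-resolution dynamic contrast-enhanced
#' (DCE) acquisition: a fast series that samples the contrast bolus at a
#' short dynamic scan interval, followed by a slow series that samples the
#' gradual tissue enhancement. Defaults reproduce a 29-volume fast series at
#' 3.2 s and a 30-volume slow series at 30.5 s.
#'
#' @param fast_interval Dynamic scan interval of the fast series, seconds.
#' @param fast_n Number of fast volumes (>= 2).
#' @param slow_interval Dynamic scan interval of the slow series, seconds.
#' @param slow_n Number of slow volumes (>= 2).
#' @param gap Dead time between the last fast and the acquisition period of
#'   the first slow volume, seconds (>= 0).
#' @param bolus_arrival Contrast arrival time relative to the first fast
#'   volume, seconds. Must fall inside the fast series.
#'
#' @return An object of class `acq_schedule`.
#' @export
#' @examples
#' sched <- acquisition_schedule()
#' length(make_time_axis(sched))  # 59 time points
acquisition_schedule <- function(fast_interval = 3.2, fast_n = 29,
                                 slow_interval = 30.5, slow_n = 30,
                                 gap = 0, bolus_arrival = 16) {
  stopifnot(is.numeric(fast_interval), is.numeric(slow_interval))
  if (fast_interval <= 0 || slow_interval <= 0)
    stop("scan intervals must be > 0")
  if (fast_n < 2 || slow_n < 2)
    stop("each series needs at least 2 volumes")
  if (gap < 0) stop("inter-sequence gap must be >= 0")
  if (bolus_arrival < 0) stop("bolus arrival must be >= 0")
  if (bolus_arrival >= (fast_n - 1) * fast_interval)
    stop("bolus arrival must fall within the fast series")
  structure(
    list(fast_interval = fast_interval, fast_n = as.integer(fast_n),
         slow_interval = slow_interval, slow_n = as.integer(slow_n),
         gap = gap, bolus_arrival = bolus_arrival),
    class = "acq_schedule")
}

#' Acquisition time axis in minutes
#'
#' The first fast frame is at t = 0; fast frames are `fast_interval` apart.
#' The first slow frame follows the last fast frame after
#' `gap + slow_interval` seconds.
#'
#' @param schedule An [acquisition_schedule()].
#' @return Numeric vector of `fast_n + slow_n` strictly increasing times in
#'   minutes, with attribute `n_fast` marking the fast/slow split.
#' @export
make_time_axis <- function(schedule) {
  stopifnot(inherits(schedule, "acq_schedule"))
  fast <- (seq_len(schedule$fast_n) - 1) * schedule$fast_interval
  slow <- max(fast) + schedule$gap +
    seq_len(schedule$slow_n) * schedule$slow_interval
  t <- c(fast, slow) / 60
  attr(t, "n_fast") <- schedule$fast_n
  t
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf("Dual-time DCE schedule: fast %d x %.1f s, slow %d x %.1f s, gap %.1f s\n",
              x$fast_n, x$fast_interval, x$slow_n, x$slow_interval, x$gap))
  cat(sprintf("  bolus arrival %.1f s; total duration %.2f min\n",
              x$bolus_arrival, max(make_time_axis(x))))
  invisible(x)
}
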