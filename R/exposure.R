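#' Piecewise-constant exposure schedule
#'
#' The toxicant influx `delta_c(t)` — particles (or toxic units) entering
#' the organism per unit time — as a step function of time. Segments are
#' half-open: the level at a breakpoint belongs to the segment that starts
#' there, so `exposure_schedule(c(0, 50), c(34, 0))` describes exposure at
#' 34 up to (but excluding) t = 50 and depuration afterwards.
#'
#' @param times Segment start times: strictly increasing, beginning at 0.
#' @param levels Influx level of each segment (>= 0), same length as
#'   `times`.
#' @param horizon Optional end time of the schedule (> last start time).
#'   When omitted, the solver's `t_max` bounds the run instead.
#' @return An object of class `tkcd_schedule`.
#' @examples
#' constant_exposure(9)
#' exposure_schedule(c(0, 50), c(34, 0), horizon = 100)  # exposure then depuration
#' @export
exposure_schedule <- function(times, levels, horizon = NULL) {
  times <- as.numeric(times)
  levels <- as.numeric(levels)
  if (length(times) == 0L || length(times) != length(levels))
    stop("`times` and `levels` must have equal, positive length",
         call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(levels)))
    stop("`times` and `levels` must be finite", call. = FALSE)
  if (times[1L] != 0)
    stop("the first segment must start at time 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("segment start times must be strictly increasing", call. = FALSE)
  if (any(levels < 0))
    stop("influx levels must be >= 0", call. = FALSE)
  if (!is.null(horizon)) {
    if (!is.numeric(horizon) || length(horizon) != 1L ||
        !is.finite(horizon) || horizon <= times[length(times)])
      stop("`horizon` must be a finite time after the last segment start",
           call. = FALSE)
    horizon <- as.numeric(horizon)
  }
  structure(list(times = times, levels = levels, horizon = horizon),
            class = "tkcd_schedule")
}

#' @rdname exposure_schedule
#' @param level Constant influx level for [constant_exposure()].
#' @export
constant_exposure <- function(level, horizon = NULL) {
  exposure_schedule(0, level, horizon)
}

#' Influx level at given times
#'
#' @param schedule A [exposure_schedule()].
#' @param t Time or vector of times; must lie in `[0, horizon]` (or just be
#'   non-negative if the schedule has no horizon).
#' @return The influx level(s) at `t`, using the half-open segment
#'   convention (a breakpoint takes the level of the segment starting
#'   there).
#' @export
delta_c_at <- function(schedule, t) {
  if (!inherits(schedule, "tkcd_schedule"))
    stop("`schedule` must be a `tkcd_schedule` object", call. = FALSE)
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  if (!is.null(schedule$horizon) && any(t > schedule$horizon))
    stop(sprintf("`t` exceeds the schedule horizon (%g)", schedule$horizon),
         call. = FALSE)
  schedule$levels[findInterval(t, schedule$times)]
}

#' @export
print.tkcd_schedule <- function(x, ...) {
  cat("Exposure schedule (piecewise constant)\n")
  for (i in seq_along(x$times)) {
    end <- if (i < length(x$times)) sprintf("%g", x$times[i + 1L])
           else if (!is.null(x$horizon)) sprintf("%g", x$horizon)
           else "end of run"
    cat(sprintf("  t in [%g, %s): delta_c = %g\n", x$times[i], end,
                x$levels[i]))
  }
  invisible(x)
}

# coerce a scalar into a constant schedule; used by simulate_tkcd()
as_schedule <- function(x) {
  if (inherits(x, "tkcd_schedule")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(constant_exposure(x))
  stop("`schedule` must be a `tkcd_schedule` or a single influx level",
       call. = FALSE)
}
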