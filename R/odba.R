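#' @include AllClasses.R
NULL

# centred moving average with shrunken edge windows, O(n) via cumsum;
# even window lengths put the extra sample on the trailing side
.movingAverage <- function(x, k) {
  n <- length(x)
  if (k >= n) return(rep(mean(x), n))
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.traceRate <- function(time) {
  if (length(time) < 2L) return(NA_real_)
  1 / stats::median(diff(time))
}

#' Static (gravitational) acceleration by smoothing
#'
#' Per-axis centred moving average over a fixed time window (default 1 s,
#' i.e. 50 samples at 50 Hz). The static component captures gravity and
#' posture; subtracting it leaves the dynamic accelerations that enter
#' ODBA. Edges use shrunken windows; traces shorter than the window fall
#' back to the whole-trace mean.
#'
#' @param trace an [AccelTrace-class].
#' @param window smoothing window in seconds (must span >= 2 samples).
#' @return data.frame with columns `ax, ay, az` (smoothed, in g).
#' @export
staticAcceleration <- function(trace, window = 1) {
  rate <- .traceRate(trace@time)
  k <- max(2L, as.integer(round(window * rate)))
  if (is.na(rate)) k <- 2L
  data.frame(ax = .movingAverage(trace@ax, k),
             ay = .movingAverage(trace@ay, k),
             az = .movingAverage(trace@az, k))
}

#' Overall Dynamic Body Acceleration
#'
#' ODBA per sample: the sum over the three axes of the absolute dynamic
#' acceleration, where dynamic = raw minus static (smoothed) acceleration.
#' A linear proxy for metabolic power in swimming and diving birds.
#'
#' @param trace an [AccelTrace-class].
#' @param window static-smoothing window in seconds (see
#'   [staticAcceleration()]).
#' @return an [OdbaSeries-class] at the trace's native rate.
#' @export
computeOdba <- function(trace, window = 1) {
  s <- staticAcceleration(trace, window)
  odba <- abs(trace@ax - s$ax) + abs(trace@ay - s$ay) + abs(trace@az - s$az)
  new("OdbaSeries", time = trace@time, odba = odba,
      rate = .traceRate(trace@time))
}

#' Per-dive ODBA sum
#'
#' Sum of per-sample ODBA over a dive interval, in g-sample units at the
#' series' native rate (sums are only comparable between series recorded
#' at the same rate; the rate is stored on the series). Samples strictly
#' within `[start, end]` are summed; surface samples outside the dive are
#' never included.
#'
#' @param odba an [OdbaSeries-class].
#' @param start,end dive start/end time in seconds.
#' @return numeric scalar.
#' @export
diveOdbaSum <- function(odba, start, end) {
  sel <- odba@time >= start & odba@time <= end
  if (!any(sel))
    stop("no ODBA samples within [", start, ", ", end, "]", call. = FALSE)
  sum(odba@odba[sel])
}

#' Attach per-dive ODBA sums to a dive table
#'
#' @param dives data.frame from [detectDives()] (columns `start`, `end`).
#' @param odba an [OdbaSeries-class] spanning the dives.
#' @return `dives` with an `odbaSum` column added.
#' @export
addDiveOdba <- function(dives, odba) {
  dives$odbaSum <- vapply(seq_len(nrow(dives)), function(i)
    diveOdbaSum(odba, dives$start[i], dives$end[i]), numeric(1))
  dives
}
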