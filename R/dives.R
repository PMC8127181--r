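#' @include AllClasses.R
NULL

.runs <- function(flag) {
  # start/end indices of TRUE runs
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect dives in a depth trace
#'
#' A dive is a maximal interval where depth exceeds the surface reference
#' (hysteresis band, default 1 m, robust to the centimetre-level noise of
#' pressure sensors near the surface), retained only when its maximum
#' depth strictly exceeds `threshold` (default 3 m, the acceptance rule
#' that avoids depth-measurement inaccuracy in the top of the water
#' column). The dive start is the time of the first submerged sample and
#' the end is the first surface sample after it (trace end + one sampling
#' step if the trace ends submerged), so the duration equals submerged
#' samples times the sampling interval.
#'
#' @param depth a [DepthTrace-class].
#' @param threshold minimum maximum-depth for acceptance, metres (strict).
#' @param surface surface reference depth, metres.
#' @return data.frame with one row per dive: `start, end, duration,
#'   maxDepth, istart, iend` (sample indices of the submerged interval).
#' @export
detectDives <- function(depth, threshold = 3, surface = 1) {
  t <- depth@time; d <- depth@depth
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), maxDepth = numeric(0),
                      istart = integer(0), iend = integer(0))
  if (length(t) == 0L) return(empty)
  dt <- if (length(t) > 1) stats::median(diff(t)) else 1
  runs <- .runs(d > surface)
  if (!nrow(runs)) return(empty)
  out <- lapply(seq_len(nrow(runs)), function(k) {
    i0 <- runs[k, "start"]; i1 <- runs[k, "end"]
    md <- max(d[i0:i1])
    if (md <= threshold) return(NULL)
    end <- if (i1 < length(t)) t[i1 + 1L] else t[i1] + dt
    data.frame(start = t[i0], end = end, duration = end - t[i0],
               maxDepth = md, istart = i0, iend = i1)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Bottom phase of a single dive
#'
#' The bottom phase spans from the end of the sustained descent (steady
#' depth increase) to the start of the final sustained ascent. Phases are
#' found from sample-to-sample vertical speed: a descent (ascent) run is a
#' run of speeds above `vspeedThreshold` (below its negative) lasting at
#' least `minRun` samples; the bottom starts where the last such descent
#' run before the first ascent run ends, and ends where that ascent run
#' begins. V-shaped dives yield bottom time 0.
#'
#' @param time,depth numeric vectors of the dive's samples (>= 3 samples;
#'   shorter dives return bottom time 0).
#' @param vspeedThreshold vertical-speed threshold, m s^-1.
#' @param minRun minimum run length, samples.
#' @return list `bottomStart, bottomEnd, bottomTime` (seconds).
#' @export
bottomPhase <- function(time, depth, vspeedThreshold = 0.25, minRun = 5L) {
  n <- length(time)
  apexT <- time[which.max(depth)]
  degenerate <- list(bottomStart = apexT, bottomEnd = apexT, bottomTime = 0)
  if (n < 3L) return(degenerate)
  s <- diff(depth) / diff(time)
  qualifying <- function(flag) {
    r <- .runs(flag)
    r[r[, "end"] - r[, "start"] + 1L >= minRun, , drop = FALSE]
  }
  desc <- qualifying(s > vspeedThreshold)
  asc <- qualifying(s < -vspeedThreshold)
  endIdx <- if (nrow(asc)) asc[1L, "start"] else n
  descBefore <- desc[desc[, "end"] < endIdx, , drop = FALSE]
  startIdx <- if (nrow(descBefore))
    descBefore[nrow(descBefore), "end"] + 1L else 1L
  if (startIdx >= endIdx) return(degenerate)
  list(bottomStart = time[startIdx], bottomEnd = time[endIdx],
       bottomTime = time[endIdx] - time[startIdx])
}

#' Attach bottom phases to a dive table
#' @param dives data.frame from [detectDives()].
#' @param depth the source [DepthTrace-class].
#' @param vspeedThreshold,minRun see [bottomPhase()].
#' @return `dives` with `bottomStart, bottomEnd, bottomTime` columns.
#' @export
addBottomPhases <- function(dives, depth, vspeedThreshold = 0.25,
                            minRun = 5L) {
  bp <- lapply(seq_len(nrow(dives)), function(k) {
    i <- dives$istart[k]:dives$iend[k]
    bottomPhase(depth@time[i], depth@depth[i], vspeedThreshold, minRun)
  })
  dives$bottomStart <- vapply(bp, `[[`, numeric(1), "bottomStart")
  dives$bottomEnd <- vapply(bp, `[[`, numeric(1), "bottomEnd")
  dives$bottomTime <- vapply(bp, `[[`, numeric(1), "bottomTime")
  dives
}

#' Benthic/pelagic classification by the intra-depth-zone rule
#'
#' A dive is benthic when its maximum depth lies within +/- `band` (default
#' 10%) of the maximum depth of the immediately preceding dive — serial
#' dives to the same depth zone indicate seabed foraging. The first dive of
#' a trip has no predecessor and takes `firstDiveClass` (default pelagic, a
#' conservative choice).
#'
#' @param dives time-ordered dive table (column `maxDepth`) of one trip.
#' @param band fractional half-width of the intra-depth zone.
#' @param firstDiveClass class of the first dive.
#' @return `dives` with a `class` column (`"benthic"` / `"pelagic"`).
#' @export
classifyIdz <- function(dives, band = 0.10, firstDiveClass = "pelagic") {
  n <- nrow(dives)
  cls <- character(n)
  if (n == 0L) { dives$class <- cls; return(dives) }
  cls[1L] <- firstDiveClass
  if (n > 1L) {
    prev <- dives$maxDepth[-n]
    cur <- dives$maxDepth[-1L]
    benthic <- cur >= (1 - band) * prev & cur <= (1 + band) * prev
    cls[-1L] <- ifelse(benthic, "benthic", "pelagic")
  }
  dives$class <- cls
  dives
}

#' Georeference dives along a GPS track
#'
#' Each dive receives the position linearly interpolated (in time) between
#' the GPS fixes bracketing its midpoint — the halfway point between fixes
#' when the dive falls midway. Dives outside the track's time span take the
#' nearest fix's position, with a warning.
#'
#' @param dives dive table (`start`, `end`).
#' @param track a [GpsTrack-class] spanning the dive times.
#' @return `dives` with `lon`, `lat` columns.
#' @export
georeferenceDives <- function(dives, track) {
  mid <- (dives$start + dives$end) / 2
  outside <- mid < min(track@time) | mid > max(track@time)
  if (any(outside))
    warning(sum(outside), " dive(s) outside the track span; ",
            "nearest-fix position used", call. = FALSE)
  dives$lon <- stats::approx(track@time, track@lon, xout = mid, rule = 2)$y
  dives$lat <- stats::approx(track@time, track@lat, xout = mid, rule = 2)$y
  dives
}

#' Split a track into foraging trips by colony radius
#'
#' A trip starts when the track leaves a radius around the colony and ends
#' when it re-enters it.
#'
#' @param track a [GpsTrack-class].
#' @param colony `c(lon, lat)`.
#' @param radiusM colony radius in metres.
#' @return list of [GpsTrack-class] segments (possibly empty).
#' @export
splitTrips <- function(track, colony, radiusM = 200) {
  d <- greatCircleDistance(track@lon, track@lat, colony[1], colony[2])
  runs <- .runs(d > radiusM)
  lapply(seq_len(nrow(runs)), function(k) {
    i <- runs[k, "start"]:runs[k, "end"]
    GpsTrack(track@time[i], track@lon[i], track@lat[i])
  })
}

#' Trip metrics for one foraging trip
#'
#' Trip length is the cumulative great-circle distance between consecutive
#' fixes; maximum distance is the largest great-circle distance from any
#' fix to the colony; duration runs from the onset of the first dive to the
#' end of the last dive.
#'
#' @param track a [GpsTrack-class] (>= 2 fixes).
#' @param dives dive table of this trip (may have zero rows).
#' @param colony `c(lon, lat)`.
#' @param individual id carried on the result.
#' @return a [ForagingTrip-class].
#' @export
tripMetrics <- function(track, dives, colony, individual = "bird") {
  if (nSamples(track) < 2L) stop("a trip needs >= 2 fixes", call. = FALSE)
  n <- nSamples(track)
  seg <- greatCircleDistance(track@lon[-n], track@lat[-n],
                             track@lon[-1L], track@lat[-1L])
  dcol <- greatCircleDistance(track@lon, track@lat, colony[1], colony[2])
  if (nrow(dives) == 0L) {
    warning("trip has no dives; duration undefined", call. = FALSE)
    dur <- NA_real_
  } else {
    dur <- (max(dives$end) - min(dives$start)) / 60
  }
  new("ForagingTrip", individual = individual, track = track,
      dives = dives, lengthKm = sum(seg) / 1000,
      maxDistanceKm = max(dcol) / 1000, durationMin = dur)
}

#' Aggregate dive statistics over foraging trips
#'
#' By default only the first foraging trip of each individual enters the
#' aggregation, so birds with several trips do not weigh more. MND is the
#' median number of dives per trip; pBD and pPD the medians of the per-trip
#' benthic/pelagic proportions (each trip's pair sums to 1); dive durations
#' are pooled per-class medians; the pelagic depth summary is the median of
#' pelagic maximum depths (the pelagic depth distribution is left-shifted,
#' which is why the median, not the mean, is used); mBBT is the minimum
#' observed benthic bottom time. With no benthic dives, pBD is 0 and mBBT
#' is `NA`.
#'
#' @param trips list of [ForagingTrip-class] objects whose dive tables
#'   carry `class` and `bottomTime` columns.
#' @param firstTripOnly keep only each individual's earliest trip.
#' @return a [TripStats-class].
#' @export
tripStatistics <- function(trips, firstTripOnly = TRUE) {
  if (!length(trips)) stop("need at least one trip", call. = FALSE)
  if (firstTripOnly) {
    ids <- vapply(trips, function(tr) tr@individual, character(1))
    t0 <- vapply(trips, function(tr) min(tr@track@time), numeric(1))
    keep <- vapply(unique(ids), function(id) {
      w <- which(ids == id); w[which.min(t0[w])]
    }, integer(1))
    trips <- trips[sort(keep)]
  }
  perTrip <- lapply(trips, function(tr) {
    dv <- tr@dives
    nb <- sum(dv$class == "benthic")
    data.frame(n = nrow(dv), pBD = nb / max(1L, nrow(dv)))
  })
  perTrip <- do.call(rbind, perTrip)
  pooled <- do.call(rbind, lapply(trips, tripDives))
  ben <- pooled[pooled$class == "benthic", , drop = FALSE]
  pel <- pooled[pooled$class == "pelagic", , drop = FALSE]
  med <- function(x) if (length(x)) stats::median(x) else NA_real_
  new("TripStats",
      MND = stats::median(perTrip$n),
      pBD = stats::median(perTrip$pBD),
      pPD = stats::median(1 - perTrip$pBD),
      DDbenthic = med(ben$duration),
      DDpelagic = med(pel$duration),
      medianPelagicDepth = med(pel$maxDepth),
      mBBT = if (nrow(ben)) min(ben$bottomTime) else NA_real_)
}
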