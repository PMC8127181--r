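#' @include AllClasses.R
NULL

#' Process one deployment into labelled, positioned dives and trips
#'
#' The full trace-to-dive-table chain: dive detection (> 3 m acceptance),
#' bottom phases, per-dive ODBA sums from the acceleration channel,
#' georeferencing along the GPS track, trip splitting by colony radius,
#' intra-depth-zone classification within each trip, and trip metrics.
#'
#' @param depth a [DepthTrace-class].
#' @param track a [GpsTrack-class].
#' @param colony `c(lon, lat)`.
#' @param accel optional [AccelTrace-class]; when supplied, per-dive ODBA
#'   sums are computed and attached.
#' @param individual id carried onto the trips.
#' @param threshold,surface see [detectDives()].
#' @param vspeedThreshold,minRun see [bottomPhase()].
#' @param band,firstDiveClass see [classifyIdz()].
#' @param colonyRadiusM see [splitTrips()].
#' @param odbaWindow see [computeOdba()].
#' @return list with `dives` (all dives, labelled and positioned) and
#'   `trips` (list of [ForagingTrip-class]).
#' @export
processDeployment <- function(depth, track, colony, accel = NULL,
                              individual = "bird", threshold = 3,
                              surface = 1, vspeedThreshold = 0.25,
                              minRun = 5L, band = 0.10,
                              firstDiveClass = "pelagic",
                              colonyRadiusM = 200, odbaWindow = 1) {
  dives <- detectDives(depth, threshold = threshold, surface = surface)
  dives <- addBottomPhases(dives, depth, vspeedThreshold, minRun)
  if (!is.null(accel))
    dives <- addDiveOdba(dives, computeOdba(accel, window = odbaWindow))
  dives <- georeferenceDives(dives, track)
  segments <- splitTrips(track, colony, radiusM = colonyRadiusM)
  trips <- list(); labelled <- list()
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    tspan <- range(seg@time)
    sel <- dives$start >= tspan[1] - colonyRadiusM &
      dives$end <= tspan[2] + colonyRadiusM
    dv <- classifyIdz(dives[sel, , drop = FALSE], band = band,
                      firstDiveClass = firstDiveClass)
    labelled[[k]] <- dv
    trips[[k]] <- tripMetrics(seg, dv, colony,
                              individual = paste0(individual, ".", k))
  }
  # one individual: its trips share the id so first-trip filters work
  for (k in seq_along(trips)) trips[[k]]@individual <- individual
  list(dives = if (length(labelled)) do.call(rbind, labelled) else dives,
       trips = trips)
}

#' Calibrate the landscape's regression models from processed trips
#'
#' Pools the dives of each individual's first foraging trip and fits the
#' per-class ODBA-sum-vs-depth and bottom-time-vs-depth regressions, plus
#' (when at least three trips are available) the dives-per-trip vs.
#' maximum-distance regression used in the distance-dependent MND mode.
#'
#' @param trips list of [ForagingTrip-class] from [processDeployment()].
#' @param families candidate regression families, see [fitBestModel()].
#' @param firstTripOnly pool only each individual's first trip.
#' @return list `odbaBenthic, odbaPelagic, btBenthic, btPelagic,
#'   divesDistance` (the last may be `NULL`).
#' @export
calibrateModels <- function(trips,
                            families = c("linear", "power", "exprise",
                                         "quadratic"),
                            firstTripOnly = TRUE) {
  if (firstTripOnly) {
    ids <- vapply(trips, function(tr) tr@individual, character(1))
    t0 <- vapply(trips, function(tr) min(tr@track@time), numeric(1))
    keep <- vapply(unique(ids), function(id) {
      w <- which(ids == id); w[which.min(t0[w])]
    }, integer(1))
    trips <- trips[sort(keep)]
  }
  dives <- do.call(rbind, lapply(trips, tripDives))
  odba <- fitOdbaDepth(dives, families = families)
  bt <- fitBottomtimeDepth(dives, families = families)
  dvd <- if (length(trips) >= 3L)
    fitDivesVsDistance(trips, families = families) else NULL
  list(odbaBenthic = odba$benthic, odbaPelagic = odba$pelagic,
       btBenthic = bt$benthic, btPelagic = bt$pelagic,
       divesDistance = dvd)
}
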