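#' @include AllClasses.R
NULL

#' Straight-line distance from the colony to each grid cell
#'
#' @param grid a [BathymetryGrid-class].
#' @param colony `c(lon, lat)`.
#' @return numeric metres, one value per cell.
#' @export
gridDistances <- function(grid, colony)
  greatCircleDistance(grid@lon, grid@lat, colony[1], colony[2])

#' Full energetic breakdown and TRC for grid cells
#'
#' Runs the whole energetics chain for vectors of cell depth and
#' colony-to-cell distance: the per-class ODBA-sum laws are evaluated at
#' 3 m and at the cell depth (benthic) or the median pelagic depth
#' (pelagic), converted to mass-specific power, integrated over the
#' dives of a trip (trapezoidal depth gradient), combined with the
#' doubled travel cost into the total cost of foraging, and divided by
#' the total bottom time. Cells shallower than 3 m or with non-positive
#' bottom time are flagged.
#'
#' `MND` is either the fixed trip-level median (`mode = "fixed"`) or
#' predicted from the maximum-distance regression (`mode = "distance"`,
#' for populations whose dives per trip scale with trip extent).
#'
#' @param depth cell seabed depth, m (vector).
#' @param distance colony distance, m (vector, recycled against depth).
#' @param models list with elements `odbaBenthic`, `odbaPelagic`,
#'   `btBenthic`, `btPelagic` and (for `mode = "distance"`)
#'   `divesDistance`, each a [RegressionModel-class].
#' @param stats a [TripStats-class].
#' @param species a [SpeciesParams-class].
#' @param mode `"fixed"` or `"distance"` MND.
#' @param warnExtrapolation passed to [predict()][RegressionModel-class].
#' @return data.frame with columns `CT, MND, MPbenthic, MPpelagic,
#'   MPMNDbenthic, MPMNDpelagic, TCF, BBT, PBT, TBT, TRC, flagged`.
#' @export
cellTrc <- function(depth, distance, models, stats, species,
                    mode = c("fixed", "distance"),
                    warnExtrapolation = TRUE) {
  mode <- match.arg(mode)
  n <- max(length(depth), length(distance))
  depth <- rep_len(depth, n); distance <- rep_len(distance, n)
  pBD <- stats@pBD; pPD <- 1 - stats@pBD
  pd <- stats@medianPelagicDepth

  mp <- function(model, at) massSpecificPower(
    voFromOdba(predict(model, at, warnExtrapolation = warnExtrapolation),
               species), species)
  mpB3 <- mp(models$odbaBenthic, 3)
  mpBD <- mp(models$odbaBenthic, depth)
  mpP3 <- mp(models$odbaPelagic, 3)
  mpPD <- mp(models$odbaPelagic, pd)

  MND <- if (mode == "fixed") rep_len(stats@MND, n) else
    predict(models$divesDistance, distance / 1000,
            warnExtrapolation = warnExtrapolation)

  MPMNDb <- mpMnd(stats@DDbenthic, mpB3, mpBD, MND, pBD)
  MPMNDp <- mpMnd(stats@DDpelagic, mpP3, mpPD, MND, pPD)
  CT <- costOfTravel(distance, species)
  TCF <- totalCostForaging(MPMNDb, MPMNDp, CT)

  BBT <- predict(models$btBenthic, depth,
                 warnExtrapolation = warnExtrapolation)
  PBT <- rep_len(predict(models$btPelagic, pd,
                         warnExtrapolation = warnExtrapolation), n)
  TBT <- totalBottomTime(stats@mBBT, BBT, PBT, MND, pBD, pPD)

  flagged <- depth < 3 | TBT <= 0
  TRC <- rep(NA_real_, n)
  TRC[!flagged] <- totalRelativeCost(TCF[!flagged], TBT[!flagged])
  data.frame(CT = CT, MND = MND, MPbenthic = mpBD, MPpelagic = mpPD,
             MPMNDbenthic = MPMNDb, MPMNDpelagic = MPMNDp, TCF = TCF,
             BBT = BBT, PBT = PBT, TBT = TBT, TRC = TRC,
             flagged = flagged)
}

#' Inverse-distance-weighted interpolation
#'
#' Shepard interpolation: the value at a target is the mean of the sample
#' values weighted by distance^(-power) over the `k` nearest samples
#' (all samples by default). A target closer than `eps` metres to a
#' sample returns that sample's value exactly, so interpolating onto the
#' sample locations reproduces them. Interpolated values are convex
#' combinations and never exceed the sample extrema.
#'
#' @param sampleLon,sampleLat,values numeric vectors of samples.
#' @param targetLon,targetLat numeric vectors of target positions.
#' @param power IDW exponent (> 0), default 2 (canonical Shepard).
#' @param k number of nearest samples, `Inf` for all.
#' @param eps exact-match tolerance, metres.
#' @return numeric values at the targets.
#' @export
idwInterpolate <- function(sampleLon, sampleLat, values,
                           targetLon, targetLat, power = 2, k = Inf,
                           eps = 1e-3) {
  ns <- length(values)
  if (ns == 0L) stop("IDW needs at least one sample", call. = FALSE)
  stopifnot(power > 0, length(sampleLon) == ns, length(sampleLat) == ns)
  nt <- length(targetLon)
  out <- numeric(nt)
  # coordinate-identical targets short-circuit to the exactness rule
  key <- match(paste(targetLon, targetLat),
               paste(sampleLon, sampleLat))
  hit <- !is.na(key)
  out[hit] <- values[key[hit]]
  todo <- which(!hit)
  for (i in todo) {
    d <- greatCircleDistance(targetLon[i], targetLat[i],
                             sampleLon, sampleLat)
    j <- which.min(d)
    if (d[j] < eps) { out[i] <- values[j]; next }
    use <- if (is.finite(k) && k < ns)
      order(d)[seq_len(k)] else seq_len(ns)
    w <- d[use]^(-power)
    out[i] <- sum(w * values[use]) / sum(w)
  }
  out
}

#' Build the energy landscape over a bathymetry grid
#'
#' Computes per-cell TRC with [cellTrc()], excludes flagged cells
#' (shallower than 3 m or with non-positive bottom time), and
#' interpolates the unflagged TRC surface with IDW. By default the
#' interpolation targets are the cell centres themselves (same
#' resolution as the bathymetry); `rasterFactor > 1` inserts that many
#' points per cell edge for a finer display raster.
#'
#' @param grid a [BathymetryGrid-class].
#' @param models list of fitted models, see [cellTrc()].
#' @param stats a [TripStats-class].
#' @param species a [SpeciesParams-class].
#' @param colony `c(lon, lat)`.
#' @param mode `"fixed"` or `"distance"` MND, see [cellTrc()].
#' @param rasterFactor integer >= 1, raster refinement per cell edge.
#' @param idwPower,idwK IDW parameters, recorded in the metadata.
#' @param warnExtrapolation passed through to the model predictions.
#' @return an [EnergyLandscape-class].
#' @export
buildEnergyLandscape <- function(grid, models, stats, species, colony,
                                 mode = c("fixed", "distance"),
                                 rasterFactor = 1L, idwPower = 2,
                                 idwK = Inf, warnExtrapolation = FALSE) {
  mode <- match.arg(mode)
  distance <- gridDistances(grid, colony)
  comp <- cellTrc(grid@depth, distance, models, stats, species,
                  mode = mode, warnExtrapolation = warnExtrapolation)
  cells <- cbind(data.frame(lon = grid@lon, lat = grid@lat,
                            depth = grid@depth, distance = distance),
                 comp)
  ok <- !cells$flagged
  if (!any(ok)) stop("all cells flagged; no landscape", call. = FALSE)
  if (rasterFactor <= 1L) {
    tLon <- cells$lon[ok]; tLat <- cells$lat[ok]
  } else {
    stepLon <- stats::median(diff(sort(unique(cells$lon)))) / rasterFactor
    stepLat <- stats::median(diff(sort(unique(cells$lat)))) / rasterFactor
    g <- expand.grid(lon = seq(min(cells$lon), max(cells$lon), by = stepLon),
                     lat = seq(min(cells$lat), max(cells$lat), by = stepLat))
    tLon <- g$lon; tLat <- g$lat
  }
  trc <- idwInterpolate(cells$lon[ok], cells$lat[ok], cells$TRC[ok],
                        tLon, tLat, power = idwPower, k = idwK)
  # convex-combination property, asserted on every run
  stopifnot(min(trc) >= min(cells$TRC[ok]) - 1e-9,
            max(trc) <= max(cells$TRC[ok]) + 1e-9)
  new("EnergyLandscape",
      cells = cells,
      raster = data.frame(lon = tLon, lat = tLat, TRC = trc),
      metadata = list(species = species, models = models, stats = stats,
                      colony = colony, mode = mode,
                      idw = list(power = idwPower, k = idwK),
                      rasterFactor = rasterFactor))
}

#' Summarise landscape cost at observed dive locations
#'
#' Each positioned dive is assigned the TRC of its grid cell (nearest
#' unflagged cell centre); dives farther than one cell size from any cell
#' are excluded and counted. Returns the per-dive values, their median and
#' range, and a histogram (default 10 equal-width bins over the pooled
#' range, so runs are directly comparable when the same edges are
#' supplied).
#'
#' @param landscape an [EnergyLandscape-class].
#' @param dives positioned dive table (`lon`, `lat`).
#' @param bins number of equal-width bins, or a vector of bin edges.
#' @return a [LandscapeSummary-class].
#' @export
summarizeAtDives <- function(landscape, dives, bins = 10L) {
  cells <- landscape@cells[!landscape@cells$flagged, , drop = FALSE]
  cellSize <- landscape@metadata$cellSize %||%
    (stats::median(diff(sort(unique(cells$lat)))) * pi * 6371000 / 180)
  trc <- rep(NA_real_, nrow(dives))
  for (i in seq_len(nrow(dives))) {
    d <- greatCircleDistance(dives$lon[i], dives$lat[i],
                             cells$lon, cells$lat)
    j <- which.min(d)
    if (d[j] <= cellSize) trc[i] <- cells$TRC[j]
  }
  excluded <- sum(is.na(trc))
  trc <- trc[!is.na(trc)]
  if (!length(trc))
    return(new("LandscapeSummary", diveTrc = numeric(0),
               median = NA_real_, range = c(NA_real_, NA_real_),
               histBreaks = numeric(0), histCounts = numeric(0),
               nExcluded = as.integer(excluded)))
  if (length(bins) == 1L) {
    rg <- range(trc)
    if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
    breaks <- seq(rg[1], rg[2], length.out = bins + 1L)
  } else breaks <- bins
  h <- graphics::hist(trc, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  new("LandscapeSummary", diveTrc = trc, median = stats::median(trc),
      range = range(trc), histBreaks = h$breaks, histCounts = h$counts,
      nExcluded = as.integer(excluded))
}
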