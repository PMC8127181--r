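#' @import methods
NULL

.strictlyIncreasing <- function(x) length(x) < 2L || all(diff(x) > 0)

#' Tri-axial acceleration trace
#'
#' Raw accelerometry sampled at a nominally constant rate (50 Hz in the
#' deployments this package emulates). Axes follow the logger convention
#' surge (`ax`), sway (`ay`), heave (`az`), all in units of g.
#'
#' @slot time numeric, seconds from deployment start, strictly increasing.
#' @slot ax,ay,az numeric, acceleration in g.
#' @exportClass AccelTrace
setClass("AccelTrace",
  representation(time = "numeric", ax = "numeric", ay = "numeric",
                 az = "numeric"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@ax) != n || length(object@ay) != n ||
        length(object@az) != n)
      return("the three axes and time must have the same length")
    if (!.strictlyIncreasing(object@time))
      return("timestamps must be strictly increasing")
    if (n >= 3) {
      dt <- diff(object@time)
      if ((max(dt) - min(dt)) > 0.01 * stats::median(dt))
        return("sampling interval must be constant to within 1%")
    }
    if (anyNA(c(object@ax, object@ay, object@az)))
      return("acceleration values must be finite")
    TRUE
  })

#' Depth (time-depth-recorder) trace
#'
#' Pressure-derived depth in metres, positive down, nominally 1 Hz. Small
#' negative values (surface sensor noise) are tolerated down to -0.5 m.
#'
#' @slot time numeric seconds, strictly increasing.
#' @slot depth numeric metres, positive down.
#' @exportClass DepthTrace
setClass("DepthTrace",
  representation(time = "numeric", depth = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@depth))
      return("time and depth must have the same length")
    if (!.strictlyIncreasing(object@time))
      return("timestamps must be strictly increasing")
    if (anyNA(object@depth) || any(!is.finite(object@depth)))
      return("depth must be finite")
    if (any(object@depth < -0.5))
      return("depth below -0.5 m violates the positive-down convention")
    TRUE
  })

#' GPS track
#'
#' Positional fixes (WGS84 lon/lat degrees) at a nominal 5-min interval.
#'
#' @slot time numeric seconds, strictly increasing.
#' @slot lon,lat numeric degrees.
#' @exportClass GpsTrack
setClass("GpsTrack",
  representation(time = "numeric", lon = "numeric", lat = "numeric"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@lon) != n || length(object@lat) != n)
      return("time, lon and lat must have the same length")
    if (!.strictlyIncreasing(object@time))
      return("timestamps must be strictly increasing")
    if (any(abs(object@lat) > 90, na.rm = TRUE))
      return("|lat| must be <= 90")
    if (any(abs(object@lon) > 180, na.rm = TRUE))
      return("|lon| must be <= 180")
    TRUE
  })

#' Bathymetry grid
#'
#' Regular grid of marine cells: cell centres in lon/lat degrees and seabed
#' depth in metres, positive down. Land or invalid cells are excluded on
#' construction, never carried as sentinels.
#'
#' @slot lon,lat numeric degrees, cell centres (unique pairs).
#' @slot depth numeric metres, > 0 for every retained (marine) cell.
#' @slot cellSize numeric, nominal cell edge in metres.
#' @slot crs character, currently `"lonlat"` (haversine distances).
#' @exportClass BathymetryGrid
setClass("BathymetryGrid",
  representation(lon = "numeric", lat = "numeric", depth = "numeric",
                 cellSize = "numeric", crs = "character"),
  validity = function(object) {
    n <- length(object@lon)
    if (length(object@lat) != n || length(object@depth) != n)
      return("lon, lat and depth must have the same length")
    if (n == 0L) return("grid has no marine cells")
    if (any(object@depth <= 0))
      return("marine cells must have depth > 0 (positive-down)")
    if (anyDuplicated(paste(object@lon, object@lat)))
      return("cell centres must be unique")
    if (length(object@cellSize) != 1L || object@cellSize <= 0)
      return("cellSize must be a single positive number")
    TRUE
  })

#' Per-sample Overall Dynamic Body Acceleration
#'
#' ODBA = |Ax| + |Ay| + |Az| of the dynamic (static-subtracted)
#' accelerations, in g, at the native sampling rate of the source trace.
#'
#' @slot time numeric seconds, same length as the source [AccelTrace-class].
#' @slot odba numeric g, non-negative.
#' @slot rate numeric sampling rate in Hz, recorded so that per-dive ODBA
#'   sums (g-sample units) stay comparable across deployments.
#' @exportClass OdbaSeries
setClass("OdbaSeries",
  representation(time = "numeric", odba = "numeric", rate = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@odba))
      return("time and odba must have the same length")
    if (any(object@odba < 0)) return("odba must be non-negative")
    TRUE
  })

#' Species-level energetic parameters
#'
#' Body mass, locomotion and oxygen-calibration constants used by the
#' energetics equations. The oxygen-consumption intercept and slope follow
#' the allometric relations intercept = 2.75 BM^0.73 and
#' slope = 3.52 BM^0.94 (ml O2 min^-1 and ml O2 min^-1 per ODBA unit)
#' unless overridden.
#'
#' @slot BM body mass, kg.
#' @slot swimSpeed commuting swim speed, m s^-1.
#' @slot transportCost mass-specific cost of transport, W kg^-1.
#' @slot voIntercept,voSlope ODBA-to-oxygen calibration, ml O2 min^-1.
#' @slot o2ToPower J s^-1 per (ml O2 min^-1).
#' @exportClass SpeciesParams
setClass("SpeciesParams",
  representation(BM = "numeric", swimSpeed = "numeric",
                 transportCost = "numeric", voIntercept = "numeric",
                 voSlope = "numeric", o2ToPower = "numeric"),
  validity = function(object) {
    v <- c(object@BM, object@swimSpeed, object@transportCost,
           object@voIntercept, object@voSlope, object@o2ToPower)
    if (length(v) != 6L || any(!is.finite(v)) || any(v <= 0))
      return("all parameters must be single positive numbers")
    TRUE
  })

#' Fitted depth-dependent regression
#'
#' One fitted response-vs-predictor relationship (e.g. per-dive ODBA sum
#' vs. maximum dive depth for benthic dives), as a named family with
#' parameters, the coefficient of determination on the original response
#' scale, and the training predictor range used to flag extrapolation.
#'
#' @slot response,predictor character names of the modelled quantities.
#' @slot diveClass `"benthic"`, `"pelagic"` or `"all"`.
#' @slot family one of `"linear"`, `"power"`, `"exprise"`, `"quadratic"`.
#' @slot coef named numeric parameter vector.
#' @slot r2 numeric in `[0, 1]`.
#' @slot n number of observations fitted.
#' @slot trainRange numeric length-2, predictor range of the training data.
#' @exportClass RegressionModel
setClass("RegressionModel",
  representation(response = "character", predictor = "character",
                 diveClass = "character", family = "character",
                 coef = "numeric", r2 = "numeric", n = "integer",
                 trainRange = "numeric"),
  validity = function(object) {
    if (!object@diveClass %in% c("benthic", "pelagic", "all"))
      return("diveClass must be benthic, pelagic or all")
    if (!object@family %in% names(.regressionFamilies()))
      return(paste("unknown family:", object@family))
    if (object@r2 < -1e-9 || object@r2 > 1 + 1e-9)
      return("R^2 must lie in [0, 1]")
    if (object@n < 3L) return("n must be >= 3")
    TRUE
  })

#' Foraging-trip level dive statistics
#'
#' Aggregated over the first foraging trip of each individual: median number
#' of dives per trip (MND), median per-trip proportions of benthic (pBD) and
#' pelagic (pPD) dives, median dive durations per class (s), the median
#' maximum depth of pelagic dives (m; the pelagic depth distribution is
#' left-shifted, so the median is used), and the minimum observed benthic
#' bottom time mBBT (s).
#'
#' @slot MND,pBD,pPD,DDbenthic,DDpelagic,medianPelagicDepth,mBBT numeric
#'   scalars; `mBBT` and class-specific fields are `NA` when a class is
#'   absent.
#' @exportClass TripStats
setClass("TripStats",
  representation(MND = "numeric", pBD = "numeric", pPD = "numeric",
                 DDbenthic = "numeric", DDpelagic = "numeric",
                 medianPelagicDepth = "numeric", mBBT = "numeric"),
  validity = function(object) {
    if (object@MND <= 0) return("MND must be > 0")
    if (!is.na(object@pBD) &&
        (object@pBD < 0 || object@pBD > 1)) return("pBD must be in [0,1]")
    if (!is.na(object@mBBT) && object@mBBT < 0) return("mBBT must be >= 0")
    TRUE
  })

#' One foraging trip
#'
#' A GPS track segment outside the colony radius with its dives and summary
#' metrics: cumulative track length, maximum great-circle distance from the
#' colony, and duration from first-dive onset to last-dive end.
#'
#' @slot individual character id.
#' @slot track [GpsTrack-class] restricted to the trip.
#' @slot dives data.frame, one row per dive (see [detectDives()]).
#' @slot lengthKm,maxDistanceKm numeric km.
#' @slot durationMin numeric minutes (`NA` when the trip holds no dives).
#' @exportClass ForagingTrip
setClass("ForagingTrip",
  representation(individual = "character", track = "GpsTrack",
                 dives = "data.frame", lengthKm = "numeric",
                 maxDistanceKm = "numeric", durationMin = "numeric"),
  validity = function(object) {
    if (object@lengthKm < 0 || object@maxDistanceKm < 0)
      return("distances must be >= 0")
    if (!is.na(object@durationMin) && object@durationMin <= 0)
      return("duration must be > 0")
    TRUE
  })

#' Configuration of the synthetic deployment generator
#'
#' Ground-truth parameters of the simulated colony: trip geometry, dive
#' depth structure, the true per-class ODBA-sum-vs-depth and
#' bottom-time-vs-depth laws, noise levels and sampling rates. A fixed
#' `seed` makes every generated object byte-identical across runs.
#'
#' Laws are lists `list(family =, coef =)` using the same family registry
#' as [fitOdbaDepth()].
#'
#' @slot seed integer RNG seed (R's default Mersenne-Twister).
#' @slot colony numeric `c(lon, lat)` degrees.
#' @slot nIndividuals integer number of simulated birds.
#' @slot tripLengthKm numeric target cumulative trip length, km.
#' @slot maxDiveDepth numeric deepest allowed dive, m.
#' @slot benthicFraction numeric target benthic fraction in `[0, 1]`.
#' @slot pelagicMedianDepth numeric median of the pelagic depth law, m.
#' @slot odbaLawBenthic,odbaLawPelagic true ODBA-sum laws (g-sample units).
#' @slot btLawBenthic,btLawPelagic true bottom-time laws (s).
#' @slot odbaNoiseSd,btNoiseSd multiplicative noise sd per law.
#' @slot descentSpeed,ascentSpeed vertical speeds, m s^-1.
#' @slot travelSpeed horizontal track speed, m s^-1.
#' @slot surfaceInterval mean post-dive surface interval, s.
#' @slot boutLength mean benthic/pelagic bout length, dives.
#' @slot accelRate,depthRate sampling rates, Hz.
#' @slot gpsInterval GPS fix interval, s.
#' @slot gpsJitterM GPS position noise sd, m.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(seed = "integer", colony = "numeric",
                 nIndividuals = "integer", tripLengthKm = "numeric",
                 maxDiveDepth = "numeric", benthicFraction = "numeric",
                 pelagicMedianDepth = "numeric",
                 odbaLawBenthic = "list", odbaLawPelagic = "list",
                 btLawBenthic = "list", btLawPelagic = "list",
                 odbaNoiseSd = "numeric", btNoiseSd = "numeric",
                 descentSpeed = "numeric", ascentSpeed = "numeric",
                 travelSpeed = "numeric", surfaceInterval = "numeric",
                 boutLength = "numeric", accelRate = "numeric",
                 depthRate = "numeric", gpsInterval = "numeric",
                 gpsJitterM = "numeric"),
  validity = function(object) {
    if (object@benthicFraction < 0 || object@benthicFraction > 1)
      return("benthicFraction must be in [0, 1]")
    sp <- c(object@descentSpeed, object@ascentSpeed, object@travelSpeed)
    if (any(sp <= 0)) return("speeds must be > 0")
    if (length(object@colony) != 2L) return("colony must be c(lon, lat)")
    for (lw in list(object@odbaLawBenthic, object@odbaLawPelagic,
                    object@btLawBenthic, object@btLawPelagic))
      if (!is.list(lw) || is.null(lw$family) || is.null(lw$coef) ||
          !lw$family %in% names(.regressionFamilies()))
        return("laws must be list(family=, coef=) with a known family")
    TRUE
  })

#' Energy landscape
#'
#' Per-cell TRC (total relative cost, J kg^-1 s^-1) over a bathymetry grid,
#' the IDW-interpolated raster, and run metadata (species parameters,
#' fitted models, interpolation settings).
#'
#' @slot cells data.frame with columns `lon, lat, depth, distance` (m),
#'   the energetic components, `TRC` and a logical `flagged` column
#'   (cells excluded from interpolation).
#' @slot raster data.frame `lon, lat, TRC` at the interpolation targets.
#' @slot metadata list.
#' @exportClass EnergyLandscape
setClass("EnergyLandscape",
  representation(cells = "data.frame", raster = "data.frame",
                 metadata = "list"),
  validity = function(object) {
    need <- c("lon", "lat", "depth", "distance", "TRC", "flagged")
    if (!all(need %in% names(object@cells)))
      return(paste("cells must contain columns:",
                   paste(need, collapse = ", ")))
    ok <- !object@cells$flagged
    if (any(ok) && any(object@cells$TRC[ok] <= 0, na.rm = TRUE))
      return("TRC must be > 0 on unflagged cells")
    TRUE
  })

#' Landscape summary at dive locations
#'
#' TRC values sampled at observed dive positions with median, range and a
#' histogram over fixed bin edges.
#'
#' @slot diveTrc numeric, one value per retained dive.
#' @slot median,range numeric summary (range is length 2).
#' @slot histBreaks,histCounts numeric histogram.
#' @slot nExcluded integer, dives outside the landscape extent.
#' @exportClass LandscapeSummary
setClass("LandscapeSummary",
  representation(diveTrc = "numeric", median = "numeric", range = "numeric",
                 histBreaks = "numeric", histCounts = "numeric",
                 nExcluded = "integer"),
  validity = function(object) {
    if (length(object@diveTrc)) {
      if (object@median < object@range[1] - 1e-12 ||
          object@median > object@range[2] + 1e-12)
        return("median must lie within the range")
      if (sum(object@histCounts) != length(object@diveTrc))
        return("histogram counts must sum to the number of retained dives")
    }
    TRUE
  })
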