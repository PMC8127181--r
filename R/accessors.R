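#' @include AllGenerics.R
NULL

#' @describeIn nSamples samples in an acceleration trace
#' @export
setMethod("nSamples", "AccelTrace", function(x) length(x@time))
#' @describeIn nSamples samples in a depth trace
#' @export
setMethod("nSamples", "DepthTrace", function(x) length(x@time))
#' @describeIn nSamples fixes in a GPS track
#' @export
setMethod("nSamples", "GpsTrack", function(x) length(x@time))
#' @describeIn nSamples marine cells in a bathymetry grid
#' @export
setMethod("nSamples", "BathymetryGrid", function(x) length(x@lon))

#' @describeIn timestamps acceleration trace timestamps
#' @export
setMethod("timestamps", "AccelTrace", function(x) x@time)
#' @describeIn timestamps depth trace timestamps
#' @export
setMethod("timestamps", "DepthTrace", function(x) x@time)
#' @describeIn timestamps GPS fix timestamps
#' @export
setMethod("timestamps", "GpsTrack", function(x) x@time)

#' @describeIn asTable acceleration trace as data.frame
#' @export
setMethod("asTable", "AccelTrace", function(x)
  data.frame(time = x@time, ax = x@ax, ay = x@ay, az = x@az))
#' @describeIn asTable depth trace as data.frame
#' @export
setMethod("asTable", "DepthTrace", function(x)
  data.frame(time = x@time, depth = x@depth))
#' @describeIn asTable GPS track as data.frame
#' @export
setMethod("asTable", "GpsTrack", function(x)
  data.frame(time = x@time, lon = x@lon, lat = x@lat))
#' @describeIn asTable bathymetry grid as data.frame
#' @export
setMethod("asTable", "BathymetryGrid", function(x)
  data.frame(lon = x@lon, lat = x@lat, depth = x@depth))

#' @describeIn landscapeCells cell table accessor
#' @export
setMethod("landscapeCells", "EnergyLandscape", function(x) x@cells)
#' @describeIn landscapeRaster raster accessor
#' @export
setMethod("landscapeRaster", "EnergyLandscape", function(x) x@raster)
#' @describeIn tripDives dive table accessor
#' @export
setMethod("tripDives", "ForagingTrip", function(x) x@dives)

.fmtSecs <- function(s) sprintf("%.1f s", s)

setMethod("show", "AccelTrace", function(object) {
  n <- length(object@time)
  rate <- if (n > 1) 1 / stats::median(diff(object@time)) else NA_real_
  cat("AccelTrace:", n, "samples @", round(rate, 2), "Hz, span",
      .fmtSecs(diff(range(object@time))), "\n")
})
setMethod("show", "DepthTrace", function(object) {
  cat("DepthTrace:", length(object@time), "samples, max depth",
      round(max(object@depth), 1), "m\n")
})
setMethod("show", "GpsTrack", function(object) {
  cat("GpsTrack:", length(object@time), "fixes, span",
      .fmtSecs(diff(range(object@time))), "\n")
})
setMethod("show", "BathymetryGrid", function(object) {
  cat("BathymetryGrid:", length(object@lon), "marine cells,",
      object@cellSize, "m cells, depth",
      paste(round(range(object@depth), 1), collapse = "-"), "m\n")
})
setMethod("show", "SpeciesParams", function(object) {
  cat(sprintf(paste0("SpeciesParams: BM %.2f kg, swim %.2f m/s, ",
                     "transport %.1f W/kg\n  Vo = %.3f + ODBA * %.3f ",
                     "(ml O2/min), %.3f J/s per ml/min\n"),
              object@BM, object@swimSpeed, object@transportCost,
              object@voIntercept, object@voSlope, object@o2ToPower))
})
setMethod("show", "RegressionModel", function(object) {
  cat(sprintf("RegressionModel [%s, %s]: %s ~ %s\n  coef: %s, R2 = %.4f, n = %d\n",
              object@diveClass, object@family, object@response,
              object@predictor,
              paste(sprintf("%s=%.5g", names(object@coef), object@coef),
                    collapse = ", "),
              object@r2, object@n))
})
setMethod("show", "TripStats", function(object) {
  cat(sprintf(paste0("TripStats: MND %.0f, pBD %.2f / pPD %.2f, ",
                     "DD %.0f/%.0f s (benthic/pelagic),\n  median pelagic ",
                     "depth %.1f m, mBBT %.0f s\n"),
              object@MND, object@pBD, object@pPD, object@DDbenthic,
              object@DDpelagic, object@medianPelagicDepth, object@mBBT))
})
setMethod("show", "ForagingTrip", function(object) {
  cat(sprintf("ForagingTrip [%s]: %.1f km, max dist %.1f km, %d dives\n",
              object@individual, object@lengthKm, object@maxDistanceKm,
              nrow(object@dives)))
})
setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: seed %d, %d individuals, trips ",
                     "~%.0f km,\n  benthic fraction %.2f, max depth %.0f m, ",
                     "pelagic median %.1f m\n"),
              object@seed, object@nIndividuals, object@tripLengthKm,
              object@benthicFraction, object@maxDiveDepth,
              object@pelagicMedianDepth))
})
setMethod("show", "EnergyLandscape", function(object) {
  ok <- !object@cells$flagged
  cat(sprintf(paste0("EnergyLandscape: %d cells (%d flagged), TRC ",
                     "%.1f-%.1f J/kg/s\n  raster: %d points\n"),
              nrow(object@cells), sum(!ok),
              min(object@cells$TRC[ok]), max(object@cells$TRC[ok]),
              nrow(object@raster)))
})
setMethod("show", "LandscapeSummary", function(object) {
  cat(sprintf(paste0("LandscapeSummary: %d dives (%d excluded), median ",
                     "TRC %.1f (range %.1f-%.1f) J/kg/s\n"),
              length(object@diveTrc), object@nExcluded, object@median,
              object@range[1], object@range[2]))
})
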