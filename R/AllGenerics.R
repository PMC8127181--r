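#' @include AllClasses.R
NULL

#' Number of samples or records in a trace-like object
#' @param x a trace, track or grid object.
#' @return integer count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Timestamps of a trace-like object
#' @param x a trace or track object.
#' @return numeric seconds.
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' Coerce a package object to a plain data.frame
#' @param x object.
#' @return data.frame.
#' @export
setGeneric("asTable", function(x) standardGeneric("asTable"))

#' Cell table of an energy landscape
#' @param x an [EnergyLandscape-class].
#' @return data.frame of cells with components and TRC.
#' @export
setGeneric("landscapeCells", function(x) standardGeneric("landscapeCells"))

#' IDW raster of an energy landscape
#' @param x an [EnergyLandscape-class].
#' @return data.frame `lon, lat, TRC`.
#' @export
setGeneric("landscapeRaster",
           function(x) standardGeneric("landscapeRaster"))

#' Dives of a foraging trip
#' @param x a [ForagingTrip-class].
#' @return data.frame, one row per dive.
#' @export
setGeneric("tripDives", function(x) standardGeneric("tripDives"))
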