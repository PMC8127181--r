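#' @include AllClasses.R
NULL

# ---- constructors ---------------------------------------------------------

#' Construct an acceleration trace
#' @param time numeric seconds (strictly increasing, constant rate).
#' @param ax,ay,az numeric acceleration in g (surge, sway, heave).
#' @return an [AccelTrace-class].
#' @export
AccelTrace <- function(time, ax, ay, az)
  new("AccelTrace", time = as.numeric(time), ax = as.numeric(ax),
      ay = as.numeric(ay), az = as.numeric(az))

#' Construct a depth trace
#' @param time numeric seconds.
#' @param depth numeric metres, positive down.
#' @return a [DepthTrace-class].
#' @export
DepthTrace <- function(time, depth)
  new("DepthTrace", time = as.numeric(time), depth = as.numeric(depth))

#' Construct a GPS track
#' @param time numeric seconds.
#' @param lon,lat numeric degrees.
#' @return a [GpsTrack-class].
#' @export
GpsTrack <- function(time, lon, lat)
  new("GpsTrack", time = as.numeric(time), lon = as.numeric(lon),
      lat = as.numeric(lat))

#' Construct a bathymetry grid from marine cells
#' @param lon,lat numeric degrees, cell centres.
#' @param depth numeric metres, positive down (> 0).
#' @param cellSize numeric metres.
#' @param crs character, only `"lonlat"` is currently supported.
#' @return a [BathymetryGrid-class].
#' @export
BathymetryGrid <- function(lon, lat, depth, cellSize, crs = "lonlat")
  new("BathymetryGrid", lon = as.numeric(lon), lat = as.numeric(lat),
      depth = as.numeric(depth), cellSize = as.numeric(cellSize), crs = crs)

# ---- time parsing ---------------------------------------------------------

# seconds as numeric; ISO-8601 strings are converted to epoch seconds (the
# timezone is reporting-level metadata, computations use seconds only)
.parseTime <- function(x, what = "time") {
  if (is.numeric(x)) return(as.numeric(x))
  t <- suppressWarnings(as.numeric(x))
  if (!anyNA(t)) return(t)
  p <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(p))
    stop("column '", what, "' is neither numeric seconds nor ISO-8601",
         call. = FALSE)
  as.numeric(p)
}

.checkMonotone <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop("non-monotone timestamps in '", path, "' at row ", bad[1] + 1L,
         call. = FALSE)
  t
}

.readCsvCols <- function(path, cols) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(cols), names(df))
  if (length(missing))
    stop("schema error: file '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

# ---- trace readers --------------------------------------------------------

#' Read an acceleration trace from CSV
#'
#' @param path CSV file with a header row.
#' @param cols named character map from internal names (`time, ax, ay, az`)
#'   to file column names.
#' @return an [AccelTrace-class].
#' @export
readAccelCsv <- function(path,
                         cols = c(time = "time", ax = "ax", ay = "ay",
                                  az = "az")) {
  df <- .readCsvCols(path, cols)
  t <- .checkMonotone(.parseTime(df[[cols[["time"]]]]), path)
  AccelTrace(t, df[[cols[["ax"]]]], df[[cols[["ay"]]]], df[[cols[["az"]]]])
}

#' Read a depth trace from CSV
#' @param path CSV file with a header row.
#' @param cols named map from `time, depth` to file column names.
#' @return a [DepthTrace-class].
#' @export
readDepthCsv <- function(path, cols = c(time = "time", depth = "depth")) {
  df <- .readCsvCols(path, cols)
  t <- .checkMonotone(.parseTime(df[[cols[["time"]]]]), path)
  DepthTrace(t, df[[cols[["depth"]]]])
}

#' Read a GPS track from CSV
#' @param path CSV file with a header row.
#' @param cols named map from `time, lon, lat` to file column names.
#' @return a [GpsTrack-class].
#' @export
readGpsCsv <- function(path,
                       cols = c(time = "time", lon = "lon", lat = "lat")) {
  df <- .readCsvCols(path, cols)
  t <- .checkMonotone(.parseTime(df[[cols[["time"]]]]), path)
  GpsTrack(t, df[[cols[["lon"]]]], df[[cols[["lat"]]]])
}

#' Read a full deployment (acceleration + depth + GPS)
#'
#' @param paths named list with elements `accel`, `depth`, `gps` (any may
#'   be omitted; omitted channels return `NULL`).
#' @param schema optional named list of per-channel column maps, see the
#'   individual readers.
#' @return list with elements `accel`, `depth`, `gps`.
#' @export
readTraces <- function(paths, schema = list()) {
  out <- list(accel = NULL, depth = NULL, gps = NULL)
  if (!is.null(paths$accel))
    out$accel <- do.call(readAccelCsv,
                         c(list(paths$accel), schema["accel"][[1]] %||% list()))
  if (!is.null(paths$depth))
    out$depth <- do.call(readDepthCsv,
                         c(list(paths$depth), schema["depth"][[1]] %||% list()))
  if (!is.null(paths$gps))
    out$gps <- do.call(readGpsCsv,
                       c(list(paths$gps), schema["gps"][[1]] %||% list()))
  for (ch in c("accel", "depth", "gps"))
    if (!is.null(out[[ch]]))
      message(ch, ": ", nSamples(out[[ch]]), " records from ", paths[[ch]])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- trace writers --------------------------------------------------------

# full-precision CSV so that write -> read is bitwise lossless
.writeFullPrecision <- function(df, path) {
  txt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(txt, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a trace, track or dive table to CSV at full float precision
#'
#' Values survive a write-then-read round trip bitwise.
#'
#' @param x an [AccelTrace-class], [DepthTrace-class], [GpsTrack-class]
#'   or data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTraceCsv <- function(x, path) {
  df <- if (is.data.frame(x)) x else asTable(x)
  .writeFullPrecision(df, path)
}

# ---- bathymetry -----------------------------------------------------------

#' Read a bathymetry grid from an xyz table
#'
#' Accepts whitespace- or comma-separated text with three columns
#' (lon, lat, depth/elevation), with or without a header. Depth is stored
#' positive-down; negative-elevation inputs (oceanographic DEM convention)
#' are negated on read when `positiveDown = FALSE`, or auto-detected when
#' `NA` (a grid whose median vertical value is negative is treated as
#' elevation). Cells that are on land after the sign convention
#' (depth <= 0) are dropped. GeoTIFF input is not supported; supply an
#' xyz export instead.
#'
#' @param path text file.
#' @param bbox optional `c(lonmin, lonmax, latmin, latmax)` filter.
#' @param cellSize cell edge in metres; inferred from the latitude spacing
#'   when `NULL`.
#' @param positiveDown logical or `NA` (auto).
#' @return a [BathymetryGrid-class].
#' @export
readBathymetry <- function(path, bbox = NULL, cellSize = NULL,
                           positiveDown = NA) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF input is not supported; export the raster to an xyz ",
         "table (lon lat depth) instead", call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[,[:space:]]+")[[1]][1])))
  df <- utils::read.table(path, header = header, sep = sep)
  if (ncol(df) < 3L)
    stop("xyz bathymetry needs three columns (lon, lat, depth)",
         call. = FALSE)
  lon <- df[[1]]; lat <- df[[2]]; z <- df[[3]]
  if (is.na(positiveDown)) positiveDown <- stats::median(z) >= 0
  if (!positiveDown) z <- -z
  if (!is.null(bbox)) {
    keep <- lon >= bbox[1] & lon <= bbox[2] & lat >= bbox[3] & lat <= bbox[4]
    lon <- lon[keep]; lat <- lat[keep]; z <- z[keep]
  }
  marine <- z > 0
  n <- sum(marine)
  if (n == 0L)
    stop("no marine cells ",
         if (!is.null(bbox)) "within the requested bbox" else "in the file",
         call. = FALSE)
  if (n < length(z))
    message(length(z) - n, " land/invalid cell(s) excluded")
  if (is.null(cellSize)) {
    ul <- sort(unique(lat[marine]))
    cellSize <- if (length(ul) > 1)
      stats::median(diff(ul)) * pi * 6371000 / 180 else 500
  }
  BathymetryGrid(lon[marine], lat[marine], z[marine], cellSize)
}

#' Write a bathymetry grid as a whitespace xyz table
#' @param grid a [BathymetryGrid-class].
#' @param path output file (header `lon lat depth`, positive-down).
#' @return `path`, invisibly.
#' @export
writeBathymetry <- function(grid, path) {
  lines <- c("lon lat depth",
             sprintf("%.17g %.17g %.17g", grid@lon, grid@lat, grid@depth))
  writeLines(lines, path)
  invisible(path)
}

# ---- model serialisation --------------------------------------------------

#' Write fitted regression models to YAML
#' @param models named list of [RegressionModel-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModelsYaml <- function(models, path) {
  ser <- lapply(models, function(m) list(
    response = m@response, predictor = m@predictor,
    diveClass = m@diveClass, family = m@family,
    coef = as.list(m@coef), r2 = m@r2, n = m@n,
    trainRange = m@trainRange))
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' Read regression models written by [writeModelsYaml()]
#' @param path YAML file.
#' @return named list of [RegressionModel-class] objects.
#' @export
readModelsYaml <- function(path) {
  ser <- yaml::read_yaml(path)
  lapply(ser, function(m)
    new("RegressionModel", response = m$response, predictor = m$predictor,
        diveClass = m$diveClass, family = m$family,
        coef = unlist(m$coef), r2 = m$r2, n = as.integer(m$n),
        trainRange = as.numeric(m$trainRange)))
}
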