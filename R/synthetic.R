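#' @include AllClasses.R
NULL

#' Configuration for the synthetic deployment generator
#'
#' Defaults describe a gentoo-like central-place forager during chick
#' guard: ~20 km looping foraging trips at 1 m s^-1 ground speed, dives to
#' at most 190 m, a benthic dive fraction of 0.35 with serial benthic
#' bouts, a left-shifted pelagic depth distribution with median 15 m,
#' trapezoidal dives with 1.5 m s^-1 vertical transit, 50 Hz tri-axial
#' accelerometry, 1 Hz depth and 5-min GPS sampling. The true per-class
#' ODBA-sum and bottom-time laws (the generator's ground truth, recovered
#' by the calibration module) default to a power law for benthic dive
#' cost and linear forms elsewhere, with 10% multiplicative noise.
#'
#' @param seed integer; fixes every generated byte.
#' @param colony `c(lon, lat)` degrees.
#' @param nIndividuals simulated birds.
#' @param tripLengthKm target cumulative trip length.
#' @param maxDiveDepth metres.
#' @param benthicFraction target benthic fraction in `[0, 1]`.
#' @param pelagicMedianDepth metres.
#' @param odbaLawBenthic,odbaLawPelagic,btLawBenthic,btLawPelagic true
#'   laws, `list(family =, coef =)` over the [fitBestModel()] registry.
#' @param odbaNoiseSd,btNoiseSd multiplicative noise sd (0 = noiseless).
#' @param descentSpeed,ascentSpeed,travelSpeed m s^-1.
#' @param surfaceInterval mean surface interval between dives, s.
#' @param boutLength mean length of benthic bouts, dives.
#' @param accelRate,depthRate Hz; gpsInterval s; gpsJitterM metres.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(seed = 1L,
                            colony = c(-61.10, -62.67),
                            nIndividuals = 8L,
                            tripLengthKm = 20,
                            maxDiveDepth = 190,
                            benthicFraction = 0.35,
                            pelagicMedianDepth = 15,
                            odbaLawBenthic = list(
                              family = "power", coef = c(a = 2.5, b = 1.05)),
                            odbaLawPelagic = list(
                              family = "linear", coef = c(a = 20, b = 4)),
                            btLawBenthic = list(
                              family = "linear", coef = c(a = 80, b = -0.15)),
                            btLawPelagic = list(
                              family = "linear", coef = c(a = 45, b = -0.3)),
                            odbaNoiseSd = 0.1,
                            btNoiseSd = 0.1,
                            descentSpeed = 1.5,
                            ascentSpeed = 1.5,
                            travelSpeed = 1.0,
                            surfaceInterval = 20,
                            boutLength = 5,
                            accelRate = 50,
                            depthRate = 1,
                            gpsInterval = 300,
                            gpsJitterM = 15) {
  new("SyntheticConfig", seed = as.integer(seed), colony = colony,
      nIndividuals = as.integer(nIndividuals),
      tripLengthKm = tripLengthKm, maxDiveDepth = maxDiveDepth,
      benthicFraction = benthicFraction,
      pelagicMedianDepth = pelagicMedianDepth,
      odbaLawBenthic = odbaLawBenthic, odbaLawPelagic = odbaLawPelagic,
      btLawBenthic = btLawBenthic, btLawPelagic = btLawPelagic,
      odbaNoiseSd = odbaNoiseSd, btNoiseSd = btNoiseSd,
      descentSpeed = descentSpeed, ascentSpeed = ascentSpeed,
      travelSpeed = travelSpeed, surfaceInterval = surfaceInterval,
      boutLength = boutLength, accelRate = accelRate,
      depthRate = depthRate, gpsInterval = gpsInterval,
      gpsJitterM = gpsJitterM)
}

# per-operation child seeds keep every generator call independently
# reproducible regardless of call order (base Mersenne-Twister RNG)
.childSeed <- function(config, op, individual = 0L) {
  offs <- c(trip = 1L, dives = 2L, accel = 3L, bathy = 4L)
  s <- (as.numeric(config@seed) * 48271 + offs[[op]] * 7919 +
          individual * 104729) %% 2147483647
  as.integer(s)
}

#' Generate a synthetic bathymetry grid
#'
#' A regular grid of cell centres around the colony with a radially
#' deepening seabed: `depth = nearDepth + gradientPerKm * distance`. A
#' shallow corridor (an angular sector whose depth is capped) and circular
#' shoal patches can be superimposed — these create the known low-cost
#' areas used to validate the landscape end to end. Purely deterministic
#' given the configuration.
#'
#' @param config a [SyntheticConfig-class].
#' @param extentKm half-width of the grid around the colony, km.
#' @param cellM cell size, metres (default the 500 m of polar bathymetric
#'   charts).
#' @param nearDepth seabed depth at the colony, m.
#' @param gradientPerKm m of depth per km of distance; default reaches
#'   `maxDiveDepth` at `extentKm`.
#' @param corridor optional `list(bearingDeg =, halfAngleDeg =, maxDepth =)`.
#' @param shoals optional list of `list(xKm =, yKm =, radiusKm =, depth =)`.
#' @return a [BathymetryGrid-class].
#' @export
generateBathymetry <- function(config, extentKm = 25, cellM = 500,
                               nearDepth = 15, gradientPerKm = NULL,
                               corridor = NULL, shoals = NULL) {
  if (cellM <= 0 || extentKm <= 0) stop("extent and cell must be > 0",
                                        call. = FALSE)
  if (cellM > extentKm * 1000)
    stop("cell size exceeds grid extent", call. = FALSE)
  if (is.null(gradientPerKm))
    gradientPerKm <- (config@maxDiveDepth - nearDepth) / extentKm
  half <- extentKm * 1000
  ax <- seq(-half + cellM / 2, half - cellM / 2, by = cellM)
  g <- expand.grid(x = ax, y = ax)
  distKm <- sqrt(g$x^2 + g$y^2) / 1000
  depth <- nearDepth + gradientPerKm * distKm
  if (!is.null(corridor)) {
    bearing <- atan2(g$x, g$y) * 180 / pi
    dAng <- abs(((bearing - corridor$bearingDeg + 180) %% 360) - 180)
    sel <- dAng <= corridor$halfAngleDeg
    depth[sel] <- pmin(depth[sel], corridor$maxDepth)
  }
  for (sh in shoals) {
    d <- sqrt((g$x / 1000 - sh$xKm)^2 + (g$y / 1000 - sh$yKm)^2)
    sel <- d <= sh$radiusKm
    depth[sel] <- pmin(depth[sel], sh$depth)
  }
  ll <- .offsetToLonLat(g$x, g$y, config@colony)
  BathymetryGrid(ll[, "lon"], ll[, "lat"], depth, cellM)
}

#' Generate a looping foraging trip
#'
#' A petal-shaped loop leaving and returning to the colony: radial
#' distance `R sin(pi t)` while the bearing swings through ~50 degrees,
#' scaled so the cumulative track length matches the configured trip
#' length scale. Fixes are placed at the GPS interval at constant ground
#' speed; interior fixes get isotropic position jitter, while the first
#' and last fix stay at the colony.
#'
#' @param config a [SyntheticConfig-class].
#' @param individual integer id (decides the loop bearing and RNG stream).
#' @return a [GpsTrack-class].
#' @export
generateTrip <- function(config, individual = 1L) {
  set.seed(.childSeed(config, "trip", individual))
  L <- config@tripLengthKm * 1000
  theta0 <- stats::runif(1, 0, 2 * pi)
  dTheta <- 0.9
  # unit petal, arc length by fine quadrature
  tt <- seq(0, 1, length.out = 4001)
  r <- sin(pi * tt)
  th <- theta0 + dTheta * (tt - 0.5)
  ux <- r * sin(th); uy <- r * cos(th)
  seg <- sqrt(diff(ux)^2 + diff(uy)^2)
  R <- L / sum(seg)
  arc <- c(0, cumsum(seg)) * R
  duration <- L / config@travelSpeed
  times <- seq(0, duration, by = config@gpsInterval)
  if (times[length(times)] < duration) times <- c(times, duration)
  sAt <- times * config@travelSpeed
  x <- stats::approx(arc, ux * R, xout = sAt, rule = 2)$y
  y <- stats::approx(arc, uy * R, xout = sAt, rule = 2)$y
  nfix <- length(times)
  if (nfix > 2L) {
    mid <- 2:(nfix - 1L)
    x[mid] <- x[mid] + stats::rnorm(length(mid), 0, config@gpsJitterM)
    y[mid] <- y[mid] + stats::rnorm(length(mid), 0, config@gpsJitterM)
  }
  ll <- .offsetToLonLat(x, y, config@colony)
  GpsTrack(times, ll[, "lon"], ll[, "lat"])
}

# seabed depth at arbitrary positions: bilinear on a complete regular
# grid (keeps the seabed smooth between cell centres, so serial benthic
# dives stay inside each other's intra-depth zone), nearest cell otherwise
.seabedAt <- function(grid, lon, lat) {
  us <- sort(unique(grid@lon)); vs <- sort(unique(grid@lat))
  if (length(us) > 1L && length(vs) > 1L &&
      length(us) * length(vs) == length(grid@lon)) {
    z <- matrix(NA_real_, length(vs), length(us))
    z[cbind(match(grid@lat, vs), match(grid@lon, us))] <- grid@depth
    i <- pmin(pmax(findInterval(lon, us), 1L), length(us) - 1L)
    j <- pmin(pmax(findInterval(lat, vs), 1L), length(vs) - 1L)
    wx <- pmin(pmax((lon - us[i]) / (us[i + 1L] - us[i]), 0), 1)
    wy <- pmin(pmax((lat - vs[j]) / (vs[j + 1L] - vs[j]), 0), 1)
    return((1 - wy) * ((1 - wx) * z[cbind(j, i)] +
                         wx * z[cbind(j, i + 1L)]) +
             wy * ((1 - wx) * z[cbind(j + 1L, i)] +
                     wx * z[cbind(j + 1L, i + 1L)]))
  }
  vapply(seq_along(lon), function(k) {
    d <- greatCircleDistance(lon[k], lat[k], grid@lon, grid@lat)
    grid@depth[which.min(d)]
  }, numeric(1))
}

#' Generate a 1 Hz dive series along a trip
#'
#' Sequential trapezoidal dives (constant-rate descent, flat bottom
#' plateau, constant-rate ascent) separated by surface intervals.
#' Benthic/pelagic labels are generated first — serial benthic bouts with
#' mean length `boutLength`, steered so the realized benthic fraction
#' tracks the configured target — and the geometry follows: benthic dives
#' reach the local seabed depth at the dive's position (clipped to the
#' configured maximum with a warning), pelagic dives sample a left-shifted
#' (log-normal) depth distribution whose median is the configured pelagic
#' median, rejected out of the preceding dive's intra-depth zone so the
#' generated labels stay recoverable. Bottom plateau durations follow the
#' class's true bottom-time law (plus multiplicative noise), quantised to
#' the 1 Hz depth grid.
#'
#' @param config a [SyntheticConfig-class].
#' @param track a [GpsTrack-class] inside the grid.
#' @param grid a [BathymetryGrid-class].
#' @param individual integer id (RNG stream).
#' @return list with `depth` (a [DepthTrace-class]) and `truth` (a
#'   data.frame with one row per dive: `start, end, class, maxDepth,
#'   bottomTime, odbaTarget, lon, lat` — the generator's ground truth).
#' @export
generateDiveSeries <- function(config, track, grid, individual = 1L) {
  force(track); force(grid)  # promises must not fire after the seed is set
  set.seed(.childSeed(config, "dives", individual))
  t0 <- min(track@time); t1 <- max(track@time)
  vD <- config@descentSpeed; vA <- config@ascentSpeed
  f <- config@benthicFraction
  posAt <- function(tm) c(
    stats::approx(track@time, track@lon, xout = tm, rule = 2)$y,
    stats::approx(track@time, track@lat, xout = tm, rule = 2)$y)

  depthSamples <- list(); truth <- list()
  tcur <- t0 + 600
  state <- stats::runif(1) < f
  prevDepth <- NA_real_
  nBen <- 0L; nTot <- 0L
  clipped <- 0L
  while (TRUE) {
    # label first (bout persistence + steering toward the target fraction)
    if (nTot > 0L) {
      realized <- nBen / nTot
      if (nTot >= 20L && abs(realized - f) > 0.03) {
        state <- realized < f
      } else if (stats::runif(1) < 1 / config@boutLength) {
        state <- if (state) FALSE else stats::runif(1) < f / (1 - f + 1e-12)
      }
    }
    if (f >= 1) state <- TRUE
    if (f <= 0) state <- FALSE
    pos <- posAt(tcur)
    seabed <- .seabedAt(grid, pos[1], pos[2])
    if (state) {
      depth <- seabed
      if (depth > config@maxDiveDepth) {
        depth <- config@maxDiveDepth
        clipped <- clipped + 1L
      }
      law <- config@btLawBenthic; noiseSd <- config@btNoiseSd
    } else {
      upper <- min(config@maxDiveDepth, 0.9 * seabed)
      for (try in 1:30) {
        depth <- stats::rlnorm(1, log(config@pelagicMedianDepth), 0.5)
        if (depth < 8) next
        if (depth > upper) next
        if (!is.na(prevDepth) &&
            depth >= 0.88 * prevDepth && depth <= 1.12 * prevDepth) next
        break
      }
      depth <- min(max(depth, 8), upper)
      law <- config@btLawPelagic; noiseSd <- config@btNoiseSd
    }
    bt <- .evalLaw(law, depth) * (1 + stats::rnorm(1, 0, noiseSd))
    bt <- max(6, round(bt))
    down <- seq(vD, depth, by = vD)
    if (down[length(down)] < depth) down <- c(down, depth)
    up <- rev(seq(vA, depth, by = vA))
    if (up[1] < depth) up <- c(depth, up)
    up <- up[-1]  # plateau already holds max depth
    profile <- c(down, rep(depth, bt), up)
    nd <- length(profile)
    if (tcur + nd + 30 > t1 - 600) break
    times <- tcur + seq_len(nd) - 1
    depthSamples[[length(depthSamples) + 1L]] <-
      cbind(time = times, depth = profile)
    mid <- posAt((times[1] + times[nd]) / 2)
    odbaLaw <- if (state) config@odbaLawBenthic else config@odbaLawPelagic
    truth[[length(truth) + 1L]] <- data.frame(
      start = times[1], end = times[nd] + 1, class = if (state) "benthic"
        else "pelagic",
      maxDepth = depth, bottomTime = bt,
      odbaTarget = .evalLaw(odbaLaw, depth) *
        (1 + stats::rnorm(1, 0, config@odbaNoiseSd)),
      lon = mid[1], lat = mid[2])
    nTot <- nTot + 1L; if (state) nBen <- nBen + 1L
    prevDepth <- depth
    surf <- max(5, round(config@surfaceInterval * stats::runif(1, 0.5, 1.5)))
    tcur <- times[nd] + 1 + surf
  }
  if (clipped)
    warning(clipped, " benthic dive(s) deeper than the configured maximum;",
            " clipped", call. = FALSE)
  truth <- do.call(rbind, truth)
  # continuous 1 Hz trace with surface zeros between dives
  allT <- seq(t0, t1, by = 1 / config@depthRate)
  d <- numeric(length(allT))
  for (blk in depthSamples) {
    idx <- match(blk[, "time"], allT)
    d[idx] <- blk[, "depth"]
  }
  list(depth = DepthTrace(allT, d), truth = truth)
}

#' Generate a 50 Hz tri-axial acceleration trace for a dive series
#'
#' The trace is a fixed 1 g static gravity vector plus a zero-mean dynamic
#' component confined to the dives: a square-wave stroking signal on the
#' surge axis whose period (0.2 s) divides the 1 s ODBA smoothing window.
#' Each dive's amplitude is calibrated through a unit-amplitude ODBA pass
#' so that the per-dive ODBA sum recovered by [computeOdba()] +
#' [diveOdbaSum()] equals the dive's `odbaTarget` from the generator's
#' truth table exactly (ODBA is exactly linear in the dynamic amplitude).
#' An optional slow sinusoidal rotation of the gravity vector exercises
#' the static-subtraction under posture change.
#'
#' @param config a [SyntheticConfig-class].
#' @param depth the [DepthTrace-class] from [generateDiveSeries()].
#' @param truth the matching truth table (`start, end, odbaTarget`).
#' @param staticRotation amplitude (radians) of a slow (300 s period)
#'   gravity rotation in the surge-heave plane; 0 keeps the orientation
#'   fixed.
#' @return an [AccelTrace-class].
#' @export
generateAccel <- function(config, depth, truth, staticRotation = 0) {
  rate <- config@accelRate
  t <- seq(min(depth@time), max(depth@time), by = 1 / rate)
  n <- length(t)
  phi <- if (staticRotation > 0)
    staticRotation * sin(2 * pi * t / 300) else rep(0, n)
  sx <- sin(phi); sz <- cos(phi)
  period <- max(2L, as.integer(round(rate / 5)))   # 0.2 s
  wave <- rep_len(rep(c(1, -1), each = period %/% 2L), n)
  dyn <- numeric(n)
  for (i in seq_len(nrow(truth))) {
    idx <- which(t >= truth$start[i] & t <= truth$end[i])
    dyn[idx] <- wave[idx]
  }
  unitTrace <- AccelTrace(t, sx + dyn, numeric(n), sz)
  unitOdba <- computeOdba(unitTrace, window = 1)
  for (i in seq_len(nrow(truth))) {
    idx <- which(t >= truth$start[i] & t <= truth$end[i])
    u <- sum(unitOdba@odba[idx])
    dyn[idx] <- dyn[idx] * (truth$odbaTarget[i] / u)
  }
  AccelTrace(t, sx + dyn, numeric(n), sz)
}

#' Simulate a full colony deployment
#'
#' Bathymetry plus, for each individual, a GPS trip, a 1 Hz dive series
#' and a 50 Hz acceleration trace, with the generator's ground truth
#' (per-dive labels, depths, bottom times, target ODBA sums and the true
#' laws) returned alongside so downstream recovery can be scored.
#'
#' @param config a [SyntheticConfig-class].
#' @param grid optional pre-built [BathymetryGrid-class]; generated with
#'   defaults when `NULL`.
#' @param accel generate acceleration traces (the slowest channel); set
#'   `FALSE` when only depth/GPS are needed.
#' @param ... passed to [generateBathymetry()] when `grid` is `NULL`.
#' @return list with `grid`, `config`, `trueLaws` and `individuals` (each
#'   a list `track, depth, accel, truth`).
#' @export
simulateDeployment <- function(config, grid = NULL, accel = TRUE, ...) {
  if (is.null(grid)) grid <- generateBathymetry(config, ...)
  individuals <- lapply(seq_len(config@nIndividuals), function(id) {
    track <- generateTrip(config, id)
    ds <- generateDiveSeries(config, track, grid, id)
    acc <- if (accel) generateAccel(config, ds$depth, ds$truth) else NULL
    list(individual = paste0("bird", id), track = track,
         depth = ds$depth, accel = acc, truth = ds$truth)
  })
  list(grid = grid, config = config,
       trueLaws = list(odbaBenthic = config@odbaLawBenthic,
                       odbaPelagic = config@odbaLawPelagic,
                       btBenthic = config@btLawBenthic,
                       btPelagic = config@btLawPelagic),
       individuals = individuals)
}
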