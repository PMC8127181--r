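# Naive reference implementations, kept deliberately independent of the
# package code paths (plain loops, own haversine formula). Used to verify
# the vectorised/optimised implementations on random instances.

refHaversine <- function(lon1, lat1, lon2, lat2, r = 6371000) {
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad
  dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# dive segmentation by direct scan over samples
refDetectDives <- function(time, depth, threshold = 3, surface = 1) {
  n <- length(time)
  dt <- if (n > 1) stats::median(diff(time)) else 1
  out <- list()
  i <- 1L
  while (i <= n) {
    if (depth[i] > surface) {
      j <- i
      while (j < n && depth[j + 1L] > surface) j <- j + 1L
      md <- max(depth[i:j])
      if (md > threshold) {
        end <- if (j < n) time[j + 1L] else time[j] + dt
        out[[length(out) + 1L]] <- c(start = time[i], end = end,
                                     maxDepth = md)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out)) do.call(rbind, out) else
    matrix(numeric(0), ncol = 3,
           dimnames = list(NULL, c("start", "end", "maxDepth")))
}

# intra-depth-zone labels by explicit loop
refClassifyIdz <- function(maxDepths, band = 0.10, firstClass = "pelagic") {
  n <- length(maxDepths)
  cls <- character(n)
  if (n == 0L) return(cls)
  cls[1L] <- firstClass
  for (i in seq_len(n)[-1L]) {
    lo <- (1 - band) * maxDepths[i - 1L]
    hi <- (1 + band) * maxDepths[i - 1L]
    cls[i] <- if (maxDepths[i] >= lo && maxDepths[i] <= hi)
      "benthic" else "pelagic"
  }
  cls
}

# ODBA with an O(n*k) moving average written as plain loops
refOdba <- function(ax, ay, az, k) {
  n <- length(ax)
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  sm <- function(x) {
    if (k >= n) return(rep(mean(x), n))
    vapply(seq_len(n), function(i)
      mean(x[max(1L, i - left):min(n, i + right)]), numeric(1))
  }
  abs(ax - sm(ax)) + abs(ay - sm(ay)) + abs(az - sm(az))
}

# all-pairs Shepard interpolation by loop
refIdw <- function(sLon, sLat, v, tLon, tLat, p = 2) {
  vapply(seq_along(tLon), function(i) {
    d <- refHaversine(tLon[i], tLat[i], sLon, sLat)
    if (any(d < 1e-3)) return(v[which.min(d)])
    w <- d^(-p)
    sum(w * v) / sum(w)
  }, numeric(1))
}

# a clean trapezoidal dive profile at 1 Hz (surface-padded)
makeTrapezoid <- function(depth, descentS, bottomS, ascentS, pad = 10L) {
  down <- seq_len(descentS) * (depth / descentS)
  up <- rev(seq_len(ascentS - 1L)) * (depth / ascentS)
  d <- c(rep(0, pad), down, rep(depth, bottomS), up, rep(0, pad))
  DepthTrace(seq_along(d) - 1, d)
}

# random surface/dive depth walk for segmentation fuzzing
randomDepthTrace <- function(n = 120L) {
  d <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- max(0, cur + stats::rnorm(1, 0, 2.5))
    if (stats::runif(1) < 0.15) cur <- 0
    d[i] <- cur
  }
  DepthTrace(seq_len(n) - 1, d)
}

handLinearModel <- function(a, b, response = "y", diveClass = "all",
                            trainRange = c(3, 200)) {
  new("RegressionModel", response = response, predictor = "maxDepth",
      diveClass = diveClass, family = "linear", coef = c(a = a, b = b),
      r2 = 1, n = 10L, trainRange = trainRange)
}

toyModels <- function() list(
  odbaBenthic = handLinearModel(10, 2, "odbaSum", "benthic"),
  odbaPelagic = handLinearModel(5, 1, "odbaSum", "pelagic"),
  btBenthic = handLinearModel(60, -0.1, "bottomTime", "benthic"),
  btPelagic = handLinearModel(40, -0.2, "bottomTime", "pelagic"),
  divesDistance = new("RegressionModel", response = "nDives",
                      predictor = "maxDistanceKm", diveClass = "all",
                      family = "linear", coef = c(a = 50, b = 5), r2 = 1,
                      n = 10L, trainRange = c(0, 40)))

toyStats <- function() new("TripStats", MND = 300, pBD = 0.3, pPD = 0.7,
                           DDbenthic = 90, DDpelagic = 60,
                           medianPelagicDepth = 15, mBBT = 23)
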