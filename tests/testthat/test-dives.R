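test_that("dives are only accepted strictly deeper than the threshold", {
  shallow <- DepthTrace(0:20, c(0, rep(2.9, 19), 0))
  expect_equal(nrow(detectDives(shallow)), 0L)
  exactly3 <- DepthTrace(0:20, c(0, rep(3, 19), 0))
  expect_equal(nrow(detectDives(exactly3)), 0L)
  deeper <- DepthTrace(0:20, c(0, rep(3.01, 19), 0))
  expect_equal(nrow(detectDives(deeper)), 1L)
  expect_equal(nrow(detectDives(DepthTrace(numeric(0), numeric(0)))), 0L)
})

test_that("a trapezoid dive is segmented with the right depth and duration", {
  tr <- makeTrapezoid(50, descentS = 10, bottomS = 100, ascentS = 10)
  dv <- detectDives(tr)
  expect_equal(nrow(dv), 1L)
  expect_equal(dv$maxDepth, 50)
  expect_equal(dv$duration, 120, tolerance = 0.02)
})

test_that("dives separated by a surface interval stay separate events", {
  one <- asTable(makeTrapezoid(30, 5, 40, 5, pad = 5L))$depth
  d <- c(one, rep(0, 10), one)
  dv <- detectDives(DepthTrace(seq_along(d) - 1, d))
  expect_equal(nrow(dv), 2L)
})

test_that("segmentation agrees with the brute-force scan on random traces", {
  set.seed(21)
  for (rep in 1:200) {
    tr <- randomDepthTrace(100L)
    got <- detectDives(tr)
    ref <- refDetectDives(tr@time, tr@depth)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start, unname(ref[, "start"]))
      expect_equal(got$end, unname(ref[, "end"]))
      expect_equal(got$maxDepth, unname(ref[, "maxDepth"]))
    }
  }
})

test_that("bottom phase spans descent end to ascent start", {
  tr <- makeTrapezoid(50, descentS = 10, bottomS = 60, ascentS = 10)
  dv <- detectDives(tr)
  bp <- bottomPhase(tr@time[dv$istart:dv$iend], tr@depth[dv$istart:dv$iend])
  expect_equal(bp$bottomTime, 60, tolerance = 1)
  # strict V dive
  v <- DepthTrace(0:20, c(0, seq(5, 50, by = 5), seq(45, 5, by = -5), 0))
  dvv <- detectDives(v)
  bpv <- bottomPhase(v@time[dvv$istart:dvv$iend], v@depth[dvv$istart:dvv$iend])
  expect_equal(bpv$bottomTime, 0)
})

test_that("bottom time stays within 10% of the plateau under depth noise", {
  set.seed(22)
  ok <- 0L
  for (rep in 1:30) {
    d <- c(rep(0, 5), seq(5, 50, by = 5), rep(50, 60), seq(45, 5, by = -5),
           rep(0, 5))
    noise <- rnorm(length(d), 0, 0.2)
    noise[d == 0] <- 0
    tr <- DepthTrace(seq_along(d) - 1, pmax(0, d + noise))
    dv <- detectDives(tr)
    bp <- bottomPhase(tr@time[dv$istart[1]:dv$iend[1]],
                      tr@depth[dv$istart[1]:dv$iend[1]])
    if (abs(bp$bottomTime - 60) <= 6) ok <- ok + 1L
  }
  expect_gte(ok, 28L)
})

test_that("IDZ classification follows the +/-10% band of the previous dive", {
  dv <- data.frame(maxDepth = c(100, 95))
  expect_equal(classifyIdz(dv)$class, c("pelagic", "benthic"))
  dv2 <- data.frame(maxDepth = c(100, 80))
  expect_equal(classifyIdz(dv2)$class, c("pelagic", "pelagic"))
  single <- data.frame(maxDepth = 40)
  expect_equal(classifyIdz(single)$class, "pelagic")
  expect_equal(classifyIdz(single, firstDiveClass = "benthic")$class,
               "benthic")
  set.seed(23)
  for (rep in 1:100) {
    depths <- runif(30, 5, 150)
    got <- classifyIdz(data.frame(maxDepth = depths))$class
    expect_identical(got, refClassifyIdz(depths))
  }
})

test_that("dives are georeferenced by time-interpolation between fixes", {
  track <- GpsTrack(c(0, 600), c(0, 0.01), c(0, 0))
  dv <- data.frame(start = c(290, 140), end = c(310, 160))
  got <- georeferenceDives(dv, track)
  expect_equal(got$lon, c(0.005, 0.0025))
  early <- data.frame(start = -100, end = -80)
  expect_warning(got2 <- georeferenceDives(early, track), "outside")
  expect_equal(got2$lon, 0)
})

test_that("trip metrics use great-circle geometry", {
  colony <- c(0, 0)
  # out-and-back along the equator to 10 km
  lons <- c(seq(0, 10, by = 2), seq(8, 0, by = -2)) / 111.194927
  track <- GpsTrack(seq_along(lons) * 300, lons, rep(0, length(lons)))
  dives <- data.frame(start = 400, end = 3000)
  trip <- tripMetrics(track, dives, colony)
  expect_equal(trip@lengthKm, 20, tolerance = 0.001)
  expect_equal(trip@maxDistanceKm, 10, tolerance = 0.001)
  # one degree of longitude on the equator
  expect_equal(greatCircleDistance(0, 0, 1, 0) / 1000, 111.19, tolerance = 1e-4)
  still <- GpsTrack(c(0, 300), c(0, 0), c(0, 0))
  expect_warning(t2 <- tripMetrics(still, dives[0, , drop = FALSE], colony),
                 "no dives")
  expect_equal(t2@lengthKm, 0)
  expect_equal(t2@maxDistanceKm, 0)
  expect_true(is.na(t2@durationMin))
})

test_that("great-circle distance is a metric on random triples", {
  set.seed(24)
  for (rep in 1:200) {
    p <- matrix(c(runif(3, -179, 179), runif(3, -89, 89)), ncol = 2)
    d12 <- greatCircleDistance(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d21 <- greatCircleDistance(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d13 <- greatCircleDistance(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d23 <- greatCircleDistance(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-6)
  }
  expect_equal(greatCircleDistance(10, -20, 10, -20), 0)
})

test_that("trips split at the colony radius", {
  colony <- c(0, 0)
  r <- c(0, 0.001, 0.02, 0.03, 0.001, 0, 0.025, 0.001)  # degrees lon
  track <- GpsTrack(seq_along(r) * 300, r, rep(0, length(r)))
  segs <- splitTrips(track, colony, radiusM = 200)
  expect_equal(length(segs), 2L)
  expect_equal(nSamples(segs[[1]]), 2L)
})

test_that("trip statistics aggregate medians over first trips", {
  mkTrip <- function(id, nDives, t0 = 0, pBen = 0.4) {
    nb <- round(nDives * pBen)
    dv <- data.frame(
      start = t0 + seq_len(nDives) * 100,
      end = t0 + seq_len(nDives) * 100 + 80,
      duration = rep(c(80, 60), length.out = nDives),
      maxDepth = rep(c(50, 15), length.out = nDives),
      bottomTime = rep(c(40, 25), length.out = nDives),
      class = c(rep("benthic", nb), rep("pelagic", nDives - nb)))
    track <- GpsTrack(t0 + c(0, nDives * 100 + 100), c(0.01, 0.02), c(0, 0))
    new("ForagingTrip", individual = id, track = track, dives = dv,
        lengthKm = 5, maxDistanceKm = 2, durationMin = nDives * 100 / 60)
  }
  trips <- list(mkTrip("a", 10), mkTrip("b", 20), mkTrip("c", 30))
  st <- tripStatistics(trips)
  expect_equal(st@MND, 20)
  expect_equal(st@pBD + st@pPD, 1, tolerance = 1e-12)
  # second trips of the same bird are ignored
  st2 <- tripStatistics(c(trips, list(mkTrip("a", 500, t0 = 1e6))))
  expect_equal(st2@MND, 20)
  # single trip: stats equal direct computation
  one <- tripStatistics(list(mkTrip("a", 10)))
  dv <- tripDives(mkTrip("a", 10))
  expect_equal(one@MND, 10)
  expect_equal(one@pBD, 0.4)
  expect_equal(one@mBBT, min(dv$bottomTime[dv$class == "benthic"]))
  expect_equal(one@medianPelagicDepth,
               median(dv$maxDepth[dv$class == "pelagic"]))
  # no benthic dives
  allP <- mkTrip("a", 10, pBen = 0)
  stp <- tripStatistics(list(allP))
  expect_equal(stp@pBD, 0)
  expect_true(is.na(stp@mBBT))
})
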