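test_that("synthetic bathymetry is deterministic, radial and validated", {
  cfg <- syntheticConfig(seed = 3)
  flat <- generateBathymetry(cfg, extentKm = 5, cellM = 1000,
                             nearDepth = 80, gradientPerKm = 0)
  expect_true(all(flat@depth == 80))
  g1 <- generateBathymetry(cfg, extentKm = 5, cellM = 1000)
  g2 <- generateBathymetry(cfg, extentKm = 5, cellM = 1000)
  expect_identical(asTable(g1), asTable(g2))
  d <- gridDistances(g1, cfg@colony)
  ord <- order(d)
  expect_true(all(diff(g1@depth[ord]) > -1e-9))
  expect_error(generateBathymetry(cfg, extentKm = 1, cellM = 2000),
               "exceeds")
  withCorridor <- generateBathymetry(cfg, extentKm = 5, cellM = 1000,
                                     corridor = list(bearingDeg = 0,
                                                     halfAngleDeg = 20,
                                                     maxDepth = 30))
  expect_lt(min(withCorridor@depth), min(g1@depth) + 30)
})

test_that("generated trips are colony-closed loops of the configured length", {
  cfg <- syntheticConfig(seed = 4, tripLengthKm = 20)
  tr <- generateTrip(cfg, 1)
  tab <- asTable(tr)
  n <- nrow(tab)
  len <- sum(greatCircleDistance(tab$lon[-n], tab$lat[-n],
                                 tab$lon[-1], tab$lat[-1])) / 1000
  expect_gte(len, 18); expect_lte(len, 22)
  dEnds <- greatCircleDistance(tab$lon[c(1, n)], tab$lat[c(1, n)],
                               cfg@colony[1], cfg@colony[2])
  expect_true(all(dEnds < 50))
  expect_identical(asTable(generateTrip(cfg, 1)), tab)
  expect_false(identical(asTable(generateTrip(cfg, 2)), tab))
})

test_that("benthic dives track the seabed and pelagic depths match the target", {
  cfg <- syntheticConfig(seed = 6, benthicFraction = 1, tripLengthKm = 15)
  flat <- generateBathymetry(cfg, extentKm = 12, cellM = 1000,
                             nearDepth = 80, gradientPerKm = 0)
  tr <- generateTrip(cfg, 1)
  ds <- generateDiveSeries(cfg, tr, flat, 1)
  expect_true(all(ds$truth$class == "benthic"))
  expect_true(all(abs(ds$truth$maxDepth - 80) < 1e-9))

  cfgP <- syntheticConfig(seed = 6, benthicFraction = 0, tripLengthKm = 35,
                          pelagicMedianDepth = 15)
  deep <- generateBathymetry(cfgP, extentKm = 20, cellM = 1000,
                             nearDepth = 120, gradientPerKm = 2)
  trP <- generateTrip(cfgP, 1)
  dsP <- generateDiveSeries(cfgP, trP, deep, 1)
  expect_true(all(dsP$truth$class == "pelagic"))
  expect_gte(nrow(dsP$truth), 300L)
  expect_lt(abs(median(dsP$truth$maxDepth) - 15) / 15, 0.2)
})

test_that("descent takes depth / speed seconds", {
  cfg <- syntheticConfig(seed = 8, benthicFraction = 1, descentSpeed = 1,
                         tripLengthKm = 15)
  flat <- generateBathymetry(cfg, extentKm = 12, cellM = 1000,
                             nearDepth = 50, gradientPerKm = 0)
  tr <- generateTrip(cfg, 1)
  ds <- generateDiveSeries(cfg, tr, flat, 1)
  first <- ds$truth[1, ]
  idx <- which(ds$depth@time >= first$start & ds$depth@time < first$end)
  prof <- ds$depth@depth[idx]
  descentLen <- which.max(prof >= 50) - 1L
  expect_equal(descentLen, 50, tolerance = 0.05)
})

test_that("the realized benthic fraction stays within 5 points of target", {
  cfg <- syntheticConfig(seed = 9, tripLengthKm = 30, benthicFraction = 0.35)
  grid <- generateBathymetry(cfg, extentKm = 20, cellM = 1000)
  tr <- generateTrip(cfg, 1)
  ds <- generateDiveSeries(cfg, tr, grid, 1)
  expect_gte(nrow(ds$truth), 200L)
  expect_lt(abs(mean(ds$truth$class == "benthic") - 0.35), 0.05)
  # serial benthic dives stay inside each other's intra-depth zone
  tru <- ds$truth
  runPairs <- which(tru$class == "benthic" &
                      c(FALSE, head(tru$class, -1) == "benthic"))
  ratio <- tru$maxDepth[runPairs] / tru$maxDepth[runPairs - 1L]
  expect_true(all(ratio >= 0.9 & ratio <= 1.1))
})

test_that("noiseless acceleration reproduces the true ODBA law end to end", {
  cfg <- syntheticConfig(seed = 10, odbaNoiseSd = 0, btNoiseSd = 0,
                         tripLengthKm = 8)
  grid <- generateBathymetry(cfg, extentKm = 8, cellM = 1000)
  tr <- generateTrip(cfg, 1)
  ds <- generateDiveSeries(cfg, tr, grid, 1)
  acc <- generateAccel(cfg, ds$depth, ds$truth)
  odba <- computeOdba(acc)
  for (i in seq_len(nrow(ds$truth))) {
    got <- diveOdbaSum(odba, ds$truth$start[i], ds$truth$end[i])
    law <- if (ds$truth$class[i] == "benthic") cfg@odbaLawBenthic else
      cfg@odbaLawPelagic
    want <- law$coef[1] * ds$truth$maxDepth[i]^law$coef[2]
    if (law$family == "linear")
      want <- law$coef[1] + law$coef[2] * ds$truth$maxDepth[i]
    expect_equal(got, unname(want), tolerance = 1e-6)
  }
})

test_that("zero dynamic amplitude gives zero ODBA; traces are reproducible", {
  cfg <- syntheticConfig(seed = 11, tripLengthKm = 8)
  grid <- generateBathymetry(cfg, extentKm = 8, cellM = 1000)
  tr <- generateTrip(cfg, 1)
  ds <- generateDiveSeries(cfg, tr, grid, 1)
  flatTruth <- ds$truth
  flatTruth$odbaTarget <- 0
  acc0 <- generateAccel(cfg, ds$depth, flatTruth)
  expect_lt(max(computeOdba(acc0)@odba), 1e-9)
  a1 <- generateAccel(cfg, ds$depth, ds$truth)
  a2 <- generateAccel(cfg, ds$depth, ds$truth)
  expect_identical(asTable(a1), asTable(a2))
  # slow gravity rotation leaves per-dive sums nearly unchanged
  a3 <- generateAccel(cfg, ds$depth, ds$truth, staticRotation = 0.2)
  o3 <- computeOdba(a3)
  s1 <- diveOdbaSum(computeOdba(a1), ds$truth$start[1], ds$truth$end[1])
  s3 <- diveOdbaSum(o3, ds$truth$start[1], ds$truth$end[1])
  expect_equal(s3, s1, tolerance = 0.01)
})

test_that("a fixed seed makes the whole deployment byte-identical", {
  cfg <- syntheticConfig(seed = 12, nIndividuals = 1, tripLengthKm = 6)
  s1 <- simulateDeployment(cfg, extentKm = 6, cellM = 1000)
  s2 <- simulateDeployment(cfg, extentKm = 6, cellM = 1000)
  expect_identical(s1$individuals[[1]]$truth, s2$individuals[[1]]$truth)
  expect_identical(asTable(s1$individuals[[1]]$accel),
                   asTable(s2$individuals[[1]]$accel))
  expect_identical(asTable(s1$grid), asTable(s2$grid))
})
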