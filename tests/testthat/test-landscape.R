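test_that("grid distances are great-circle distances from the colony", {
  g <- BathymetryGrid(c(0, 1, -1), c(0, 0, 0), c(50, 100, 100), 500)
  d <- gridDistances(g, c(0, 0))
  expect_equal(d[1], 0)
  expect_equal(d[2], 111194.9, tolerance = 1e-6)
  expect_equal(d[2], d[3])
})

test_that("cell TRC matches an independent spreadsheet-style computation", {
  models <- toyModels()
  stats <- toyStats()
  sp <- speciesParams(BM = 5.2)
  depth <- 80; dist <- 12000
  got <- cellTrc(depth, dist, models, stats, sp, warnExtrapolation = FALSE)
  # manual chain with plain arithmetic
  mp <- function(odba) (sp@voIntercept + sp@voSlope * odba) * 0.333 / 5.2
  mpB3 <- mp(10 + 2 * 3);  mpBD <- mp(10 + 2 * depth)
  mpP3 <- mp(5 + 1 * 3);   mpPD <- mp(5 + 1 * 15)
  MND <- 300
  mb <- 90 * (mpB3 + mpBD) * MND / 2 * 0.3
  mpnd <- 60 * (mpP3 + mpPD) * MND / 2 * 0.7
  ct <- dist / 2.3 * 16.1
  tcf <- mb + mpnd + 2 * ct
  bbt <- 60 - 0.1 * depth; pbt <- 40 - 0.2 * 15
  tbt <- (23 + bbt) / 2 * MND * 0.3 + pbt * MND * 0.7
  expect_equal(got$TRC, tcf / tbt, tolerance = 1e-9)
  expect_equal(got$TCF, tcf, tolerance = 1e-9)
  expect_equal(got$TBT, tbt, tolerance = 1e-9)
  expect_false(got$flagged)
})

test_that("TRC increases with distance at fixed depth (fixed MND)", {
  models <- toyModels(); stats <- toyStats(); sp <- speciesParams()
  d <- cellTrc(rep(80, 5), seq(1000, 30000, length.out = 5), models,
               stats, sp, warnExtrapolation = FALSE)
  expect_true(all(diff(d$TRC) > 0))
})

test_that("at 3 m depth the benthic power trapezoid degenerates", {
  models <- toyModels(); stats <- toyStats(); sp <- speciesParams()
  got <- cellTrc(3, 1000, models, stats, sp, warnExtrapolation = FALSE)
  mp3 <- massSpecificPower(voFromOdba(10 + 2 * 3, sp), sp)
  expect_equal(got$MPbenthic, mp3)
  expect_equal(got$MPMNDbenthic,
               stats@DDbenthic * (2 * mp3) * stats@MND / 2 * stats@pBD)
  shallow <- cellTrc(2.5, 1000, models, stats, sp,
                     warnExtrapolation = FALSE)
  expect_true(shallow$flagged)
})

test_that("IDW is exact at samples, symmetric at midpoints and convex", {
  sLon <- c(0, 0.02); sLat <- c(0, 0); v <- c(100, 120)
  for (p in c(1, 2, 3.7)) {
    expect_equal(idwInterpolate(sLon, sLat, v, 0.01, 0, power = p), 110)
  }
  expect_equal(idwInterpolate(sLon, sLat, v, 0, 0), 100)
  set.seed(41)
  sLon <- runif(40, -0.1, 0.1); sLat <- runif(40, -0.1, 0.1)
  v <- runif(40, 50, 250)
  tLon <- runif(100, -0.1, 0.1); tLat <- runif(100, -0.1, 0.1)
  got <- idwInterpolate(sLon, sLat, v, tLon, tLat)
  expect_true(all(got >= min(v) - 1e-9 & got <= max(v) + 1e-9))
  ref <- refIdw(sLon, sLat, v, tLon, tLat)
  expect_lt(max(abs(got - ref)), 1e-9)
  expect_error(idwInterpolate(numeric(0), numeric(0), numeric(0), 0, 0),
               "at least one sample")
})

test_that("the landscape raster respects sample extrema and is deterministic", {
  cfg <- syntheticConfig(seed = 5)
  grid <- generateBathymetry(cfg, extentKm = 6, cellM = 1000)
  ls1 <- buildEnergyLandscape(grid, toyModels(), toyStats(),
                              speciesParams(), cfg@colony)
  ls2 <- buildEnergyLandscape(grid, toyModels(), toyStats(),
                              speciesParams(), cfg@colony)
  expect_identical(landscapeRaster(ls1), landscapeRaster(ls2))
  cells <- landscapeCells(ls1)
  ok <- !cells$flagged
  expect_gte(min(landscapeRaster(ls1)$TRC), min(cells$TRC[ok]))
  expect_lte(max(landscapeRaster(ls1)$TRC), max(cells$TRC[ok]))
  # finer raster keeps the convex-combination property
  ls3 <- buildEnergyLandscape(grid, toyModels(), toyStats(),
                              speciesParams(), cfg@colony,
                              rasterFactor = 2L)
  expect_gt(nrow(landscapeRaster(ls3)), nrow(landscapeRaster(ls1)))
  expect_gte(min(landscapeRaster(ls3)$TRC), min(cells$TRC[ok]))
})

test_that("dive-location summaries take the nearest cell and conserve counts", {
  cells <- data.frame(lon = c(0, 0.02), lat = c(0, 0), depth = c(50, 50),
                      distance = c(0, 2224), CT = 0, MND = 300,
                      MPbenthic = 1, MPpelagic = 1, MPMNDbenthic = 1,
                      MPMNDpelagic = 1, TCF = 1, BBT = 1, PBT = 1, TBT = 1,
                      TRC = c(100, 120), flagged = FALSE)
  ls <- new("EnergyLandscape", cells = cells,
            raster = cells[, c("lon", "lat", "TRC")],
            metadata = list(cellSize = 2300))
  oneCell <- data.frame(lon = rep(0.0001, 4), lat = rep(0, 4))
  s1 <- summarizeAtDives(ls, oneCell)
  expect_equal(s1@median, 100)
  expect_equal(diff(s1@range), 0)
  both <- data.frame(lon = c(0, 0, 0.02, 0.02), lat = rep(0, 4))
  s2 <- summarizeAtDives(ls, both)
  expect_equal(s2@median, 110)
  far <- data.frame(lon = c(0, 5), lat = c(0, 5))
  s3 <- summarizeAtDives(ls, far)
  expect_equal(s3@nExcluded, 1L)
  expect_equal(sum(s3@histCounts) + s3@nExcluded, nrow(far))
})
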