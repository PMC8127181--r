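test_that("noiseless power-law dive costs are recovered to 4 significant digits", {
  depths <- seq(5, 180, length.out = 60)
  dives <- data.frame(class = "benthic", maxDepth = depths,
                      odbaSum = 0.5 * depths^1.2)
  dives <- rbind(dives, data.frame(class = "pelagic", maxDepth = depths,
                                   odbaSum = 30 + 2 * depths))
  m <- fitOdbaDepth(dives)
  expect_equal(m$benthic@family, "power")
  expect_equal(unname(m$benthic@coef), c(0.5, 1.2), tolerance = 1e-4)
  expect_equal(m$pelagic@family, "linear")
  expect_equal(unname(m$pelagic@coef), c(30, 2), tolerance = 1e-4)
  expect_gt(m$benthic@r2, 1 - 1e-9)
})

test_that("a constant response selects a flat linear fit with R2 = 0", {
  x <- seq(5, 100, length.out = 20)
  m <- fitBestModel(x, rep(7, 20), response = "bottomTime")
  expect_equal(m@family, "linear")
  expect_equal(unname(m@coef[2]), 0, tolerance = 1e-12)
  expect_equal(m@r2, 0)
})

test_that("10% noise at n = 300 recovers parameters within 10%", {
  set.seed(31)
  x <- runif(300, 5, 180)
  y <- (0.5 * x^1.2) * (1 + rnorm(300, 0, 0.1))
  m <- fitBestModel(x, y, response = "odbaSum")
  expect_equal(m@family, "power")
  expect_lt(max(abs(m@coef - c(0.5, 1.2)) / c(0.5, 1.2)), 0.1)
  expect_gt(m@r2, 0.6)
  expect_lt(m@r2, 0.97)
})

test_that("a single-family set forces that family", {
  x <- seq(5, 100, length.out = 30)
  y <- 0.5 * x^1.3
  m <- fitBestModel(x, y, families = "linear")
  expect_equal(m@family, "linear")
})

test_that("noiseless bottom-time laws are recovered exactly and stay in range", {
  depths <- seq(5, 150, length.out = 50)
  bt <- 80 - 0.2 * depths
  dives <- data.frame(class = rep(c("benthic", "pelagic"), each = 50),
                      maxDepth = rep(depths, 2),
                      bottomTime = c(bt, 45 - 0.1 * depths))
  m <- fitBottomtimeDepth(dives)
  expect_equal(unname(m$benthic@coef), c(80, -0.2), tolerance = 1e-6)
  pred <- predict(m$benthic, depths, warnExtrapolation = FALSE)
  expect_true(all(pred >= min(bt) - 1e-6 & pred <= max(bt) + 1e-6))
})

test_that("dives-vs-distance regression recovers a linear law and clamps", {
  mkTrip <- function(id, dist) {
    nd <- round(50 + 5 * dist)
    dv <- data.frame(start = seq_len(nd), end = seq_len(nd) + 1)
    new("ForagingTrip", individual = id,
        track = GpsTrack(c(0, 300), c(0, 0.01), c(0, 0)), dives = dv,
        lengthKm = 2 * dist, maxDistanceKm = dist, durationMin = 100)
  }
  trips <- lapply(1:6, function(i) mkTrip(paste0("b", i), 5 * i))
  m <- fitDivesVsDistance(trips)
  expect_equal(m@family, "linear")
  expect_equal(unname(m@coef), c(50, 5), tolerance = 1e-6)
  expect_equal(predict(m, 0, warnExtrapolation = FALSE),
               unname(m@coef[1]))
  neg <- handLinearModel(5, -2, response = "nDives")
  expect_equal(predict(neg, 100, warnExtrapolation = FALSE), 1)
  expect_error(fitDivesVsDistance(trips[1:2]), ">= 3 trips")
})

test_that("too few dives in a class raises an error naming the class", {
  dives <- data.frame(class = c("benthic", "benthic", "pelagic", "pelagic",
                                "pelagic"),
                      maxDepth = c(50, 60, 10, 12, 14),
                      odbaSum = c(100, 120, 30, 35, 40))
  expect_error(fitOdbaDepth(dives), "benthic")
})

test_that("family selection is deterministic and logged", {
  set.seed(32)
  x <- runif(50, 5, 100)
  y <- (10 + 2 * x) * (1 + rnorm(50, 0, 0.05))
  m1 <- fitBestModel(x, y)
  m2 <- fitBestModel(x, y)
  expect_identical(m1@family, m2@family)
  expect_identical(m1@coef, m2@coef)
  log <- attr(m1, "fitLog")
  expect_gte(length(log), 2L)
  expect_true(all(vapply(log, function(c) c$r2, numeric(1)) <= m1@r2 + 1e-9))
})

test_that("out-of-range predictions warn but still extrapolate", {
  m <- handLinearModel(10, 2, trainRange = c(3, 100))
  expect_warning(p <- predict(m, 150), "extrapolation")
  expect_equal(p, 310)
  expect_silent(predict(m, 120))  # within 1.25 * max
})
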