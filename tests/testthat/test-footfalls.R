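test_that("flat traces yield no footfall events", {
  flat <- makeSeries(0:719, y = rep(300, 720), name = "paw")
  expect_length(detectFootfallsDeviation(flat, "paw", 5), 0)
  expect_length(detectFootfallsBaseline(flat, "paw", 5), 0)
  expect_length(detectFootfallsThreshold(flat, "paw", rungY = 310, 5), 0)
})

test_that("deviation detection recovers injected dips in time, space and depth", {
  ffs <- list(c(1, .25, 20), c(2, .2, 25), c(2.8, .3, 22),
              c(4, .25, 30), c(5, .2, 24))
  cfg <- ladderSimConfig(amplitude = 0, noiseSd = 0.5, footfalls = ffs,
                         seed = 6)
  lt <- generateLadderTrace(cfg)
  ff <- detectFootfallsDeviation(lt$series, "paw", 10)
  ev <- footfallEvents(ff)
  expect_equal(nrow(ev), 5)
  expect_true(all(abs(ev$onset - lt$truth$onset) <= 5))
  expect_true(all(abs(ev$offset - lt$truth$offset) <= 5))
  expect_true(all(abs(ev$depth - lt$truth$depth) / lt$truth$depth < 0.15))
  # events are sorted and non-overlapping
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$onset[-1] >= ev$offset[-nrow(ev)]))
  # a dip at half the threshold prominence is not detected
  lt2 <- generateLadderTrace(ladderSimConfig(
    amplitude = 0, footfalls = list(c(2, .25, 5))))
  expect_length(detectFootfallsDeviation(lt2$series, "paw", 10), 0)
})

test_that("lowering the prominence threshold never loses events", {
  lt <- generateLadderTrace(ladderSimConfig(
    noiseSd = 1, seed = 12,
    footfalls = list(c(1, .2, 12), c(2.5, .3, 25), c(4, .2, 40))))
  thresholds <- c(30, 20, 10, 5, 2)
  counts <- vapply(thresholds, function(th)
    length(detectFootfallsDeviation(lt$series, "paw", th)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("threshold detection gives closed-form results on a square wave", {
  y <- rep(295, 600)
  y[101:112] <- 310  # 10 px below a rung line at 300, for 12 frames
  ps <- makeSeries(0:599, y = y, name = "paw")
  ff <- footfallEvents(detectFootfallsThreshold(ps, "paw", rungY = 300,
                                                minExcursionPx = 5))
  expect_equal(nrow(ff), 1)
  expect_equal(ff$depth, 10)
  expect_equal(ff$onset, 101)
  expect_equal(ff$duration, 12 / 120)
  # paw always above the rung line: nothing detected
  expect_length(detectFootfallsThreshold(
    makeSeries(0:599, y = rep(290, 600), name = "paw"), "paw", 300, 5), 0)
})

test_that("the three algorithms agree on clean synthetic crossings", {
  ffs <- list(c(1, .25, 20), c(2.5, .2, 25), c(4, .3, 22))
  lt <- generateLadderTrace(ladderSimConfig(amplitude = 0, noiseSd = 0.5,
                                            footfalls = ffs, seed = 4))
  dev <- footfallEvents(detectFootfallsDeviation(lt$series, "paw", 10))
  thr <- footfallEvents(detectFootfallsThreshold(lt$series, "paw", 300, 5))
  bas <- footfallEvents(detectFootfallsBaseline(lt$series, "paw", 10))
  expect_equal(nrow(dev), 3)
  expect_equal(nrow(thr), 3)
  expect_equal(nrow(bas), 3)
  # without drift, baseline correction changes events by at most 1 frame
  expect_true(all(abs(dev$onset - bas$onset) <= 1))
  expect_true(all(abs(dev$offset - bas$offset) <= 1))
})

test_that("baseline correction rescues detection under camera drift", {
  fr <- 720
  drift <- seq(0, 30, length.out = fr)
  y <- 300 + drift
  dip <- 200:230
  y[dip] <- y[dip] + 15 * sin(pi * seq_along(dip) / length(dip))
  ps <- makeSeries(seq_len(fr), y = y, name = "paw")
  ff <- detectFootfallsBaseline(ps, "paw", 8)
  expect_length(ff, 1)
  ev <- footfallEvents(ff)
  expect_true(ev$peak >= 200 && ev$peak <= 230)
  # a trace shorter than the baseline window is rejected
  expect_error(detectFootfallsBaseline(
    makeSeries(1:100, y = rep(300, 100), name = "paw"), "paw", 8),
    "shorter")
})

test_that("validation filters events and preserves order", {
  lt <- generateLadderTrace(ladderSimConfig(
    amplitude = 0, noiseSd = 1, seed = 2,
    footfalls = list(c(1, .25, 20), c(2.5, .2, 25), c(4, .3, 22))))
  ff <- detectFootfallsDeviation(lt$series, "paw", 10)
  # all accept is the identity on events
  acc <- applyValidation(ff, rep("accept", length(ff)))
  expect_equal(footfallEvents(acc)$onset, footfallEvents(ff)$onset)
  expect_true(all(footfallEvents(acc)$validated == "accepted"))
  # all reject annihilates
  expect_length(applyValidation(ff, rep("reject", length(ff))), 0)
  # out-of-range decision index errors
  expect_error(
    applyValidation(ff, data.frame(event = length(ff) + 1,
                                   decision = "reject")),
    "out of range")
})

test_that("oracle-driven validation matches the injected count under a permissive threshold", {
  ffs <- list(c(0.8, .25, 20), c(2, .2, 26), c(3, .3, 22), c(4.5, .2, 30))
  lt <- generateLadderTrace(ladderSimConfig(noiseSd = 1, seed = 13,
                                            footfalls = ffs))
  # permissive threshold: may over-detect (never under)
  ff <- detectFootfallsDeviation(lt$series, "paw", 4)
  ev <- footfallEvents(ff)
  expect_gte(nrow(ev), nrow(lt$truth))
  # accept an event iff its peak falls inside a true dip interval
  keep <- vapply(seq_len(nrow(ev)), function(i)
    any(ev$peak[i] >= lt$truth$onset & ev$peak[i] <= lt$truth$offset),
    logical(1))
  dec <- ifelse(keep, "accept", "reject")
  expect_equal(length(applyValidation(ff, dec)), nrow(lt$truth))
})

test_that("footfall summaries expose exactly the three parameter families", {
  ev <- data.frame(paw = "paw", onset = c(10L, 50L), offset = c(22L, 86L),
                   peak = c(15L, 60L), depth = c(10, 20),
                   duration = c(0.1, 0.3), validated = "accepted")
  ff <- FootfallSet(ev, fps = 120)
  s <- footfallSummary(ff, nRuns = 1)
  expect_s3_class(s, "footfallSummary")
  expect_named(s, c("number", "depth", "duration"))
  expect_equal(s$number[["count"]], 2)
  expect_equal(s$depth[["mean"]], 15)
  expect_equal(s$depth[["total"]], 30)
  expect_equal(s$duration[["mean"]], 0.2)
  expect_equal(s$duration[["total"]], 0.4)
  # empty events give zeros, not NaN
  s0 <- footfallSummary(FootfallSet(ev[0, ], fps = 120), nRuns = 4)
  expect_equal(s0$number[["count"]], 0)
  expect_equal(s0$depth[["mean"]], 0)
  expect_equal(s0$duration[["total"]], 0)
})
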