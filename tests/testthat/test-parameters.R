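test_that("joint angles match the law-of-cosines oracle", {
  # collinear and perpendicular closed forms
  s3 <- PoseSeries(matrix(c(0, 1, 2), 3, 2,
                          dimnames = list(c("a", "v", "c"), NULL)),
                   matrix(0, 3, 2), matrix(1, 3, 2), fps = 10)
  expect_equal(as.numeric(jointAngleSeries(s3, "a", "v", "c")),
               c(180, 180))
  s4 <- PoseSeries(matrix(c(0, 1, 1), 3, 2,
                          dimnames = list(c("a", "v", "c"), NULL)),
                   matrix(c(0, 0, 1), 3, 2), matrix(1, 3, 2), fps = 10)
  expect_equal(as.numeric(jointAngleSeries(s4, "a", "v", "c")),
               c(90, 90))
  # 1000 random triads against the independent oracle
  set.seed(1)
  pts <- matrix(rnorm(6000), ncol = 6)
  xm <- t(pts[, c(1, 3, 5)]); ym <- t(pts[, c(2, 4, 6)])
  rownames(xm) <- c("a", "v", "c")
  ps <- PoseSeries(xm, ym, matrix(1, 3, 1000), fps = 10)
  got <- jointAngleSeries(ps, "a", "v", "c")
  want <- vapply(seq_len(1000), function(i)
    lawOfCosinesAngle(pts[i, 1:2], pts[i, 3:4], pts[i, 5:6]), numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)
  # unknown body part is named in the error
  expect_error(jointAngleSeries(ps, "a", "v", "nope"), "nope")
  # zero-length ray gives a missing angle
  s0 <- PoseSeries(matrix(c(1, 1, 2), 3, 2,
                          dimnames = list(c("a", "v", "c"), NULL)),
                   matrix(c(0, 0, 1), 3, 2), matrix(1, 3, 2), fps = 10)
  expect_true(all(is.na(jointAngleSeries(s0, "a", "v", "c"))))
})

test_that("per-cycle angle features recover prescribed oscillations", {
  # constant series: flexion = extension = mean, amplitude 0
  f <- angleFeatures(rep(90, 50), 1, 51)
  expect_equal(unname(f), c(90, 90, 90, 0))
  # noiseless knee oscillation between 60 and 140 degrees
  tr <- generateTreadmillTrace(gaitSimConfig())
  pt <- extractParameterTable(tr$series)
  df <- paramTable(pt)
  expect_true(all(abs(df$knee_angle_flexion - 60) < 1))
  expect_true(all(abs(df$knee_angle_extension - 140) < 1))
  expect_true(all(df$knee_angle_amplitude >= 0))
  expect_true(all(df$hip_angle_amplitude >= 0))
  # heavily missing cycles are flagged, not silently summarised
  a <- rep(90, 50); a[1:20] <- NA
  expect_warning(f2 <- angleFeatures(a, 1, 51), "missing")
  expect_true(all(is.na(f2)))
})

test_that("endpoint features recover generator truth and are additive", {
  cfg <- gaitSimConfig(stepHeight = 15, strideLength = 60)
  tr <- generateTreadmillTrace(cfg)
  df <- paramTable(extractParameterTable(tr$series))
  expect_true(all(abs(df$step_height - 15) < 0.5))
  expect_true(all(abs(df$stride_length - 60) < 0.5))
  expect_equal(df$stride_length, df$swing_length + df$stance_length,
               tolerance = 1e-6)
  expect_true(all(df$toe_crest_distance_max >= df$toe_crest_distance_mean))
  expect_true(all(df$t_peak_height_pct >= 0 & df$t_peak_height_pct <= 100))
})

test_that("temporal features are exact arithmetic on the phase mask", {
  mask <- rep(c("swing", "stance"), c(24, 36))
  cyc <- StepCycles(onset = 1L, offset = 61L, degenerate = FALSE,
                    phase = c(mask, "swing"), beltSpeed = 2, fps = 120)
  tf <- temporalFeatures(cyc, 1, strideLength = 96)
  expect_equal(tf[["stride_duration"]], 0.5)
  expect_equal(tf[["stance_pct"]], 60)
  expect_equal(tf[["swing_pct"]], 40)
  expect_equal(tf[["cadence"]], 2)
  expect_equal(tf[["stance_pct"]] + tf[["swing_pct"]], 100)
  expect_equal(tf[["stride_speed"]], 96 / 0.5)
  # recovered stride duration on the generator within one frame
  tr <- generateTreadmillTrace(gaitSimConfig(strideDuration = 0.4))
  df <- paramTable(extractParameterTable(tr$series))
  expect_true(all(abs(df$stride_duration - 0.4) <= 1 / 120))
  expect_equal(df$stance_pct + df$swing_pct, rep(100, nrow(df)),
               tolerance = 1e-9)
})

test_that("DTW cost matches closed forms and the enumeration oracle", {
  expect_equal(as.numeric(dtwAlignmentCost(c(0, 1, 2), c(0, 1, 2))), 0)
  expect_equal(as.numeric(dtwAlignmentCost(0, 3)), 3)
  expect_error(dtwAlignmentCost(numeric(0), 1), "empty")
  # symmetry
  set.seed(3)
  a <- rnorm(15); b <- rnorm(9)
  expect_equal(as.numeric(dtwAlignmentCost(a, b)),
               as.numeric(dtwAlignmentCost(b, a)))
  # exhaustive equivalence with the R path-enumeration oracle (length <= 4)
  seqs <- enumerateSequences(1:4, 0:2)
  set.seed(9)
  pick <- sample(length(seqs), 40)
  for (i in pick) for (j in pick) {
    expect_equal(as.numeric(dtwAlignmentCost(seqs[[i]], seqs[[j]])),
                 bruteDtwR(seqs[[i]], seqs[[j]]), tolerance = 1e-12)
  }
})

test_that("DTW variability is zero for identical cycles and grows with perturbation", {
  traj <- cbind(sin(seq(0, 2 * pi, length.out = 40)),
                cos(seq(0, 2 * pi, length.out = 40)))
  vf <- variabilityFeatures(list(traj, traj))
  expect_equal(unname(unlist(vf[2, ])), rep(0, 6))
  expect_true(all(is.na(vf[1, ])))
  # perturbing one cycle's height strictly increases its DTW columns
  # periodic noiseless gait: successive cycles align almost perfectly
  tr <- generateTreadmillTrace(gaitSimConfig())
  pt <- extractParameterTable(tr$series)
  expect_lt(max(paramTable(pt)$dtw_dist_norm, na.rm = TRUE), 1)
  bumps <- c(2, 5, 10)
  costs <- vapply(bumps, function(h) {
    t2 <- traj; t2[, 2] <- t2[, 2] + h * sin(seq(0, pi, length.out = 40))
    as.numeric(dtwAlignmentCost(traj, t2))
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
})

test_that("component DTW cost never exceeds the 2-D cost", {
  set.seed(4)
  for (k in 1:20) {
    a <- cbind(rnorm(20), rnorm(20))
    b <- cbind(rnorm(25), rnorm(25))
    dy <- as.numeric(dtwAlignmentCost(a[, 2], b[, 2]))
    d2 <- as.numeric(dtwAlignmentCost(a, b))
    expect_lte(dy, d2 + 1e-9)
  }
})

test_that("dragging features follow the clearance rule", {
  # swing apex far above ground: no dragging
  tr <- generateTreadmillTrace(gaitSimConfig())
  df <- paramTable(extractParameterTable(tr$series))
  expect_equal(df$dragging_pct, rep(0, nrow(df)))
  # configured drag fraction is recovered
  tr3 <- generateTreadmillTrace(gaitSimConfig(dragFraction = 0.3))
  df3 <- paramTable(extractParameterTable(tr3$series))
  expect_true(all(abs(df3$dragging_pct - tr3$truth$draggingPct) <= 5))
  # full drag: 100% dragging and the degenerate flag
  tr1 <- generateTreadmillTrace(gaitSimConfig(dragFraction = 1))
  pt1 <- extractParameterTable(tr1$series)
  expect_equal(paramTable(pt1)$dragging_pct, rep(100, nrow(pt1)))
  expect_true(all(isDegenerate(pt1@metadata$cycles)))
})

test_that("the parameter table has the stable 44-column schema", {
  sch <- kinematicParameterSchema()
  expect_length(sch, 44)
  expect_equal(unname(table(sch)[c("joint_angles", "endpoint", "temporal",
                                   "variability", "dragging")]),
               c(16L, 12L, 8L, 6L, 2L), ignore_attr = TRUE)
  tr <- generateTreadmillTrace(gaitSimConfig(noiseSd = 1, seed = 2))
  pt <- extractParameterTable(tr$series)
  expect_identical(names(paramTable(pt)), names(sch))
  expect_identical(paramCategories(pt), sch)
  # noiseless 10-stride trace yields 10 rows
  cfg10 <- gaitSimConfig(duration = (29 + 10 * 48 + 24) / 120)
  pt10 <- extractParameterTable(generateTreadmillTrace(cfg10)$series)
  expect_equal(nrow(pt10), 10)
  # pure drag: only dragging-category columns are populated
  ptd <- extractParameterTable(
    generateTreadmillTrace(gaitSimConfig(dragFraction = 1))$series)
  dfd <- paramTable(ptd)
  dragCols <- names(sch)[sch == "dragging"]
  expect_true(all(!is.na(dfd[, dragCols])))
  expect_true(all(is.na(dfd[, setdiff(names(sch), dragCols)])))
  # zero complete cycles: empty table, schema intact
  flat <- makeSeries(rep(5, 600))
  xm <- do.call(rbind, rep(list(rep(5, 600)), 6))
  rownames(xm) <- c("toe", "mtp", "ankle", "knee", "hip", "crest")
  flat6 <- PoseSeries(xm, xm + 10, xm * 0 + 1, fps = 120)
  cfgFixed <- analysisConfig(beltSpeed = 2)
  pt0 <- extractParameterTable(flat6, cfgFixed)
  expect_equal(nrow(pt0), 0)
  expect_identical(names(paramTable(pt0)), names(sch))
})

test_that("parameters are invariant to a global coordinate translation", {
  tr <- generateTreadmillTrace(gaitSimConfig(noiseSd = 0.5, seed = 8))
  shifted <- PoseSeries(poseX(tr$series) + 321, poseY(tr$series) - 57,
                        poseLikelihood(tr$series), fps = 120)
  a <- paramTable(extractParameterTable(tr$series))
  b <- paramTable(extractParameterTable(shifted))
  expect_equal(a, b, tolerance = 1e-9)
})
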