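# Synthetic treadmill and ladder traces with exact ground truth.
#
# The treadmill generator prescribes the toe trajectory directly (belt-
# driven backward stance motion, smoothstep-in-x / half-sine-in-y swing
# arc) and builds the rest of the six-marker chain (crest, hip, knee,
# ankle, MTP) by forward kinematics from the hip with prescribed joint
# angle oscillations, so true joint angles exist in closed form.

# evaluate expr under a private RNG stream, restoring global state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.interiorAngle <- function(ax, ay, vx, vy, cx, cy) {
  ux <- ax - vx; uy <- ay - vy
  wx <- cx - vx; wy <- cy - vy
  nu <- sqrt(ux^2 + uy^2); nw <- sqrt(wx^2 + wy^2)
  cosv <- (ux * wx + uy * wy) / (nu * nw)
  ang <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  ang[nu == 0 | nw == 0] <- NA_real_
  ang
}

#' Treadmill gait simulation configuration
#'
#' Parameters of the synthetic treadmill trace. Defaults describe a mouse
#' on a slow belt filmed at 120 fps at roughly 30 px/cm: 0.4 s strides at
#' duty factor 0.6, a 2 px/frame belt, 25 px step height and a 96 px
#' stride, chosen mutually consistent (stride length = belt speed x
#' stride frames) so the simulated animal holds station on the belt.
#'
#' @param fps frames per second.
#' @param duration trace duration (s); must cover at least 2 strides.
#' @param beltSpeed belt speed (px/frame, > 0): stance-phase backward toe
#'   velocity in the camera frame.
#' @param strideDuration stride period (s).
#' @param dutyFactor stance fraction of the stride, in (0, 1).
#' @param stepHeight peak swing toe clearance above the ground line (px).
#' @param strideLength belt-frame toe displacement per stride (px);
#'   `NULL` (default) derives it as `beltSpeed * strideFrames`.
#' @param segmentLengths named numeric: `crest`, `thigh`, `shank`, `foot`
#'   segment lengths (px) of the crest-hip-knee-ankle-MTP chain.
#' @param noiseSd additive Gaussian pixel noise sd (px).
#' @param dragFraction fraction of swing spent clamped at ground level,
#'   in \[0, 1\]; 1 gives a fully dragging (degenerate) gait.
#' @param groundY image y of the ground line (px, y increases downward).
#' @param seed integer RNG seed; one private stream per trace.
#' @return a `gaitSimConfig` list.
#' @export
gaitSimConfig <- function(fps = 120, duration = 5, beltSpeed = 2,
                          strideDuration = 0.4, dutyFactor = 0.6,
                          stepHeight = 25, strideLength = NULL,
                          segmentLengths = c(crest = 25, thigh = 35,
                                             shank = 38, foot = 20),
                          noiseSd = 0, dragFraction = 0, groundY = 400,
                          seed = 1) {
  stopifnot(fps > 0, duration > 0, beltSpeed > 0,
            dutyFactor > 0, dutyFactor < 1, stepHeight >= 0,
            noiseSd >= 0, dragFraction >= 0, dragFraction <= 1)
  strideFrames <- round(strideDuration * fps)
  if (is.null(strideLength)) strideLength <- beltSpeed * strideFrames
  cfg <- list(fps = fps, duration = duration, beltSpeed = beltSpeed,
              strideDuration = strideDuration, dutyFactor = dutyFactor,
              stepHeight = stepHeight, strideLength = strideLength,
              segmentLengths = segmentLengths, noiseSd = noiseSd,
              dragFraction = dragFraction, groundY = groundY, seed = seed)
  class(cfg) <- "gaitSimConfig"
  cfg
}

#' Generate a synthetic treadmill trace with ground truth
#'
#' Produces a six-marker [PoseSeries] (toe, mtp, ankle, knee, hip, crest)
#' plus the generator's ground truth. The toe moves backward at
#' `-beltSpeed` px/frame during stance and forward along a smoothstep-x /
#' half-sine-y arc during swing, reaching exactly `stepHeight` clearance
#' at the apex (the sampled half-sine is renormalised so the maximum is
#' exact). Dragging is modelled by clamping the first `dragFraction` of
#' each swing's frames to the ground line. The trace opens with one full
#' stance segment so the first toe-off is detectable, then whole strides
#' until the duration is exhausted (the trailing partial stride remains
#' in the trace and is excluded downstream as incomplete).
#'
#' @param cfg a [gaitSimConfig()].
#' @return a list with elements `series` (the [PoseSeries]) and `truth`:
#'   belt speed, stride onset frames (1-based swing starts), number of
#'   complete toe-off-to-toe-off cycles, per-frame phase labels, realised
#'   per-cycle step height / stride length / drag fraction, closed-form
#'   hip/knee/ankle angle series plus the numerically derived MTP angle,
#'   and the ground line.
#' @export
generateTreadmillTrace <- function(cfg) {
  stopifnot(inherits(cfg, "gaitSimConfig"))
  fps <- cfg$fps
  frames <- round(fps * cfg$duration)
  strideFrames <- round(cfg$strideDuration * fps)
  stanceFrames <- round(cfg$dutyFactor * strideFrames)
  swingFrames <- strideFrames - stanceFrames
  if (stanceFrames < 2 || swingFrames < 2)
    stop("stride too short: need >= 2 stance and >= 2 swing frames")
  if (frames < stanceFrames + 2 * strideFrames)
    stop("duration too short: must cover at least 2 full strides")

  dragFrames <- round(cfg$dragFraction * swingFrames)
  arcFrames <- swingFrames - dragFrames

  # per-frame phase layout: lead-in stance, then whole [swing, stance]
  # strides; a trailing swing is emitted only if it fits completely, so
  # every recorded toe-off is cleanly detectable downstream
  phase <- rep("stance", frames)
  onsets <- integer()
  t0 <- stanceFrames + 1L
  while (t0 + swingFrames - 1L <= frames) {
    onsets <- c(onsets, t0)
    phase[seq(t0, t0 + swingFrames - 1L)] <- "swing"
    t0 <- t0 + strideFrames
  }
  nComplete <- max(0L, length(onsets) - 1L)

  # toe trajectory, adjusted (belt) frame first
  xAdj <- numeric(frames)
  yToe <- rep(cfg$groundY, frames)
  plant <- 200
  xAdj[seq_len(stanceFrames)] <- plant
  arcShape <- if (arcFrames > 0) {
    raw <- sin(pi * seq_len(arcFrames) / (arcFrames + 1))
    raw / max(raw)
  } else numeric(0)
  smoothstep <- function(s) s * s * (3 - 2 * s)
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    swingIdx <- seq(on, min(on + swingFrames - 1L, frames))
    prog <- smoothstep(seq_along(swingIdx) / swingFrames)
    xAdj[swingIdx] <- plant + cfg$strideLength * prog
    if (arcFrames > 0) {
      arcIdx <- on + dragFrames + seq_len(arcFrames) - 1L
      keep <- arcIdx <= frames
      yToe[arcIdx[keep]] <-
        cfg$groundY - cfg$stepHeight * arcShape[keep]
    }
    newPlant <- plant + cfg$strideLength
    stIdx <- seq(min(on + swingFrames, frames + 1L),
                 min(on + strideFrames - 1L, frames))
    if (length(stIdx) && stIdx[1] <= frames) xAdj[stIdx] <- newPlant
    plant <- newPlant
  }
  lastSet <- if (length(onsets))
    min(onsets[length(onsets)] + strideFrames - 1L, frames)
  else stanceFrames
  if (lastSet < frames) xAdj[(lastSet + 1):frames] <- plant
  tIdx <- seq_len(frames) - 1
  xToe <- xAdj - cfg$beltSpeed * tIdx

  # chain by forward kinematics from the hip, prescribed joint angles
  sl <- cfg$segmentLengths
  meanSpeed <- cfg$strideLength / strideFrames
  firstOn <- onsets[1]
  phi <- ((tIdx - (firstOn - 1)) %% strideFrames) / strideFrames
  hipXAdj <- 180 + meanSpeed * tIdx
  hipX <- hipXAdj - cfg$beltSpeed * tIdx
  hipY <- cfg$groundY - (sl[["thigh"]] + sl[["shank"]] - 10) +
    3 * sin(2 * pi * phi)
  deg <- pi / 180
  phiCrest <- 230 * deg
  crestX <- hipX + sl[["crest"]] * cos(phiCrest)
  crestY <- hipY + sl[["crest"]] * sin(phiCrest)
  thighAng <- (90 + 25 * sin(2 * pi * phi + pi / 2)) * deg
  kneeInterior <- 100 + 40 * sin(2 * pi * phi)            # degrees
  ankleInterior <- 90 + 30 * sin(2 * pi * phi + pi / 3)   # degrees
  kneeX <- hipX + sl[["thigh"]] * cos(thighAng)
  kneeY <- hipY + sl[["thigh"]] * sin(thighAng)
  shankAng <- thighAng - pi + kneeInterior * deg
  ankleX <- kneeX + sl[["shank"]] * cos(shankAng)
  ankleY <- kneeY + sl[["shank"]] * sin(shankAng)
  footAng <- shankAng - pi + ankleInterior * deg
  mtpX <- ankleX + sl[["foot"]] * cos(footAng)
  mtpY <- ankleY + sl[["foot"]] * sin(footAng)

  hipInterior <- .interiorAngle(crestX, crestY, hipX, hipY, kneeX, kneeY)
  mtpInterior <- .interiorAngle(ankleX, ankleY, mtpX, mtpY, xToe, yToe)

  xm <- rbind(toe = xToe, mtp = mtpX, ankle = ankleX, knee = kneeX,
              hip = hipX, crest = crestX)
  ym <- rbind(toe = yToe, mtp = mtpY, ankle = ankleY, knee = kneeY,
              hip = hipY, crest = crestY)

  out <- .withSeed(cfg$seed, {
    if (cfg$noiseSd > 0) {
      xm <- xm + matrix(rnorm(length(xm), 0, cfg$noiseSd), nrow(xm))
      ym <- ym + matrix(rnorm(length(ym), 0, cfg$noiseSd), nrow(ym))
    }
    lm <- matrix(pmin(1, pmax(0, 1 - abs(rnorm(length(xm), 0, 0.005)))),
                 nrow(xm), dimnames = dimnames(xm))
    if (cfg$noiseSd > 0) {
      dip <- matrix(runif(length(lm)) < 0.01, nrow(lm))
      lm[dip] <- runif(sum(dip), 0.2, 0.55)
    }
    list(xm = xm, ym = ym, lm = lm)
  })

  series <- PoseSeries(out$xm, out$ym, out$lm, fps = fps,
                       provenance = "synthetic")
  truth <- list(
    beltSpeed = cfg$beltSpeed,
    strideOnsets = onsets,
    nCompleteCycles = nComplete,
    strideFrames = strideFrames,
    phase = phase,
    stepHeight = if (arcFrames > 0) cfg$stepHeight else 0,
    strideLength = cfg$strideLength,
    strideDuration = strideFrames / fps,
    dutyFactor = stanceFrames / strideFrames,
    dragFraction = dragFrames / swingFrames,
    draggingPct = 100 * dragFrames / swingFrames,
    groundY = cfg$groundY,
    angles = data.frame(hip = hipInterior, knee = kneeInterior,
                        ankle = ankleInterior, mtp = mtpInterior)
  )
  list(series = series, truth = truth)
}

#' Ladder crossing simulation configuration
#'
#' @param fps frames per second.
#' @param duration trace duration (s).
#' @param rungY image y of the rung line (px); the paw stays at or above
#'   it (y <= rungY) during normal stepping.
#' @param amplitude normal stepping oscillation above the rung line (px).
#' @param stepRate stepping rate (steps/s) of the normal oscillation.
#' @param footfalls list of numeric triples `c(onset_s, duration_s,
#'   depth_px)`; injected downward paw deviations below the rung line.
#'   Intervals must not overlap and depths must be positive.
#' @param noiseSd additive Gaussian pixel noise sd (px).
#' @param seed integer RNG seed.
#' @return a `ladderSimConfig` list.
#' @export
ladderSimConfig <- function(fps = 120, duration = 6, rungY = 300,
                            amplitude = 5, stepRate = 2.5,
                            footfalls = list(), noiseSd = 0, seed = 1) {
  stopifnot(fps > 0, duration > 0, amplitude >= 0, noiseSd >= 0)
  if (length(footfalls)) {
    ff <- do.call(rbind, lapply(footfalls, function(f) f[1:3]))
    if (any(ff[, 3] <= 0)) stop("footfall depth must be > 0")
    if (any(ff[, 1] < 0) || any(ff[, 1] + ff[, 2] > duration))
      stop("footfalls must lie within the trace duration")
    o <- order(ff[, 1])
    ends <- ff[o, 1] + ff[o, 2]
    if (any(ff[o, 1][-1] < head(ends, -1)))
      stop("config error: footfall intervals overlap")
  }
  cfg <- list(fps = fps, duration = duration, rungY = rungY,
              amplitude = amplitude, stepRate = stepRate,
              footfalls = footfalls, noiseSd = noiseSd, seed = seed)
  class(cfg) <- "ladderSimConfig"
  cfg
}

#' Generate a synthetic ladder crossing with injected footfalls
#'
#' The paw y oscillates between `rungY - amplitude` and exactly `rungY`
#' during normal stepping (never below the rung line), and during each
#' configured footfall dips below it along a half-sine of the stated
#' duration, reaching exactly `depth` px below the line at the dip centre
#' (sampled half-sine renormalised). The paw advances steadily in x.
#'
#' @param cfg a [ladderSimConfig()].
#' @return a list with `series` (single-body-part [PoseSeries], `"paw"`)
#'   and `truth`: a data.frame of injected events (1-based `onset`,
#'   `offset`, `peak` frames, `depth` px, `duration` s) in configuration
#'   order.
#' @export
generateLadderTrace <- function(cfg) {
  stopifnot(inherits(cfg, "ladderSimConfig"))
  frames <- round(cfg$fps * cfg$duration)
  tSec <- (seq_len(frames) - 1) / cfg$fps
  y <- cfg$rungY - cfg$amplitude *
    (0.5 + 0.5 * sin(2 * pi * cfg$stepRate * tSec - pi / 2))
  x <- 50 + 60 * tSec
  truth <- data.frame(onset = integer(), offset = integer(),
                      peak = integer(), depth = numeric(),
                      duration = numeric())
  for (f in cfg$footfalls) {
    f0 <- floor(f[1] * cfg$fps) + 1L
    f1 <- min(frames, floor((f[1] + f[2]) * cfg$fps))
    k <- seq_len(f1 - f0 + 1L)
    raw <- sin(pi * k / (length(k) + 1))
    y[f0 + k - 1L] <- cfg$rungY + f[3] * raw / max(raw)
    truth <- rbind(truth, data.frame(
      onset = f0, offset = f1, peak = f0 + which.max(raw) - 1L,
      depth = f[3], duration = (f1 - f0 + 1L) / cfg$fps))
  }
  out <- .withSeed(cfg$seed, {
    if (cfg$noiseSd > 0) {
      x <- x + rnorm(frames, 0, cfg$noiseSd)
      y <- y + rnorm(frames, 0, cfg$noiseSd)
    }
    lik <- pmin(1, pmax(0, 1 - abs(rnorm(frames, 0, 0.005))))
    list(x = x, y = y, lik = lik)
  })
  xm <- matrix(out$x, 1, dimnames = list("paw", NULL))
  series <- PoseSeries(xm, matrix(out$y, 1), matrix(out$lik, 1),
                       fps = cfg$fps, provenance = "synthetic")
  list(series = series, truth = truth)
}

#' Generate a labeled two-group per-cycle parameter dataset
#'
#' Runs the full treadmill pipeline (clean, smooth, belt-speed, adjust,
#' phase, segment, all 44 parameters) on `n` traces per configuration and
#' concatenates the per-cycle rows with group labels `"a"` / `"b"`.
#' Trace `i` of each group uses seed `cfg$seed + i - 1`.
#'
#' @param cfgA,cfgB [gaitSimConfig()] objects for the two groups.
#' @param nTracesPerGroup traces per group, >= 1.
#' @param config analysis configuration, see [analysisConfig()].
#' @return a labeled [GaitParameterTable].
#' @export
generateGroupDataset <- function(cfgA, cfgB, nTracesPerGroup = 5,
                                 config = analysisConfig()) {
  stopifnot(nTracesPerGroup >= 1)
  one <- function(cfg, grp, i) {
    cfg$seed <- cfg$seed + i - 1
    tr <- tryCatch(generateTreadmillTrace(cfg),
                   error = function(e) stop("trace ", i, " (group ", grp,
                                            "): ", conditionMessage(e)))
    pt <- tryCatch(extractParameterTable(tr$series, config),
                   error = function(e) stop("trace ", i, " (group ", grp,
                                            "): ", conditionMessage(e)))
    df <- paramTable(pt)
    df$.group <- grp
    df$.trace <- paste0(grp, i)
    df
  }
  rows <- c(lapply(seq_len(nTracesPerGroup), function(i) one(cfgA, "a", i)),
            lapply(seq_len(nTracesPerGroup), function(i) one(cfgB, "b", i)))
  df <- do.call(rbind, rows)
  grp <- factor(df$.group, levels = c("a", "b"))
  trace <- df$.trace
  df$.group <- NULL
  df$.trace <- NULL
  rownames(df) <- NULL
  GaitParameterTable(df, .parameterCategories(),
                     group = grp,
                     metadata = list(trace = trace,
                                     nTracesPerGroup = nTracesPerGroup))
}
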