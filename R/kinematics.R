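# Treadmill kinematics core: belt-speed estimation, coordinate
# adjustment into the belt frame, stance/swing classification from toe
# velocity, and toe-off-to-toe-off stride segmentation.

# median-smoothed central-difference velocity (px/frame); one-sided at ends
.velocity <- function(x, window = 5) {
  k <- min(window, length(x) - 1)
  if (k %% 2 == 0) k <- k - 1
  xs <- if (k >= 3) .medfilt(x, k) else x
  n <- length(xs)
  v <- numeric(n)
  if (n >= 3) v[2:(n - 1)] <- (xs[3:n] - xs[1:(n - 2)]) / 2
  v[1] <- xs[2] - xs[1]
  v[n] <- xs[n] - xs[n - 1]
  v
}

#' Estimate treadmill belt speed from the toe trajectory
#'
#' During stance the toe rides the belt, so its camera-frame x velocity
#' sits at `-beltSpeed`; during swing it is mostly positive. The belt
#' speed is recovered as minus the median of the smoothed per-frame toe
#' x velocity over frames with negative velocity — the stance velocities
#' form a tight mode at `-beltSpeed` that dominates the median. A second
#' pass re-takes the median over frames below half the first estimate,
#' which discards the near-zero swing-transition frames that would
#' otherwise bias the estimate toward zero under pixel noise.
#'
#' @param series a [PoseSeries]; at least 1 s of frames.
#' @param toe toe body part name.
#' @param smoothWindow odd median window for the velocity estimate.
#' @return belt speed (px/frame, > 0), with attribute `fractionUsed`:
#'   the fraction of frames entering the final median.
#' @export
estimateBeltSpeed <- function(series, toe = "toe", smoothWindow = 5) {
  if (nFrames(series) < frameRate(series))
    stop("need at least 1 s of frames to estimate belt speed")
  v <- .velocity(.bp(series, toe)$x, smoothWindow)
  neg <- v < 0
  if (mean(neg) < 0.2)
    stop("no stance-like motion detected: only ",
         round(100 * mean(neg), 1), "% of frames have negative toe ",
         "velocity (animal not walking, or camera mirrored)")
  b0 <- -median(v[neg])
  stance <- v <= -b0 / 2
  b <- -median(v[stance])
  attr(b, "fractionUsed") <- mean(stance)
  b
}

#' Adjust coordinates for belt motion
#'
#' Adds `beltSpeed * t` to every body part's x so that a stance foot
#' becomes near-stationary and the body progresses forward monotonically;
#' y is untouched. `t` is the 0-based frame index.
#'
#' @param series a [PoseSeries].
#' @param beltSpeed belt speed in px/frame, >= 0.
#' @return the adjusted [PoseSeries].
#' @export
adjustCoordinates <- function(series, beltSpeed) {
  stopifnot(is.numeric(beltSpeed), length(beltSpeed) == 1, beltSpeed >= 0)
  xm <- poseX(series)
  shift <- as.numeric(beltSpeed) * (seq_len(ncol(xm)) - 1)
  xm <- sweep(xm, 2, shift, "+")
  PoseSeries(xm, poseY(series), poseLikelihood(series),
             fps = frameRate(series), provenance = series@provenance)
}

# merge phase runs shorter than minPhaseFrames into their neighbours
.mergeShortRuns <- function(mask, minPhaseFrames) {
  repeat {
    r <- rle(mask)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < minPhaseFrames)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- if (i == 1) r$values[2] else r$values[i - 1]
    mask <- inverse.rle(r)
  }
  mask
}

#' Classify stance and swing phases
#'
#' A frame is stance iff the smoothed camera-frame toe x velocity
#' satisfies `v(t) <= -beltSpeed / 2`, the midpoint of the bimodal
#' velocity distribution (stance near `-beltSpeed`, swing positive);
#' otherwise swing. Phase runs shorter than `minPhaseFrames` are merged
#' into their neighbour to suppress jitter-induced micro-phases.
#'
#' @param series a [PoseSeries] (camera frame, unadjusted).
#' @param toe toe body part name.
#' @param beltSpeed belt speed in px/frame, > 0.
#' @param minPhaseFrames minimum run length kept, in frames.
#' @param smoothWindow odd median window for the velocity estimate.
#' @return character vector of `"stance"` / `"swing"`, one per frame.
#' @export
classifyPhases <- function(series, toe = "toe", beltSpeed,
                           minPhaseFrames = 3, smoothWindow = 5) {
  stopifnot(beltSpeed > 0)
  v <- .velocity(.bp(series, toe)$x, smoothWindow)
  mask <- ifelse(v <= -beltSpeed / 2, "stance", "swing")
  .mergeShortRuns(mask, minPhaseFrames)
}

#' Segment complete stride cycles at toe-off transitions
#'
#' Cycle boundaries are the stance-to-swing transitions (toe-off): each
#' complete cycle spans one toe-off to the next, swing first. The leading
#' partial segment before the first toe-off and the trailing segment
#' after the last are excluded, so every returned cycle is complete.
#' Cycles whose toe never clears the ground line during swing (clearance
#' `<= dragTolerancePx` on every swing frame; ground line = median
#' stance-phase toe y over the whole trace) are flagged degenerate
#' full-drag: only cycle-independent parameters are computed for them.
#'
#' @param series the [PoseSeries] the mask was derived from.
#' @param mask per-frame phase mask from [classifyPhases()].
#' @param beltSpeed belt speed in px/frame.
#' @param toe toe body part name.
#' @param dragTolerancePx ground-clearance tolerance (px) for drag.
#' @return a [StepCycles]; empty (zero cycles) if fewer than two
#'   toe-offs are present.
#' @export
segmentStrides <- function(series, mask, beltSpeed, toe = "toe",
                           dragTolerancePx = 3) {
  stopifnot(length(mask) == nFrames(series))
  toeOff <- which(mask[-1] == "swing" & mask[-length(mask)] == "stance") + 1L
  if (length(toeOff) < 2)
    return(StepCycles(phase = mask, beltSpeed = as.numeric(beltSpeed),
                      fps = frameRate(series)))
  onset <- toeOff[-length(toeOff)]
  offset <- toeOff[-1]
  y <- .bp(series, toe)$y
  stanceY <- y[mask == "stance"]
  degenerate <- vapply(seq_along(onset), function(i) {
    idx <- onset[i]:(offset[i] - 1L)
    sw <- idx[mask[idx] == "swing"]
    if (!length(sw) || !length(stanceY)) return(FALSE)
    groundY <- median(stanceY)
    all(groundY - y[sw] <= dragTolerancePx)
  }, logical(1))
  StepCycles(onset = onset, offset = offset, degenerate = degenerate,
             phase = mask, beltSpeed = as.numeric(beltSpeed),
             fps = frameRate(series))
}
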