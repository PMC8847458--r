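# Per-cycle kinematic parameters: 44 columns in five categories.
#
# joint_angles (16): mean / flexion / extension / amplitude for hip,
#   knee, ankle, MTP.
# endpoint (12): step height, stride/swing/stance length, toe-crest
#   distance stats, toe coordinate amplitudes, swing speed stats, path
#   length, swing-relative time of peak height.
# temporal (8): durations, phase percentages, cadence, ratio, speed.
# variability (6): DTW costs vs the preceding cycle (x, y, 2-D; raw and
#   path-length-normalised).
# dragging (2): dragging % of swing, drag duration.

.JOINTS <- list(hip = c("crest", "hip", "knee"),
                knee = c("hip", "knee", "ankle"),
                ankle = c("knee", "ankle", "mtp"),
                mtp = c("ankle", "mtp", "toe"))

.parameterCategories <- function() {
  ja <- paste0(rep(names(.JOINTS), each = 4), "_angle_",
               rep(c("mean", "flexion", "extension", "amplitude"), 4))
  ep <- c("step_height", "stride_length", "swing_length", "stance_length",
          "toe_crest_distance_mean", "toe_crest_distance_max",
          "toe_x_amplitude", "toe_y_amplitude", "peak_swing_speed",
          "mean_swing_speed", "endpoint_path_length", "t_peak_height_pct")
  tm <- c("stride_duration", "stance_duration", "swing_duration",
          "stance_pct", "swing_pct", "cadence", "stance_swing_ratio",
          "stride_speed")
  vb <- c("dtw_x", "dtw_y", "dtw_distance",
          "dtw_x_norm", "dtw_y_norm", "dtw_dist_norm")
  dr <- c("dragging_pct", "drag_duration")
  stats::setNames(
    c(rep("joint_angles", 16), rep("endpoint", 12), rep("temporal", 8),
      rep("variability", 6), rep("dragging", 2)),
    c(ja, ep, tm, vb, dr))
}

#' Canonical kinematic parameter schema
#'
#' @return named character vector of length 44 mapping each parameter
#'   column name to its category (`joint_angles`, `endpoint`, `temporal`,
#'   `variability`, `dragging`). The schema is versioned: order and names
#'   are stable across inputs.
#' @export
kinematicParameterSchema <- function() .parameterCategories()

#' Per-frame interior joint angle
#'
#' Interior angle at `vertex` between the rays `vertex -> a` and
#' `vertex -> c`, in degrees within \[0, 180\]. Frames where either ray
#' has zero length give `NA`.
#'
#' @param series a [PoseSeries].
#' @param a,vertex,c body part names (three distinct markers).
#' @return numeric vector of per-frame angles (degrees).
#' @export
jointAngleSeries <- function(series, a, vertex, c) {
  stopifnot(length(unique(c(a, vertex, c))) == 3)
  pa <- .bp(series, a); pv <- .bp(series, vertex); pc <- .bp(series, c)
  .interiorAngle(pa$x, pa$y, pv$x, pv$y, pc$x, pc$y)
}

#' Per-cycle joint angle features
#'
#' Over the frames of one complete cycle: `flexion` is the minimum angle,
#' `extension` the maximum, `amplitude` their difference, `mean` the
#' arithmetic mean. If more than 20% of the cycle's angle frames are
#' missing, all four are `NA` with a warning.
#'
#' @param angleSeries per-frame angle vector from [jointAngleSeries()].
#' @param onset,offset cycle frame bounds (1-based, offset exclusive).
#' @return named numeric: `mean`, `flexion`, `extension`, `amplitude`.
#' @export
angleFeatures <- function(angleSeries, onset, offset) {
  a <- angleSeries[onset:(offset - 1)]
  if (mean(is.na(a)) > 0.2) {
    warning("more than 20% of angle frames missing in cycle; ",
            "features set to NA")
    return(c(mean = NA_real_, flexion = NA_real_, extension = NA_real_,
             amplitude = NA_real_))
  }
  a <- a[!is.na(a)]
  c(mean = mean(a), flexion = min(a), extension = max(a),
    amplitude = max(a) - min(a))
}

#' Per-cycle limb endpoint features
#'
#' Computed on the belt-adjusted series ([adjustCoordinates()]). Step
#' height is the maximal swing-phase clearance `groundY - toe_y` (y is
#' unaffected by adjustment). Lengths are adjusted toe x displacements:
#' the stride total and its swing/stance split (additive by
#' construction). Swing speeds are adjusted toe speeds in px/s.
#' `t_peak_height_pct` is the swing-relative time of the clearance
#' maximum in percent.
#'
#' @param seriesAdj belt-adjusted [PoseSeries].
#' @param cycles a [StepCycles].
#' @param i cycle index.
#' @param groundY ground line (px) from [dragFeatures()].
#' @param toe,crest body part names.
#' @return named numeric vector of the 12 endpoint parameters (all `NA`
#'   for degenerate full-drag cycles).
#' @export
endpointFeatures <- function(seriesAdj, cycles, i, groundY,
                             toe = "toe", crest = "crest") {
  nms <- names(.parameterCategories())
  nms <- nms[.parameterCategories() == "endpoint"]
  out <- stats::setNames(rep(NA_real_, length(nms)), nms)
  if (isDegenerate(cycles)[i]) return(out)
  on <- cycleOnsets(cycles)[i]; off <- cycleOffsets(cycles)[i]
  idx <- on:(off - 1)
  mask <- phaseMask(cycles)[idx]
  tp <- .bp(seriesAdj, toe); cr <- .bp(seriesAdj, crest)
  fps <- frameRate(seriesAdj)
  sw <- idx[mask == "swing"]
  clear <- groundY - tp$y[sw]
  out["step_height"] <- max(clear)
  out["stride_length"] <- tp$x[off] - tp$x[on]
  firstStance <- idx[which(mask == "stance")[1]]
  if (is.na(firstStance)) firstStance <- off
  out["swing_length"] <- tp$x[firstStance] - tp$x[on]
  out["stance_length"] <- tp$x[off] - tp$x[firstStance]
  dcx <- abs(tp$x[idx] - cr$x[idx])
  out["toe_crest_distance_mean"] <- mean(dcx)
  out["toe_crest_distance_max"] <- max(dcx)
  out["toe_x_amplitude"] <- diff(range(tp$x[idx]))
  out["toe_y_amplitude"] <- diff(range(tp$y[idx]))
  step <- sqrt(diff(tp$x[on:off])^2 + diff(tp$y[on:off])^2)
  swStep <- step[mask == "swing"]
  out["peak_swing_speed"] <- max(swStep) * fps
  out["mean_swing_speed"] <- mean(swStep) * fps
  out["endpoint_path_length"] <- sum(step)
  out["t_peak_height_pct"] <- if (length(sw) > 1)
    100 * (which.max(clear) - 1) / (length(sw) - 1) else 0
  out
}

#' Per-cycle temporal gait features
#'
#' @param cycles a [StepCycles].
#' @param i cycle index.
#' @param strideLength adjusted stride length (px) for `stride_speed`;
#'   `NA` gives `NA` speed.
#' @return named numeric: stride/stance/swing durations (s), stance and
#'   swing percentages (summing to 100), cadence (strides/s),
#'   stance/swing ratio, stride speed (px/s).
#' @export
temporalFeatures <- function(cycles, i, strideLength = NA_real_) {
  on <- cycleOnsets(cycles)[i]; off <- cycleOffsets(cycles)[i]
  fps <- cycles@fps
  mask <- phaseMask(cycles)[on:(off - 1)]
  nTot <- off - on
  nSt <- sum(mask == "stance")
  nSw <- nTot - nSt
  strideDur <- nTot / fps
  c(stride_duration = strideDur, stance_duration = nSt / fps,
    swing_duration = nSw / fps, stance_pct = 100 * nSt / nTot,
    swing_pct = 100 * nSw / nTot, cadence = 1 / strideDur,
    stance_swing_ratio = if (nSw > 0) nSt / nSw else Inf,
    stride_speed = strideLength / strideDur)
}

#' Dynamic time warping alignment cost
#'
#' Classic DTW between two trajectories (1-D vectors or point matrices
#' with one row per sample): Euclidean local cost, full window,
#' boundary-anchored, symmetric match/insert/delete step pattern. The
#' cost of a trajectory against itself is 0 and the measure is
#' symmetric. Used here to quantify spatial variability between
#' successive limb endpoint trajectories.
#'
#' @param a,b numeric vectors or matrices (rows = samples); non-empty.
#' @return nonnegative accumulated alignment cost, with attribute
#'   `pathLength` (number of alignment steps, for normalisation).
#' @export
dtwAlignmentCost <- function(a, b) {
  a <- if (is.matrix(a)) a else matrix(as.numeric(a), ncol = 1)
  b <- if (is.matrix(b)) b else matrix(as.numeric(b), ncol = 1)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty trajectory")
  r <- .gk_dtw(a, b)
  structure(r$cost, pathLength = r$pathLength)
}

#' Spatial variability via DTW between successive cycles
#'
#' For cycle `i >= 2`: `dtw_x` and `dtw_y` are 1-D costs on the x and y
#' components of the adjusted toe trajectory against cycle `i - 1`,
#' `dtw_distance` the 2-D cost; `*_norm` divide each by its alignment
#' path length. The first cycle has no predecessor: all six are `NA`.
#'
#' @param trajs list of per-cycle adjusted toe trajectories (two-column
#'   x/y matrices), each re-referenced to its cycle onset so that shape,
#'   not belt-frame progression, is compared; `NULL` entries (degenerate
#'   cycles) are skipped — a cycle is compared against the nearest
#'   preceding non-degenerate one.
#' @return data.frame with one row per cycle and the six DTW columns.
#' @export
variabilityFeatures <- function(trajs) {
  n <- length(trajs)
  nms <- c("dtw_x", "dtw_y", "dtw_distance",
           "dtw_x_norm", "dtw_y_norm", "dtw_dist_norm")
  out <- as.data.frame(matrix(NA_real_, n, 6, dimnames = list(NULL, nms)))
  valid <- !vapply(trajs, is.null, logical(1))
  if (sum(valid) < 2) {
    warning("fewer than 2 complete cycles: DTW variability undefined")
    return(out)
  }
  prev <- NA_integer_
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (!is.na(prev)) {
      a <- trajs[[prev]]; b <- trajs[[i]]
      cx <- dtwAlignmentCost(a[, 1], b[, 1])
      cy <- dtwAlignmentCost(a[, 2], b[, 2])
      cd <- dtwAlignmentCost(a, b)
      out[i, ] <- c(cx, cy, cd,
                    cx / attr(cx, "pathLength"),
                    cy / attr(cy, "pathLength"),
                    cd / attr(cd, "pathLength"))
    }
    prev <- i
  }
  out
}

#' Per-cycle dragging features and the ground line
#'
#' The ground line is the median toe y over all stance frames of the
#' trace. A swing frame drags iff its clearance `groundY - toe_y` is at
#' most `dragTolerancePx`. `dragging_pct` is the dragging percentage of
#' the cycle's swing frames; `drag_duration` the dragging time in
#' seconds. 100% dragging marks the cycle degenerate.
#'
#' @param series a [PoseSeries] (y is adjustment-invariant).
#' @param cycles a [StepCycles].
#' @param i cycle index.
#' @param toe toe body part name.
#' @param dragTolerancePx clearance tolerance (px), default 3.
#' @return named numeric: `dragging_pct`, `drag_duration`, `ground_y`.
#' @export
dragFeatures <- function(series, cycles, i, toe = "toe",
                         dragTolerancePx = 3) {
  y <- .bp(series, toe)$y
  mask <- phaseMask(cycles)
  if (!any(mask == "stance"))
    stop("no stance frames in trace: ground line undefined")
  groundY <- median(y[mask == "stance"])
  idx <- cycleOnsets(cycles)[i]:(cycleOffsets(cycles)[i] - 1)
  sw <- idx[mask[idx] == "swing"]
  if (!length(sw)) stop("cycle ", i, " has no swing frames")
  drag <- (groundY - y[sw]) <= dragTolerancePx
  c(dragging_pct = 100 * mean(drag),
    drag_duration = sum(drag) / frameRate(series),
    ground_y = groundY)
}

#' Extract the full 44-parameter table from a pose trace
#'
#' Runs the complete treadmill chain: low-confidence interpolation,
#' median smoothing, belt-speed estimation (or a fixed value),
#' coordinate adjustment, stance/swing classification, stride
#' segmentation, then all five parameter categories per complete cycle.
#' Degenerate full-drag cycles carry values only in the dragging
#' columns; the first cycle's six DTW columns are structurally missing.
#'
#' @param series a [PoseSeries] containing the six hindlimb markers
#'   named in `config$bodyparts`.
#' @param config an [analysisConfig()].
#' @return a [GaitParameterTable] with exactly 44 parameter columns
#'   (zero rows, schema intact, if no complete cycle is found).
#' @export
extractParameterTable <- function(series, config = analysisConfig()) {
  bp <- config$bodyparts
  need <- unlist(bp[c("toe", "mtp", "ankle", "knee", "hip", "crest")])
  missing <- setdiff(need, bodyparts(series))
  if (length(missing))
    stop("missing body parts: ", paste(missing, collapse = ", "))
  cats <- .parameterCategories()

  s <- cleanLowConfidence(series, config$likelihoodThreshold)
  s <- smoothSeries(s, config$smoothWindow)
  b <- if (identical(config$beltSpeed, "auto"))
    as.numeric(estimateBeltSpeed(s, bp$toe, config$smoothWindow))
  else as.numeric(config$beltSpeed)
  mask <- classifyPhases(s, bp$toe, b, config$minPhaseFrames,
                         config$smoothWindow)
  cycles <- segmentStrides(s, mask, b, bp$toe, config$dragTolerancePx)
  sAdj <- adjustCoordinates(s, b)

  n <- length(cycles)
  tab <- as.data.frame(matrix(NA_real_, n, length(cats),
                              dimnames = list(NULL, names(cats))))
  meta <- list(fps = frameRate(series), beltSpeed = b,
               provenance = series@provenance,
               nCycles = n, nDegenerate = sum(isDegenerate(cycles)),
               cycles = cycles)
  if (n == 0)
    return(GaitParameterTable(tab, cats, metadata = meta))

  angles <- lapply(.JOINTS, function(j)
    jointAngleSeries(s, bp[[j[1]]], bp[[j[2]]], bp[[j[3]]]))

  drags <- t(vapply(seq_len(n), function(i)
    dragFeatures(s, cycles, i, bp$toe, config$dragTolerancePx),
    numeric(3)))
  groundY <- drags[1, "ground_y"]

  trajs <- vector("list", n)
  tx <- .bp(sAdj, bp$toe)$x; ty <- .bp(sAdj, bp$toe)$y
  for (i in seq_len(n)) {
    tab[i, c("dragging_pct", "drag_duration")] <-
      drags[i, c("dragging_pct", "drag_duration")]
    if (isDegenerate(cycles)[i]) next
    on <- cycleOnsets(cycles)[i]; off <- cycleOffsets(cycles)[i]
    for (j in names(.JOINTS)) {
      f <- angleFeatures(angles[[j]], on, off)
      tab[i, paste0(j, "_angle_", names(f))] <- f
    }
    ef <- endpointFeatures(sAdj, cycles, i, groundY, bp$toe, bp$crest)
    tab[i, names(ef)] <- ef
    tf <- temporalFeatures(cycles, i, ef[["stride_length"]])
    tab[i, names(tf)] <- tf
    # cycle trajectories are re-referenced to their onset: the adjusted
    # x advances one stride length per cycle, which would swamp the
    # shape differences DTW is meant to measure
    trajs[[i]] <- cbind(tx[on:(off - 1)] - tx[on], ty[on:(off - 1)])
  }
  if (sum(!vapply(trajs, is.null, logical(1))) >= 2) {
    vf <- variabilityFeatures(trajs)
    tab[, names(vf)] <- vf
  }
  GaitParameterTable(tab, cats, metadata = meta)
}
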