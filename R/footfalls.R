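# Ladder-rung footfall detection from paw y-traces.
#
# In image coordinates y increases downward, so a paw slipping below the
# rung line produces a positive peak in raw y. The deviation algorithm is
# peak detection on that raw signal with a prominence threshold;
# prominence is the footfall depth. Deliberately permissive thresholds
# over-detect; a validation pass removes false positives.

# local maxima with plateau handling (peak = first frame of plateau top)
.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  peaks <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j])
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

# prominence and width bounds for each peak; the width is measured at
# relHeight * prominence below the peak (the exact prominence base sits
# at the surrounding minima, so its crossing is fragile under noise)
.peakProminences <- function(y, relHeight = 0.9) {
  peaks <- .localMaxima(y)
  n <- length(y)
  res <- lapply(peaks, function(p) {
    h <- y[p]
    j <- p - 1L; lmin <- h; lpos <- p
    while (j >= 1L && y[j] <= h) {
      if (y[j] < lmin) { lmin <- y[j]; lpos <- j }
      j <- j - 1L
    }
    j <- p + 1L; rmin <- h; rpos <- p
    while (j <= n && y[j] <= h) {
      if (y[j] < rmin) { rmin <- y[j]; rpos <- j }
      j <- j + 1L
    }
    prom <- h - max(lmin, rmin)
    level <- h - relHeight * prom
    on <- p
    while (on > lpos && y[on - 1L] > level) on <- on - 1L
    if (on > 1L) on <- on - 1L           # crossing sample at/below level
    off <- p
    while (off < rpos && y[off + 1L] > level) off <- off + 1L
    if (off < n) off <- off + 1L
    c(peak = p, prominence = prom, onset = on, offset = off)
  })
  if (!length(res))
    return(data.frame(peak = integer(), prominence = numeric(),
                      onset = integer(), offset = integer()))
  as.data.frame(do.call(rbind, res))
}

.eventsFromPeaks <- function(pk, paw, fps, y) {
  if (!nrow(pk))
    return(data.frame(paw = character(), onset = integer(),
                      offset = integer(), peak = integer(),
                      depth = numeric(), duration = numeric(),
                      validated = character()))
  pk <- pk[order(pk$peak), , drop = FALSE]
  # resolve overlaps at the valley between adjacent peaks
  if (nrow(pk) > 1) {
    for (i in seq_len(nrow(pk) - 1)) {
      if (pk$onset[i + 1] < pk$offset[i]) {
        valley <- pk$peak[i] +
          which.min(y[pk$peak[i]:pk$peak[i + 1]]) - 1L
        pk$offset[i] <- valley
        pk$onset[i + 1] <- valley
      }
    }
  }
  data.frame(paw = paw, onset = as.integer(pk$onset),
             offset = as.integer(pk$offset),
             peak = as.integer(pk$peak), depth = pk$prominence,
             duration = (pk$offset - pk$onset) / fps,
             validated = "auto", stringsAsFactors = FALSE)
}

#' Detect footfalls by peak prominence on the raw y signal
#'
#' The deviation algorithm: positive peaks in the raw paw y-coordinate
#' (dips below the rung line, since y points down) with prominence at
#' least `prominencePx` become events. Depth is the peak prominence;
#' onset and offset are the frames where the signal crosses the peak's
#' prominence base. A permissive threshold may yield false positives, to
#' be removed with [applyValidation()].
#'
#' @param series a [PoseSeries].
#' @param paw paw body part name.
#' @param prominencePx prominence (depth) threshold in px, > 0.
#' @return a [FootfallSet], events sorted by onset.
#' @export
detectFootfallsDeviation <- function(series, paw = "paw",
                                     prominencePx = 10) {
  stopifnot(prominencePx > 0)
  y <- .bp(series, paw)$y
  pk <- .peakProminences(y)
  pk <- pk[pk$prominence >= prominencePx, , drop = FALSE]
  FootfallSet(.eventsFromPeaks(pk, paw, frameRate(series), y),
              fps = frameRate(series), algorithm = "deviation")
}

#' Detect footfalls by fixed rung-line threshold
#'
#' Maximal runs of frames with excursion `y - rungY > minExcursionPx`
#' become events; depth is the maximal excursion in the run. Requires
#' the rung line to be known, which constrains the recording set-up.
#'
#' @param series a [PoseSeries].
#' @param paw paw body part name.
#' @param rungY image y of the rung line (px).
#' @param minExcursionPx minimal excursion below the line (px).
#' @return a [FootfallSet].
#' @export
detectFootfallsThreshold <- function(series, paw = "paw", rungY,
                                     minExcursionPx = 5) {
  y <- .bp(series, paw)$y
  exc <- y - rungY
  r <- rle(exc > minExcursionPx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  fps <- frameRate(series)
  rows <- lapply(keep, function(k) {
    on <- starts[k]; last <- ends[k]
    p <- on + which.max(exc[on:last]) - 1L
    off <- min(last + 1L, length(y))
    c(peak = p, prominence = max(exc[on:last]), onset = on, offset = off)
  })
  pk <- if (length(rows)) as.data.frame(do.call(rbind, rows))
  else data.frame(peak = integer(), prominence = numeric(),
                  onset = integer(), offset = integer())
  FootfallSet(.eventsFromPeaks(pk, paw, fps, y), fps = fps,
              algorithm = "threshold")
}

#' Detect footfalls after rolling-median baseline correction
#'
#' Subtracts a rolling-median baseline (window about 2 s) from y before
#' deviation-style peak detection — suited to traces where the camera or
#' ladder line drifts.
#'
#' @param series a [PoseSeries].
#' @param paw paw body part name.
#' @param prominencePx prominence threshold in px on the detrended
#'   signal.
#' @param baselineWindowS baseline window in seconds.
#' @return a [FootfallSet].
#' @export
detectFootfallsBaseline <- function(series, paw = "paw",
                                    prominencePx = 10,
                                    baselineWindowS = 2) {
  stopifnot(prominencePx > 0)
  y <- .bp(series, paw)$y
  w <- round(baselineWindowS * frameRate(series))
  if (w %% 2 == 0) w <- w + 1L
  if (length(y) < w)
    stop("trace shorter than the baseline window (", w, " frames)")
  det <- y - .medfilt(y, w)
  pk <- .peakProminences(det)
  pk <- pk[pk$prominence >= prominencePx, , drop = FALSE]
  FootfallSet(.eventsFromPeaks(pk, paw, frameRate(series), det),
              fps = frameRate(series), algorithm = "baseline")
}

#' Apply validation decisions to detected footfalls
#'
#' Replaces the interactive validation pass: rejected events are removed,
#' survivors are marked `accepted`, order is preserved. Decisions may be
#' a character vector (`"accept"`/`"reject"`, positional, `NA` or
#' missing trailing entries mean accept) or a data.frame with columns
#' `event` (index) and `decision`.
#'
#' @param ff a [FootfallSet].
#' @param decisions decisions as described above.
#' @return the validated [FootfallSet].
#' @export
applyValidation <- function(ff, decisions = character()) {
  ev <- footfallEvents(ff)
  n <- nrow(ev)
  dec <- rep("accept", n)
  if (is.data.frame(decisions)) {
    if (nrow(decisions) && (any(decisions$event < 1) ||
                            any(decisions$event > n)))
      stop("decision index out of range (", n, " events)")
    dec[decisions$event] <- as.character(decisions$decision)
  } else if (length(decisions)) {
    if (length(decisions) > n)
      stop("decision index out of range (", n, " events)")
    d <- as.character(decisions)
    dec[seq_along(d)][!is.na(d)] <- d[!is.na(d)]
  }
  if (!all(dec %in% c("accept", "reject")))
    stop("decisions must be 'accept' or 'reject'")
  ev <- ev[dec == "accept", , drop = FALSE]
  if (nrow(ev)) ev$validated <- "accepted"
  rownames(ev) <- NULL
  FootfallSet(ev, fps = ff@fps, algorithm = ff@algorithm)
}

#' Summarise footfalls into the three parameter families
#'
#' @param ff a [FootfallSet] (typically after validation).
#' @param nRuns number of ladder runs the events came from, >= 1.
#' @return an object of class `footfallSummary`: a list with the three
#'   families `number` (count, mean per run), `depth` (mean, total; px)
#'   and `duration` (mean, total; s). Empty event sets give zeros.
#' @export
footfallSummary <- function(ff, nRuns = 1) {
  stopifnot(nRuns >= 1)
  ev <- footfallEvents(ff)
  m <- function(v) if (length(v)) mean(v) else 0
  out <- list(
    number = c(count = nrow(ev), mean_per_run = nrow(ev) / nRuns),
    depth = c(mean = m(ev$depth), total = sum(ev$depth)),
    duration = c(mean = m(ev$duration), total = sum(ev$duration)))
  class(out) <- "footfallSummary"
  out
}

#' @export
print.footfallSummary <- function(x, ...) {
  cat("Footfall summary\n")
  cat(sprintf("  number:   count %d, mean/run %.3g\n",
              as.integer(x$number["count"]), x$number["mean_per_run"]))
  cat(sprintf("  depth:    mean %.3g px, total %.3g px\n",
              x$depth["mean"], x$depth["total"]))
  cat(sprintf("  duration: mean %.3g s, total %.3g s\n",
              x$duration["mean"], x$duration["total"]))
  invisible(x)
}
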