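# Reading, quality-filtering and smoothing of pose-estimation tables.
#
# The text dialect is the three-header-row CSV emitted by common
# markerless-tracking software: row 1 "scorer", row 2 body part names
# repeated x3, row 3 coords in {x, y, likelihood}; first column is the
# 0-based frame index.

#' Read a pose-estimation coordinate table
#'
#' Parses the three-header-row CSV dialect (scorer / bodyparts / coords)
#' into a [PoseSeries]. Coordinates are passed through unaltered; the
#' frame index column is checked but not stored (frames are positional).
#'
#' @param path path to the coordinate table.
#' @param fps recording frame rate (frames/second), > 0.
#' @return a [PoseSeries] with every body part in file order.
#' @seealso [writePoseTable()] for the inverse, [cleanLowConfidence()] and
#'   [smoothSeries()] for the standard preprocessing chain.
#' @export
readPoseTable <- function(path, fps) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    stop("fps must be a single positive number")
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L)
    stop("format error: expected 3 header rows (scorer/bodyparts/coords), ",
         "got ", length(hdr))
  h2 <- strsplit(hdr[2], ",", fixed = TRUE)[[1]]
  h3 <- strsplit(hdr[3], ",", fixed = TRUE)[[1]]
  if (!grepl("bodyparts", h2[1], ignore.case = TRUE))
    stop("format error in header row 2: expected 'bodyparts' label, got '",
         h2[1], "'")
  if (!grepl("coords", h3[1], ignore.case = TRUE))
    stop("format error in header row 3: expected 'coords' label, got '",
         h3[1], "'")
  bps <- h2[-1]
  coords <- h3[-1]
  if (length(bps) != length(coords) || length(bps) == 0 ||
      length(bps) %% 3 != 0)
    stop("format error: header rows 2/3 must list x,y,likelihood triples")
  parts <- bps[seq(1, length(bps), by = 3)]
  if (anyDuplicated(parts))
    stop("format error: duplicate body part names: ",
         paste(unique(parts[duplicated(parts)]), collapse = ", "))
  for (i in seq_along(parts)) {
    idx <- (i - 1) * 3 + 1:3
    if (!all(bps[idx] == parts[i]))
      stop("format error in header row 2: body part names must repeat x3")
    if (!identical(tolower(coords[idx]), c("x", "y", "likelihood")))
      stop("format error in header row 3: coords for '", parts[i],
           "' must be x,y,likelihood, got ",
           paste(coords[idx], collapse = ","))
  }
  dat <- read.csv(path, skip = 3, header = FALSE,
                  colClasses = "character", strip.white = TRUE)
  if (ncol(dat) != length(bps) + 1)
    stop("format error: data rows have ", ncol(dat),
         " columns, header implies ", length(bps) + 1)
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(dat[, -1, drop = FALSE])),
           nrow = nrow(dat)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("parse error: non-numeric value at frame ", bad["row"] - 1,
         ", body part '", parts[ceiling(bad["col"] / 3)], "'")
  }
  xm <- t(vals[, seq(1, ncol(vals), by = 3), drop = FALSE])
  ym <- t(vals[, seq(2, ncol(vals), by = 3), drop = FALSE])
  lm <- t(vals[, seq(3, ncol(vals), by = 3), drop = FALSE])
  rownames(xm) <- parts
  PoseSeries(xm, ym, lm, fps = fps, provenance = path)
}

#' Write a PoseSeries as a pose coordinate table
#'
#' Emits the exact three-header-row text dialect read by
#' [readPoseTable()], so that `readPoseTable(writePoseTable(s))` is the
#' identity. The first column is the 0-based frame index.
#'
#' @param series a [PoseSeries].
#' @param path output file path.
#' @param scorer scorer name for header row 1.
#' @return `path`, invisibly.
#' @export
writePoseTable <- function(series, path, scorer = "gaitkin") {
  parts <- bodyparts(series)
  n <- nFrames(series)
  h1 <- paste(c("scorer", rep(scorer, 3 * length(parts))), collapse = ",")
  h2 <- paste(c("bodyparts", rep(parts, each = 3)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
              collapse = ",")
  cols <- vector("list", 3 * length(parts))
  for (i in seq_along(parts)) {
    bp <- .bp(series, parts[i])
    cols[[(i - 1) * 3 + 1]] <- bp$x
    cols[[(i - 1) * 3 + 2]] <- bp$y
    cols[[(i - 1) * 3 + 3]] <- bp$likelihood
  }
  body <- do.call(cbind, lapply(cols, function(v) sprintf("%.17g", v)))
  rows <- apply(cbind(seq_len(n) - 1L, body), 1, paste, collapse = ",")
  writeLines(c(h1, h2, h3, rows), path)
  invisible(path)
}

#' Interpolate low-confidence pose samples
#'
#' Samples whose likelihood falls below `threshold` have x and y replaced
#' by linear interpolation between the nearest flanking samples at or
#' above the threshold; leading/trailing low-confidence runs are filled
#' with the nearest valid value. Likelihoods are preserved, so the
#' operation is idempotent at a fixed threshold. The per-body-part count
#' of replaced samples is recorded in
#' `metadata(result)$replacedLowConfidence`.
#'
#' @param series a [PoseSeries].
#' @param threshold likelihood cutoff in \[0, 1\]; default 0.6.
#' @return a cleaned [PoseSeries].
#' @export
cleanLowConfidence <- function(series, threshold = 0.6) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  xm <- poseX(series); ym <- poseY(series); lm <- poseLikelihood(series)
  replaced <- integer(nrow(xm)); names(replaced) <- rownames(xm)
  for (i in seq_len(nrow(xm))) {
    ok <- lm[i, ] >= threshold
    if (!any(ok))
      stop("body part '", rownames(xm)[i], "' has no samples with ",
           "likelihood >= ", threshold, "; cannot interpolate")
    if (all(ok)) next
    idx <- seq_len(ncol(xm))
    xm[i, !ok] <- stats::approx(idx[ok], xm[i, ok], xout = idx[!ok],
                                rule = 2)$y
    ym[i, !ok] <- stats::approx(idx[ok], ym[i, ok], xout = idx[!ok],
                                rule = 2)$y
    replaced[i] <- sum(!ok)
  }
  out <- PoseSeries(xm, ym, lm, fps = frameRate(series),
                    provenance = series@provenance)
  metadata(out)$replacedLowConfidence <- replaced
  out
}

# centered median filter with shrinking windows at the edges
.medfilt <- function(v, window) {
  if (window == 1 || length(v) <= 2) return(v)
  k <- min(window, if (length(v) %% 2 == 0) length(v) - 1 else length(v))
  out <- stats::runmed(v, k, endrule = "keep")
  h <- (k - 1) / 2
  for (i in seq_len(h)) {
    out[i] <- median(v[seq_len(i + h)])
    j <- length(v) - i + 1
    out[j] <- median(v[seq(j - h, length(v))])
  }
  out
}

#' Median-smooth pose coordinates
#'
#' Replaces x and y with a centered running median of odd width `window`
#' (shrinking windows at the edges); likelihoods are untouched. The median
#' (rather than a mean) rejects the heavy-tailed single-frame glitches
#' typical of marker identity swaps in tracking output.
#'
#' @param series a [PoseSeries].
#' @param window odd window width in frames, `1 <= window < nFrames`;
#'   default 5 (at 120 fps).
#' @return the smoothed [PoseSeries].
#' @export
smoothSeries <- function(series, window = 5) {
  if (!is.numeric(window) || length(window) != 1 || window %% 2 != 1)
    stop("window must be a single odd integer")
  if (window < 1 || window >= nFrames(series))
    stop("window must satisfy 1 <= window < number of frames")
  xm <- poseX(series); ym <- poseY(series)
  for (i in seq_len(nrow(xm))) {
    xm[i, ] <- .medfilt(xm[i, ], window)
    ym[i, ] <- .medfilt(ym[i, ], window)
  }
  PoseSeries(xm, ym, poseLikelihood(series), fps = frameRate(series),
             provenance = series@provenance)
}
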