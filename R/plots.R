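# Core visualisations: per-cycle endpoint trajectories coloured by
# phase, PCA scree, RF confusion matrix, and the footfall trace.

#' Plot per-cycle adjusted endpoint trajectories
#'
#' Overlays the belt-adjusted toe path of every complete cycle, coloured
#' by phase (swing green, stance grey), on the current device. Height is
#' drawn positive-up (`groundY - y`).
#'
#' @param seriesAdj belt-adjusted [PoseSeries].
#' @param cycles a [StepCycles] with at least one cycle.
#' @param toe toe body part name.
#' @return invisibly, the number of cycles drawn.
#' @export
plotTrajectories <- function(seriesAdj, cycles, toe = "toe") {
  if (length(cycles) == 0) stop("no cycles to plot")
  tp <- .bp(seriesAdj, toe)
  mask <- phaseMask(cycles)
  on <- cycleOnsets(cycles); off <- cycleOffsets(cycles)
  idxAll <- on[1]:(off[length(off)] - 1)
  gy <- median(tp$y[mask == "stance"])
  plot(NA, xlim = range(tp$x[idxAll]), ylim = range(gy - tp$y[idxAll]),
       xlab = "adjusted toe x (px)", ylab = "toe height (px)",
       main = "Endpoint trajectories by phase")
  cols <- c(stance = "grey55", swing = "forestgreen")
  drawn <- 0L
  for (i in seq_along(on)) {
    idx <- on[i]:(off[i] - 1)
    segments(tp$x[idx[-length(idx)]], gy - tp$y[idx[-length(idx)]],
             tp$x[idx[-1]], gy - tp$y[idx[-1]],
             col = cols[mask[idx[-1]]])
    drawn <- drawn + 1L
  }
  legend("topright", legend = names(cols), col = cols, lwd = 2, bty = "n")
  invisible(drawn)
}

#' Scree plot of explained-variance ratios
#'
#' @param result a [GaitPCA].
#' @param maxComponents number of leading components to show.
#' @return invisibly, the plotted ratios.
#' @export
plotScree <- function(result, maxComponents = 15) {
  ev <- result@explainedVar
  if (!length(ev)) stop("no components to plot")
  k <- min(maxComponents, length(ev))
  bp <- barplot(100 * ev[seq_len(k)], names.arg = paste0("PC", seq_len(k)),
                ylab = "explained variance (%)", main = "Scree plot",
                col = "steelblue")
  lines(bp, 100 * cumsum(ev[seq_len(k)]), type = "b", pch = 19)
  invisible(ev[seq_len(k)])
}

#' Confusion-matrix heat map
#'
#' @param result a [GaitClassification].
#' @return invisibly, the confusion matrix.
#' @export
plotConfusion <- function(result) {
  cm <- result@confusion
  if (!sum(cm)) stop("empty confusion matrix")
  n <- nrow(cm)
  image(seq_len(n), seq_len(n), t(cm[n:1, , drop = FALSE]),
        col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE),
        axes = FALSE, xlab = "predicted", ylab = "true",
        main = sprintf("Held-out accuracy %.1f%%", 100 * result@accuracy))
  axis(1, seq_len(n), colnames(cm))
  axis(2, seq_len(n), rev(rownames(cm)))
  for (i in seq_len(n)) for (j in seq_len(n))
    text(j, n - i + 1, cm[i, j])
  invisible(cm)
}

#' Plot a paw y-trace with detected footfalls
#'
#' Draws the raw paw y signal (image-down, so dips below the rung line
#' point up in the plot is avoided by keeping native orientation) and
#' marks each detected event's onset/offset span, peak and depth.
#'
#' @param series the [PoseSeries] the events were detected on.
#' @param ff a [FootfallSet].
#' @param paw paw body part name.
#' @return invisibly, the number of events marked.
#' @export
plotFootfalls <- function(series, ff, paw = "paw") {
  y <- .bp(series, paw)$y
  ev <- footfallEvents(ff)
  plot(seq_along(y), y, type = "l", col = "grey30", ylim = rev(range(y)),
       xlab = "frame", ylab = "paw y (px, image down)",
       main = sprintf("Footfalls: %d events", nrow(ev)))
  if (nrow(ev)) {
    rect(ev$onset, max(y), ev$offset, min(y),
         col = grDevices::adjustcolor("firebrick", 0.15), border = NA)
    points(ev$peak, y[ev$peak], pch = 19, col = "firebrick")
    text(ev$peak, y[ev$peak], sprintf("%.1f px", ev$depth),
         pos = 4, cex = 0.7, col = "firebrick")
  }
  invisible(nrow(ev))
}
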