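#' PoseSeries: per-frame 2D pose coordinates with tracking confidence
#'
#' Container for the per-frame (x, y, likelihood) output of markerless pose
#' estimation for a set of named body parts at a fixed frame rate. Extends
#' \linkS4class{SummarizedExperiment}: rows are body parts, columns are
#' frames, and the three assays are `x` (px), `y` (px, image coordinates
#' with y increasing downward), and `likelihood` (in \[0, 1\]).
#'
#' All height-like quantities downstream are computed as
#' `ground_y - y` so they read positive-up despite the image axis.
#'
#' @param x For the constructor: numeric matrix of x coordinates
#'   (body parts in rows, frames in columns). For accessors: a `PoseSeries`.
#' @param y numeric matrix of y coordinates, same dimensions as `x`.
#' @param likelihood numeric matrix of per-sample tracking confidence in
#'   \[0, 1\], same dimensions as `x`.
#' @param fps frames per second, > 0.
#' @param provenance character scalar, source file path or `"synthetic"`.
#'
#' @return `PoseSeries()` returns a `PoseSeries` object. `poseX`, `poseY`
#'   and `poseLikelihood` return body part x frame matrices; `bodyparts`
#'   the body part names; `nFrames` the frame count; `frameRate` the fps.
#'
#' @examples
#' x <- matrix(0:9, nrow = 1, dimnames = list("toe", NULL))
#' ps <- PoseSeries(x, x + 100, x * 0 + 1, fps = 120)
#' bodyparts(ps)
#' nFrames(ps)
#'
#' @aliases bodyparts nFrames frameRate poseX poseY poseLikelihood
#' @export PoseSeries
#' @exportClass PoseSeries
.PoseSeries <- setClass("PoseSeries",
  contains = "SummarizedExperiment",
  slots = c(fps = "numeric", provenance = "character")
)

setValidity("PoseSeries", function(object) {
  msg <- character()
  need <- c("x", "y", "likelihood")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, "assays must include 'x', 'y' and 'likelihood'")
  if (length(object@fps) != 1 || is.na(object@fps) || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  if (ncol(object) < 2)
    msg <- c(msg, "a PoseSeries needs at least 2 frames")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "body part names must be present and unique")
  if (all(need %in% assayNames(object))) {
    lik <- assay(object, "likelihood")
    if (anyNA(lik) || any(lik < 0) || any(lik > 1))
      msg <- c(msg, "likelihood values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

PoseSeries <- function(x, y, likelihood, fps, provenance = "synthetic") {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  stopifnot(identical(dim(x), dim(y)), identical(dim(x), dim(likelihood)))
  if (is.null(rownames(x)))
    stop("x must have body part names as rownames")
  rownames(y) <- rownames(likelihood) <- rownames(x)
  se <- SummarizedExperiment(assays = list(x = x, y = y,
                                           likelihood = likelihood))
  .PoseSeries(se, fps = as.numeric(fps), provenance = provenance)
}

#' @rdname PoseSeries-class
#' @export
setMethod("bodyparts", "PoseSeries", function(x) rownames(x))

#' @rdname PoseSeries-class
#' @export
setMethod("nFrames", "PoseSeries", function(x) ncol(x))

#' @rdname PoseSeries-class
#' @export
setMethod("frameRate", "PoseSeries", function(x) x@fps)

#' @rdname PoseSeries-class
#' @export
setMethod("poseX", "PoseSeries", function(x) assay(x, "x"))

#' @rdname PoseSeries-class
#' @export
setMethod("poseY", "PoseSeries", function(x) assay(x, "y"))

#' @rdname PoseSeries-class
#' @export
setMethod("poseLikelihood", "PoseSeries",
          function(x) assay(x, "likelihood"))

setMethod("show", "PoseSeries", function(object) {
  cat("PoseSeries:", nrow(object), "body parts x", ncol(object),
      "frames @", object@fps, "fps\n")
  cat("  bodyparts:", paste(rownames(object), collapse = ", "), "\n")
  cat("  provenance:", object@provenance, "\n")
})

# pull one body part as a list of per-frame vectors
.bp <- function(series, name) {
  if (!name %in% rownames(series))
    stop("unknown body part: '", name, "'")
  list(x = as.numeric(assay(series, "x")[name, ]),
       y = as.numeric(assay(series, "y")[name, ]),
       likelihood = as.numeric(assay(series, "likelihood")[name, ]))
}


#' StepCycles: segmented stride cycles with stance/swing phase mask
#'
#' One object holds all complete stride cycles segmented from a trace,
#' the full per-frame phase mask, and the belt-speed context. Cycles run
#' from one toe-off (stance-to-swing transition) to the next; `offset` is
#' exclusive and equals the next cycle's onset, so cycles tile the span
#' between first and last toe-off. Cycles in which the toe never clears
#' the ground during swing are flagged degenerate (full drag): only
#' cycle-independent parameters are computed for those.
#'
#' @param x a `StepCycles` object.
#'
#' @return `cycleOnsets`/`cycleOffsets` return integer frame indices
#'   (1-based, offsets exclusive); `phaseMask` the full-trace
#'   `"stance"`/`"swing"` vector; `beltSpeed` the belt speed in px/frame;
#'   `isDegenerate` the per-cycle full-drag flag.
#'
#' @aliases cycleOnsets cycleOffsets phaseMask beltSpeed isDegenerate
#' @export StepCycles
#' @exportClass StepCycles
.StepCycles <- setClass("StepCycles",
  slots = c(onset = "integer", offset = "integer", degenerate = "logical",
            phase = "character", beltSpeed = "numeric", fps = "numeric")
)

setValidity("StepCycles", function(object) {
  msg <- character()
  n <- length(object@onset)
  if (length(object@offset) != n || length(object@degenerate) != n)
    msg <- c(msg, "onset, offset and degenerate must have equal length")
  if (n > 0) {
    if (any(object@onset >= object@offset))
      msg <- c(msg, "every cycle must satisfy onset < offset")
    if (n > 1 && any(object@onset[-1] != object@offset[-n]))
      msg <- c(msg, "cycles must tile: each onset equals previous offset")
  }
  if (!all(object@phase %in% c("stance", "swing")))
    msg <- c(msg, "phase mask entries must be 'stance' or 'swing'")
  if (length(msg)) msg else TRUE
})

StepCycles <- function(onset = integer(), offset = integer(),
                       degenerate = logical(length(onset)),
                       phase = character(), beltSpeed = NA_real_,
                       fps = NA_real_) {
  .StepCycles(onset = as.integer(onset), offset = as.integer(offset),
              degenerate = degenerate, phase = phase,
              beltSpeed = beltSpeed, fps = fps)
}

#' @rdname StepCycles-class
#' @export
setMethod("length", "StepCycles", function(x) length(x@onset))

#' @rdname StepCycles-class
#' @export
setMethod("cycleOnsets", "StepCycles", function(x) x@onset)

#' @rdname StepCycles-class
#' @export
setMethod("cycleOffsets", "StepCycles", function(x) x@offset)

#' @rdname StepCycles-class
#' @export
setMethod("phaseMask", "StepCycles", function(x) x@phase)

#' @rdname StepCycles-class
#' @export
setMethod("beltSpeed", "StepCycles", function(x) x@beltSpeed)

#' @rdname StepCycles-class
#' @export
setMethod("isDegenerate", "StepCycles", function(x) x@degenerate)

setMethod("show", "StepCycles", function(object) {
  cat("StepCycles:", length(object@onset), "complete cycles",
      sprintf("(%d degenerate full-drag)", sum(object@degenerate)), "\n")
  cat("  belt speed:", format(object@beltSpeed, digits = 4), "px/frame @",
      object@fps, "fps\n")
})


#' GaitParameterTable: per-cycle kinematic parameters in five categories
#'
#' One row per complete stride cycle, exactly 44 named numeric parameter
#' columns, each tagged with one of five categories: `joint_angles` (16),
#' `endpoint` (12), `temporal` (8), `variability` (6, dynamic time
#' warping), `dragging` (2). Degenerate full-drag cycles carry values only
#' in the cycle-independent dragging columns; the first cycle's six DTW
#' columns are structurally missing (no preceding cycle to compare to).
#'
#' @param x a `GaitParameterTable`.
#'
#' @return `paramTable` returns the cycles x 44 data.frame;
#'   `paramCategories` the named category vector; `groupLabels` the
#'   per-row group factor (length zero when unlabeled).
#'
#' @aliases paramTable paramCategories groupLabels
#' @export GaitParameterTable
#' @exportClass GaitParameterTable
.GaitParameterTable <- setClass("GaitParameterTable",
  slots = c(params = "data.frame", categories = "character",
            group = "factor", metadata = "list")
)

setValidity("GaitParameterTable", function(object) {
  msg <- character()
  if (!identical(sort(names(object@params)), sort(names(object@categories))))
    msg <- c(msg, "every parameter column must carry a category tag")
  if (length(object@group) && length(object@group) != nrow(object@params))
    msg <- c(msg, "group labels must match the number of rows")
  if (length(msg)) msg else TRUE
})

GaitParameterTable <- function(params, categories, group = factor(),
                               metadata = list()) {
  .GaitParameterTable(params = params, categories = categories,
                      group = group, metadata = metadata)
}

#' @rdname GaitParameterTable-class
#' @export
setMethod("paramTable", "GaitParameterTable", function(x) x@params)

#' @rdname GaitParameterTable-class
#' @export
setMethod("paramCategories", "GaitParameterTable", function(x) x@categories)

#' @rdname GaitParameterTable-class
#' @export
setMethod("groupLabels", "GaitParameterTable", function(x) x@group)

#' @rdname GaitParameterTable-class
#' @export
setMethod("dim", "GaitParameterTable", function(x) dim(x@params))

setMethod("show", "GaitParameterTable", function(object) {
  cat("GaitParameterTable:", nrow(object@params), "cycles x",
      ncol(object@params), "parameters\n")
  tb <- table(object@categories)
  cat("  categories:", paste(names(tb), tb, sep = "=", collapse = ", "),
      "\n")
  if (length(object@group))
    cat("  groups:", paste(levels(object@group), collapse = ", "), "\n")
})


#' FootfallSet: detected ladder-rung footfall events
#'
#' Events detected on a paw y-trace during ladder crossings. Each event
#' carries onset/offset/peak frames, depth (px; the peak prominence of the
#' dip below the rung line) and duration (s), plus a validation state in
#' `auto`, `accepted`, `rejected`.
#'
#' @param x a `FootfallSet`.
#' @return `footfallEvents` returns the events data.frame (one row per
#'   event, ordered by onset).
#'
#' @aliases footfallEvents
#' @export FootfallSet
#' @exportClass FootfallSet
.FootfallSet <- setClass("FootfallSet",
  slots = c(events = "data.frame", fps = "numeric", algorithm = "character")
)

setValidity("FootfallSet", function(object) {
  msg <- character()
  ev <- object@events
  need <- c("paw", "onset", "offset", "peak", "depth", "duration",
            "validated")
  if (!all(need %in% names(ev)))
    msg <- c(msg, paste("events must have columns:",
                        paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (any(ev$onset > ev$peak | ev$peak > ev$offset))
      msg <- c(msg, "each event must satisfy onset <= peak <= offset")
    if (any(ev$depth <= 0)) msg <- c(msg, "depth must be > 0")
    if (any(ev$duration <= 0)) msg <- c(msg, "duration must be > 0")
    if (!all(ev$validated %in% c("auto", "accepted", "rejected")))
      msg <- c(msg, "validated must be auto/accepted/rejected")
  }
  if (length(msg)) msg else TRUE
})

FootfallSet <- function(events, fps, algorithm = "deviation") {
  .FootfallSet(events = events, fps = as.numeric(fps),
               algorithm = algorithm)
}

#' @rdname FootfallSet-class
#' @export
setMethod("footfallEvents", "FootfallSet", function(x) x@events)

#' @rdname FootfallSet-class
#' @export
setMethod("length", "FootfallSet", function(x) nrow(x@events))

setMethod("show", "FootfallSet", function(object) {
  cat("FootfallSet:", nrow(object@events), "events (",
      object@algorithm, "algorithm )\n")
  if (nrow(object@events))
    cat("  mean depth:", format(mean(object@events$depth), digits = 4),
        "px; mean duration:",
        format(mean(object@events$duration), digits = 4), "s\n")
})


#' GaitClassification: held-out random-forest classification result
#'
#' @slot accuracy held-out accuracy in \[0, 1\].
#' @slot confusion confusion matrix on the test split (rows = true class,
#'   columns = predicted class).
#' @slot importance per-parameter Gini importances, normalised to sum 1,
#'   sorted descending.
#' @slot trainSize,testSize split sizes.
#' @slot seed RNG seed used for the split and forest.
#'
#' @export GaitClassification
#' @exportClass GaitClassification
.GaitClassification <- setClass("GaitClassification",
  slots = c(accuracy = "numeric", confusion = "matrix",
            importance = "numeric", trainSize = "integer",
            testSize = "integer", seed = "integer")
)

setValidity("GaitClassification", function(object) {
  msg <- character()
  if (abs(sum(object@importance) - 1) > 1e-9)
    msg <- c(msg, "importances must sum to 1")
  if (sum(object@confusion) != object@testSize)
    msg <- c(msg, "confusion matrix total must equal test size")
  acc <- sum(diag(object@confusion)) / sum(object@confusion)
  if (abs(acc - object@accuracy) > 1e-9)
    msg <- c(msg, "accuracy must equal confusion-matrix trace/total")
  if (length(msg)) msg else TRUE
})

GaitClassification <- function(accuracy, confusion, importance, trainSize,
                               testSize, seed) {
  .GaitClassification(accuracy = accuracy, confusion = confusion,
                      importance = importance,
                      trainSize = as.integer(trainSize),
                      testSize = as.integer(testSize),
                      seed = as.integer(seed))
}

setMethod("show", "GaitClassification", function(object) {
  cat("GaitClassification: held-out accuracy",
      format(object@accuracy, digits = 4),
      sprintf("(train %d / test %d, seed %d)\n", object@trainSize,
              object@testSize, object@seed))
  cat("  top importances:",
      paste(names(head(object@importance, 3)),
            format(head(object@importance, 3), digits = 3),
            sep = "=", collapse = ", "), "\n")
})


#' GaitPCA: principal component analysis of standardized gait parameters
#'
#' Correlation-matrix PCA: columns are standardized to mean 0, sd 1 before
#' eigendecomposition. Loadings are eigenvectors scaled by the square root
#' of their eigenvalues (component standard deviations).
#'
#' @slot scores per-cycle scores on all components.
#' @slot rotation orthonormal eigenvector matrix (parameters x components).
#' @slot loadings factor loadings (parameters x components).
#' @slot explainedVar explained-variance ratios, nonincreasing, sum 1.
#' @slot center,scale per-column standardization parameters.
#' @slot dropped names of zero-variance columns removed before PCA.
#'
#' @export GaitPCA
#' @exportClass GaitPCA
.GaitPCA <- setClass("GaitPCA",
  slots = c(scores = "matrix", rotation = "matrix", loadings = "matrix",
            explainedVar = "numeric", center = "numeric", scale = "numeric",
            dropped = "character")
)

setValidity("GaitPCA", function(object) {
  msg <- character()
  ev <- object@explainedVar
  if (length(ev)) {
    if (any(diff(ev) > 1e-12)) msg <- c(msg, "ratios must be nonincreasing")
    if (any(ev < -1e-12 | ev > 1 + 1e-12))
      msg <- c(msg, "ratios must lie in [0, 1]")
    if (abs(sum(ev) - 1) > 1e-9) msg <- c(msg, "ratios must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

GaitPCA <- function(scores, rotation, loadings, explainedVar, center,
                    scale, dropped = character()) {
  .GaitPCA(scores = scores, rotation = rotation, loadings = loadings,
           explainedVar = explainedVar, center = center, scale = scale,
           dropped = dropped)
}

setMethod("show", "GaitPCA", function(object) {
  k <- min(3L, length(object@explainedVar))
  cat("GaitPCA:", nrow(object@scores), "cycles,",
      length(object@explainedVar), "components\n")
  cat("  explained variance:",
      paste0("PC", seq_len(k), "=",
             format(100 * object@explainedVar[seq_len(k)], digits = 3),
             "%", collapse = ", "), "\n")
  if (length(object@dropped))
    cat("  dropped zero-variance columns:",
        paste(object@dropped, collapse = ", "), "\n")
})
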