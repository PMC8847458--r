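#' @rdname PoseSeries-class
#' @export
setGeneric("bodyparts", function(x) standardGeneric("bodyparts"))

#' @rdname PoseSeries-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname PoseSeries-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname PoseSeries-class
#' @export
setGeneric("poseX", function(x) standardGeneric("poseX"))

#' @rdname PoseSeries-class
#' @export
setGeneric("poseY", function(x) standardGeneric("poseY"))

#' @rdname PoseSeries-class
#' @export
setGeneric("poseLikelihood", function(x) standardGeneric("poseLikelihood"))

#' @rdname StepCycles-class
#' @export
setGeneric("cycleOnsets", function(x) standardGeneric("cycleOnsets"))

#' @rdname StepCycles-class
#' @export
setGeneric("cycleOffsets", function(x) standardGeneric("cycleOffsets"))

#' @rdname StepCycles-class
#' @export
setGeneric("phaseMask", function(x) standardGeneric("phaseMask"))

#' @rdname StepCycles-class
#' @export
setGeneric("beltSpeed", function(x) standardGeneric("beltSpeed"))

#' @rdname StepCycles-class
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname GaitParameterTable-class
#' @export
setGeneric("paramTable", function(x) standardGeneric("paramTable"))

#' @rdname GaitParameterTable-class
#' @export
setGeneric("paramCategories", function(x) standardGeneric("paramCategories"))

#' @rdname GaitParameterTable-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname FootfallSet-class
#' @export
setGeneric("footfallEvents", function(x) standardGeneric("footfallEvents"))
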