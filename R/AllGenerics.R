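#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Each has methods
#' documented on the corresponding class page.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The stored component (see the method documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("emgSignal", function(x) standardGeneric("emgSignal"))

#' @rdname accessors
#' @export
setGeneric("pressureSignal", function(x) standardGeneric("pressureSignal"))

#' @rdname accessors
#' @export
setGeneric("accSignal", function(x) standardGeneric("accSignal"))

#' @rdname accessors
#' @export
setGeneric("videoStream", function(x) standardGeneric("videoStream"))

#' @rdname accessors
#' @export
setGeneric("samplingRates", function(x) standardGeneric("samplingRates"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("getFrames", function(x, idx) standardGeneric("getFrames"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("sensorId", function(x) standardGeneric("sensorId"))

#' @rdname accessors
#' @export
setGeneric("activityStats", function(x) standardGeneric("activityStats"))

#' @rdname accessors
#' @export
setGeneric("subjectStats", function(x) standardGeneric("subjectStats"))

#' @rdname accessors
#' @export
setGeneric("overallStats", function(x) standardGeneric("overallStats"))

#' @rdname accessors
#' @export
setGeneric("confusionPercent", function(x) standardGeneric("confusionPercent"))

#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
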