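#' @import methods
#' @importFrom stats approx coef lm mad median quantile rnorm sd setNames var IQR runmed predict fitted
#' @importFrom utils read.csv write.csv head tail
NULL

#' @rdname ProtocolSpec-class
#' @export
setGeneric("breathingDuration", function(x) standardGeneric("breathingDuration"))

#' @rdname ProtocolSpec-class
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' @rdname MaskRecording-class
#' @export
setGeneric("resistanceMatrix", function(x) standardGeneric("resistanceMatrix"))

#' @rdname MaskRecording-class
#' @export
setGeneric("samplingTimes", function(x) standardGeneric("samplingTimes"))

#' @rdname MaskRecording-class
#' @export
setGeneric("sensorInfo", function(x) standardGeneric("sensorInfo"))

#' @rdname MaskRecording-class
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname MaskRecording-class
#' @export
setGeneric("ambientConditions", function(x) standardGeneric("ambientConditions"))

#' @rdname MaskRecording-class
#' @export
setGeneric("breathLog", function(x) standardGeneric("breathLog"))

#' Clip overflow readings
#'
#' Data-logger readings above the measurable resistance range (carried as
#' \code{Inf} overflow markers) and finite values above \code{limit} are set
#' to exactly \code{limit}; all other values are unchanged.
#'
#' @param x numeric vector of resistances (ohms) or a \code{MaskRecording}.
#' @param limit positive clipping level in ohms (default \code{1e8}).
#' @return An object of the same shape as \code{x} with all values finite and
#'   at most \code{limit}.
#' @export
setGeneric("clipOverflow", function(x, limit = 1e8) standardGeneric("clipOverflow"))
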