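#' @name mepcov-generics
#' @title Generics for TrialSet accessors and data reduction
#' @param x,trials a [TrialSet] object
#' @param ... passed to methods
NULL

#' @rdname mepcov-generics
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))

#' @rdname mepcov-generics
#' @export
setGeneric("epochStart", function(x, ...) standardGeneric("epochStart"))

#' @rdname mepcov-generics
#' @export
setGeneric("trialConditions", function(x, ...) standardGeneric("trialConditions"))

#' @rdname mepcov-generics
#' @export
setGeneric("participants", function(x, ...) standardGeneric("participants"))

#' @rdname mepcov-generics
#' @export
setGeneric("channelTraces", function(x, ...) standardGeneric("channelTraces"))

#' @rdname mepcov-generics
#' @export
setGeneric("extractFeatures", function(trials, ...) standardGeneric("extractFeatures"))
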