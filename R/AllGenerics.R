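# S4 generics for the package's accessors and core verbs.

#' @export
setGeneric("doses", function(x, ...) standardGeneric("doses"))

#' @export
setGeneric("nPanelists", function(x, ...) standardGeneric("nPanelists"))

#' @export
setGeneric("nCorrect", function(x, ...) standardGeneric("nCorrect"))

#' @export
setGeneric("pCorrect", function(x, ...) standardGeneric("pCorrect"))

#' @export
setGeneric("pDetect", function(x, ...) standardGeneric("pDetect"))

#' @export
setGeneric("odorThresholds", function(x, ...) standardGeneric("odorThresholds"))

#' @export
setGeneric("oav", function(x, ...) standardGeneric("oav"))

#' @export
setGeneric("oavBands", function(x, ...) standardGeneric("oavBands"))

#' @export
setGeneric("oavProfile", function(x, ...) standardGeneric("oavProfile"))

#' @export
setGeneric("compoundSummary", function(x, ...) standardGeneric("compoundSummary"))

#' @export
setGeneric("contributingCompounds",
           function(x, ...) standardGeneric("contributingCompounds"))

#' @export
setGeneric("interactionCall", function(x, ...) standardGeneric("interactionCall"))

#' @export
setGeneric("thresholdValue", function(x, ...) standardGeneric("thresholdValue"))
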