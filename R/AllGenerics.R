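#' @rdname triadMatrix
#' @export
setGeneric("triadMatrix", function(x, ...) standardGeneric("triadMatrix"))

#' @rdname slopeCI
#' @export
setGeneric("slopeCI", function(fit, tail = 0.0125) standardGeneric("slopeCI"))

#' @rdname compareSlopes
#' @export
setGeneric("compareSlopes", function(fit1, fit2, tail = 0.0125)
    standardGeneric("compareSlopes"))

#' @rdname computeIndices
#' @export
setGeneric("computeIndices", function(x, ...) standardGeneric("computeIndices"))

#' @rdname generateTriad
#' @export
setGeneric("generateTriad", function(truth) standardGeneric("generateTriad"))

#' Coerce package value classes to data.frame
#'
#' `IndexTable`, `UtrAnnotation`, `PairScoreTable` and
#' `StratifiedDistances` coerce to plain data frames for export and
#' plotting.
#'
#' @param x object to coerce.
#' @param row.names,optional,... passed for interface compatibility.
#' @return a data.frame.
#' @name as.data.frame-methods
NULL
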