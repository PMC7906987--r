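#' @rdname ExpressionDataset
#' @param object an object.
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))

#' @rdname ExpressionDataset
#' @export
setGeneric("compartment", function(object) standardGeneric("compartment"))

#' @rdname ExpressionDataset
#' @export
setGeneric("sampleGroup", function(object) standardGeneric("sampleGroup"))

#' @rdname ExpressionDataset
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' @rdname ExpressionDataset
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' @rdname CorrelatedPairs
#' @param object an object.
#' @export
setGeneric("pairTable", function(object) standardGeneric("pairTable"))

#' @rdname CorrelatedPairs
#' @export
setGeneric("cohortDetail", function(object) standardGeneric("cohortDetail"))
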