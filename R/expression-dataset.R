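#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of log2 expression, rows = genes (rownames
#'   required, unique), columns = samples.
#' @param group character vector, one of \code{"case"}/\code{"control"} per
#'   sample.
#' @param compartment \code{"tubule"} or \code{"glomerulus"} (one value for the
#'   whole dataset).
#' @param datasetId single string naming the study.
#' @param patientId optional per-sample patient identifier (required for
#'   cohorts entering cross-compartment correlation).
#'
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' ds <- ExpressionDataset(m, group = c("case", "case", "control", "control"),
#'                         compartment = "tubule", datasetId = "toy")
#' dim(ds)
#' @export
ExpressionDataset <- function(values, group, compartment, datasetId,
                              patientId = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("expression matrix must carry gene identifiers as rownames")
    if (is.null(colnames(values)))
        colnames(values) <- paste0("S", seq_len(ncol(values)))
    cd <- S4Vectors::DataFrame(group = as.character(group),
                               row.names = colnames(values))
    if (!is.null(patientId)) cd$patient_id <- as.character(patientId)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd)
    new("ExpressionDataset", se, datasetId = as.character(datasetId),
        compartment = as.character(compartment))
}

#' @rdname ExpressionDataset
#' @export
setMethod("datasetId", "ExpressionDataset", function(object) object@datasetId)

#' @rdname ExpressionDataset
#' @export
setMethod("compartment", "ExpressionDataset",
          function(object) object@compartment)

#' @rdname ExpressionDataset
#' @export
setMethod("sampleGroup", "ExpressionDataset", function(object)
    as.character(SummarizedExperiment::colData(object)$group))

#' @rdname ExpressionDataset
#' @export
setMethod("patientId", "ExpressionDataset", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if ("patient_id" %in% colnames(cd)) as.character(cd$patient_id) else NULL
})

#' @rdname ExpressionDataset
#' @export
setMethod("exprs", "ExpressionDataset", function(object)
    SummarizedExperiment::assay(object, "exprs"))

setMethod("show", "ExpressionDataset", function(object) {
    g <- sampleGroup(object)
    cat("ExpressionDataset '", object@datasetId, "' (",
        object@compartment, ")\n", sep = "")
    cat("  ", nrow(object), " genes x ", ncol(object), " samples (",
        sum(g == "case"), " case / ", sum(g == "control"), " control)\n",
        sep = "")
    if (!is.null(patientId(object)))
        cat("  patient ids present (", length(unique(patientId(object))),
            " patients)\n", sep = "")
})

#' Whether a dataset has enough replication for meta-analysis
#'
#' The meta-analysis stage requires at least two case and two control samples
#' to estimate within-group variances; smaller datasets are skipped with a
#' message.
#' @param object an \linkS4class{ExpressionDataset}.
#' @return logical scalar.
#' @export
usableForMeta <- function(object) {
    g <- sampleGroup(object)
    sum(g == "case") >= 2L && sum(g == "control") >= 2L
}

#' Construct a StudyCollection
#'
#' @param datasets list of \linkS4class{ExpressionDataset}.
#' @param pairedCohorts data.frame with columns \code{cohort_id},
#'   \code{tubule_id}, \code{glomerulus_id}; may be empty when no paired
#'   cohorts exist.
#' @return A \linkS4class{StudyCollection}.
#' @export
StudyCollection <- function(datasets, pairedCohorts = NULL) {
    if (is.null(pairedCohorts))
        pairedCohorts <- data.frame(cohort_id = character(),
                                    tubule_id = character(),
                                    glomerulus_id = character())
    names(datasets) <- vapply(datasets, datasetId, character(1))
    new("StudyCollection", datasets = datasets,
        pairedCohorts = as.data.frame(pairedCohorts))
}

setMethod("show", "StudyCollection", function(object) {
    comp <- vapply(object@datasets, compartment, character(1))
    cat("StudyCollection:", length(object@datasets), "datasets (",
        sum(comp == "tubule"), "tubule /", sum(comp == "glomerulus"),
        "glomerulus ),", nrow(object@pairedCohorts), "paired cohorts\n")
})

#' Datasets of one compartment
#' @param collection a \linkS4class{StudyCollection}.
#' @param compartment \code{"tubule"} or \code{"glomerulus"}.
#' @return list of \linkS4class{ExpressionDataset}.
#' @export
compartmentDatasets <- function(collection, compartment) {
    keep <- vapply(collection@datasets, function(d)
        d@compartment == compartment, logical(1))
    collection@datasets[keep]
}
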