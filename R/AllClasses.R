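#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ExpressionDataset: one study's log2 expression matrix with sample annotation
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding a single
#' cohort: a genes x samples matrix of log2 expression, a case/control group
#' label per sample, the kidney compartment the samples were dissected from
#' (tubule or glomerulus), and, for paired cohorts, a patient identifier per
#' sample so the two compartments can be aligned patient-by-patient.
#'
#' Validity requires finite values, unique gene identifiers, and per-sample
#' group labels in \code{{"case","control"}}. Datasets with fewer than two
#' case or two control samples are valid containers but are rejected by the
#' meta-analysis stage.
#'
#' @slot datasetId single character identifier, unique within a collection.
#' @slot compartment \code{"tubule"} or \code{"glomerulus"}.
#' @export
setClass("ExpressionDataset",
    contains = "SummarizedExperiment",
    representation(datasetId = "character", compartment = "character"))

setValidity("ExpressionDataset", function(object) {
    msg <- NULL
    if (length(object@datasetId) != 1L || is.na(object@datasetId) ||
        !nzchar(object@datasetId))
        msg <- c(msg, "datasetId must be a single non-empty string")
    if (length(object@compartment) != 1L ||
        !object@compartment %in% c("tubule", "glomerulus"))
        msg <- c(msg, "compartment must be 'tubule' or 'glomerulus'")
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        x <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(x)) msg <- c(msg, "expression values must be numeric")
        else if (any(!is.finite(x)))
            msg <- c(msg, "expression values must all be finite")
    }
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "gene identifiers must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'group' column")
    else if (!all(cd$group %in% c("case", "control")))
        msg <- c(msg, "group labels must be 'case' or 'control'")
    if (is.null(msg)) TRUE else msg
})

#' StudyCollection: the full set of cohorts entering the pipeline
#'
#' Holds the per-study \linkS4class{ExpressionDataset} objects plus the
#' pairing table naming which (tubule, glomerulus) dataset pairs profile the
#' same patients and therefore support cross-compartment correlation.
#'
#' @slot datasets named list of \linkS4class{ExpressionDataset}.
#' @slot pairedCohorts data.frame with columns \code{cohort_id},
#'   \code{tubule_id}, \code{glomerulus_id}; each row names one paired cohort.
#' @export
setClass("StudyCollection",
    representation(datasets = "list", pairedCohorts = "data.frame"))

setValidity("StudyCollection", function(object) {
    msg <- NULL
    ok <- vapply(object@datasets, is, logical(1), class2 = "ExpressionDataset")
    if (!all(ok)) msg <- c(msg, "all datasets must be ExpressionDataset objects")
    ids <- vapply(object@datasets, function(d) d@datasetId, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "dataset ids must be unique")
    pc <- object@pairedCohorts
    need <- c("cohort_id", "tubule_id", "glomerulus_id")
    if (nrow(pc) > 0) {
        if (!all(need %in% colnames(pc)))
            msg <- c(msg, "pairedCohorts needs cohort_id/tubule_id/glomerulus_id")
        else {
            known <- all(c(pc$tubule_id, pc$glomerulus_id) %in% ids)
            if (!known) msg <- c(msg, "pairedCohorts reference unknown dataset ids")
            else for (i in seq_len(nrow(pc))) {
                tub <- object@datasets[[match(pc$tubule_id[i], ids)]]
                glo <- object@datasets[[match(pc$glomerulus_id[i], ids)]]
                pt <- intersect(patientId(tub), patientId(glo))
                if (length(pt) < 3)
                    msg <- c(msg, sprintf(
                        "paired cohort %s shares fewer than 3 patients",
                        pc$cohort_id[i]))
            }
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' AnalysisConfig: all thresholds and switches of the pipeline
#'
#' @slot fdr_max BH-adjusted q cutoff on the pooled effect size (default 0.05).
#' @slot sam_q_max per-dataset SAM q cutoff (default 0.10).
#' @slot repl_p_max cutoff on the cross-dataset SAM combination p (default 0.05).
#' @slot r_min minimum absolute correlation for a crosstalk pair (default 0.7).
#' @slot corr_p_max correlation p cutoff (default 0.001).
#' @slot fold_change_min linear fold-change cutoff for enrichment export
#'   (default 1.5).
#' @slot n_permutations SAM label permutations (default 1000, minimum 100).
#' @slot seed root seed; every stochastic stage derives its own stream from it.
#' @slot corr_consensus which correlation methods must pass the cutoffs:
#'   \code{"pearson_only"} (default), \code{"all_three"}, or \code{"any_one"}.
#' @slot sam_combine cross-dataset SAM combination: \code{"fisher"} (default,
#'   Fisher's combined probability test) or \code{"binomial"} (exact binomial
#'   replication tail).
#' @slot min_datasets_present minimum datasets a gene must appear in to be
#'   pooled (default 2).
#' @export
setClass("AnalysisConfig",
    representation(
        fdr_max = "numeric", sam_q_max = "numeric", repl_p_max = "numeric",
        r_min = "numeric", corr_p_max = "numeric", fold_change_min = "numeric",
        n_permutations = "integer", seed = "integer",
        corr_consensus = "character", sam_combine = "character",
        min_datasets_present = "integer"))

setValidity("AnalysisConfig", function(object) {
    msg <- NULL
    frac <- function(x, nm, lo = 0, hi = 1) {
        if (length(x) != 1L || !is.finite(x) || x < lo || x > hi)
            sprintf("%s must be a single value in [%g, %g]", nm, lo, hi)
        else NULL
    }
    msg <- c(msg,
        frac(object@fdr_max, "fdr_max"), frac(object@sam_q_max, "sam_q_max"),
        frac(object@repl_p_max, "repl_p_max"),
        frac(object@corr_p_max, "corr_p_max"),
        frac(object@r_min, "r_min", 0, 1))
    if (object@fold_change_min < 1)
        msg <- c(msg, "fold_change_min must be >= 1 (a linear ratio)")
    if (object@n_permutations < 100L)
        msg <- c(msg, "n_permutations must be >= 100")
    if (!object@corr_consensus %in% c("all_three", "any_one", "pearson_only"))
        msg <- c(msg, "corr_consensus must be all_three, any_one or pearson_only")
    if (!object@sam_combine %in% c("fisher", "binomial"))
        msg <- c(msg, "sam_combine must be 'fisher' or 'binomial'")
    if (object@min_datasets_present < 1L)
        msg <- c(msg, "min_datasets_present must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' GeneratorConfig: study conditions for the synthetic-data generator
#'
#' Defaults are the simulation conditions used throughout the package's
#' validation: four cohorts of 15 case vs 15 control samples with 50 planted
#' DEGs at Hedges-scale effect 1.0 among 1000 genes, and four paired
#' two-compartment cohorts of 40 patients with 20 planted cross-compartment
#' pairs at latent correlation 0.85.
#'
#' @export
setClass("GeneratorConfig",
    representation(
        n_genes = "integer", n_datasets = "integer",
        n_case = "integer", n_control = "integer",
        n_planted_degs = "integer", effect_size_true = "numeric",
        n_paired_cohorts = "integer", n_patients = "integer",
        n_planted_pairs = "integer", rho_true = "numeric",
        batch_shift_sd = "numeric", noise_sd = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
    msg <- NULL
    if (object@n_planted_degs > object@n_genes)
        msg <- c(msg, "n_planted_degs cannot exceed n_genes")
    if (2L * object@n_planted_pairs > object@n_genes)
        msg <- c(msg, "need n_genes >= 2 * n_planted_pairs")
    if (abs(object@rho_true) >= 1)
        msg <- c(msg, "|rho_true| must be < 1")
    if (object@noise_sd <= 0) msg <- c(msg, "noise_sd must be > 0")
    if (object@batch_shift_sd < 0) msg <- c(msg, "batch_shift_sd must be >= 0")
    if (object@n_patients < 3) msg <- c(msg, "n_patients must be >= 3")
    if (is.null(msg)) TRUE else msg
})

#' SyntheticTruth: planted signals of a synthetic run
#'
#' @slot degTruth data.frame (gene, compartment, effect_size) of planted DEGs.
#' @slot pairTruth data.frame (tubule_gene, glom_gene, rho_true) of planted
#'   cross-compartment pairs.
#' @export
setClass("SyntheticTruth",
    representation(degTruth = "data.frame", pairTruth = "data.frame"))

#' CorrelatedPairs: consensus cross-compartment pairs with per-cohort detail
#'
#' @slot pairs one row per consensus pair: tubule_gene, glom_gene,
#'   consensus_sign ("pos"/"neg"), median_r (median Pearson r over cohorts),
#'   n_cohorts.
#' @slot perCohort long table: one row per pair per cohort carrying the full
#'   correlation triple (pearson/spearman/kendall coefficient + p, n_patients).
#' @export
setClass("CorrelatedPairs",
    representation(pairs = "data.frame", perCohort = "data.frame"))

#' PairNetwork: the signed bipartite tubule-glomerulus gene network
#'
#' @slot nodes data.frame (gene, side) where side is tubule, glomerulus, or
#'   both (gene appears on both sides across pairs).
#' @slot edges data.frame (tubule_gene, glom_gene, sign, median_r).
#' @export
setClass("PairNetwork",
    representation(nodes = "data.frame", edges = "data.frame"))
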