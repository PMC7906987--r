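#' Run the full cross-compartment analysis pipeline
#'
#' Orchestrates preprocess -> per-compartment dual-method meta-analysis ->
#' tubule/glomerulus DEG comparison -> paired-cohort correlation screen ->
#' secreted-protein annotation -> result writers. All stochastic stages
#' draw from streams derived from \code{config@seed}, and all writers are
#' deterministic, so re-running with identical inputs and seed reproduces
#' byte-identical outputs.
#'
#' Outputs in \code{outDir}: per-compartment DEG tables
#' (\code{degs_<compartment>.tsv}) and enrichment gene lists, Venn gene
#' lists (\code{venn_*.txt}), the consensus pair table
#' (\code{pairs.tsv}), SIF network (\code{network.sif} +
#' \code{network.sif.nodes.tsv}), the annotated pair table
#' (\code{pairs_annotated.tsv}, when a secretome is given), and a
#' machine-readable \code{run_log.json} recording config, seed, dataset
#' ids, and per-stage counts. Any stage error aborts the run, removes
#' \code{outDir}'s partial outputs, and names the failing stage.
#'
#' @param collection a \linkS4class{StudyCollection}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param secretomePath optional path to a secreted-protein gene list.
#' @param outDir output directory (created).
#' @param preprocess quantile-normalize each dataset first (default TRUE;
#'   set FALSE when matrices are already normalized).
#' @return invisible list with the in-memory stage results (\code{tubule},
#'   \code{glomerulus}, \code{venn}, \code{pairs}, \code{network},
#'   \code{secretome}, \code{log}).
#' @export
runPipeline <- function(collection, config = analysisConfig(),
                        secretomePath = NULL, outDir, preprocess = TRUE) {
    validObject(config)
    validObject(collection)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wrote <- character(0)
    stage <- "setup"
    result <- try({
        log <- list(config = .configAsList(config),
                    seed = config@seed,
                    dataset_ids = names(collection@datasets),
                    counts = list())

        stage <- "preprocess"
        if (preprocess)
            collection@datasets <- lapply(collection@datasets,
                                          preprocessDataset)

        stage <- "meta_analysis"
        res <- list()
        for (comp in c("tubule", "glomerulus")) {
            ds <- compartmentDatasets(collection, comp)
            ds <- ds[vapply(ds, usableForMeta, logical(1))]
            if (!length(ds)) next
            res[[comp]] <- metaAnalyze(ds, config)
            f <- file.path(outDir, paste0("degs_", comp, ".tsv"))
            writeDegTable(res[[comp]]$calls, f)
            wrote <- c(wrote, f)
            wrote <- c(wrote, exportEnrichmentGenelist(
                res[[comp]]$calls, config, outDir,
                prefix = paste0("enrich_", comp)))
            log$counts[[paste0("degs_", comp)]] <-
                sum(res[[comp]]$calls$final_call)
        }

        stage <- "venn"
        venn <- NULL
        if (all(c("tubule", "glomerulus") %in% names(res))) {
            degT <- res$tubule$calls$gene[res$tubule$calls$final_call]
            degG <- res$glomerulus$calls$gene[
                res$glomerulus$calls$final_call]
            venn <- vennPartition(degT, degG,
                                  labels = c("tubule", "glomerulus"))
            for (nm in c("unique_a", "unique_b", "shared")) {
                f <- file.path(outDir, paste0("venn_", nm, ".txt"))
                writeLines(sort(venn[[nm]]), f)
                wrote <- c(wrote, f)
            }
            log$counts$venn <- as.list(venn$counts)
        }

        stage <- "crosstalk"
        pairs <- NULL; network <- NULL
        pc <- collection@pairedCohorts
        if (nrow(pc) > 0 && !is.null(venn)) {
            perCohort <- list()
            for (i in seq_len(nrow(pc))) {
                tub <- collection@datasets[[pc$tubule_id[i]]]
                glo <- collection@datasets[[pc$glomerulus_id[i]]]
                perCohort[[pc$cohort_id[i]]] <-
                    findPairsOneCohort(tub, glo, degT, degG, config)
            }
            pairs <- intersectPairs(perCohort)
            log$counts$consensus_pairs <- nrow(pairTable(pairs))
            # expected false pairs implied by the uncorrected p cutoff
            log$expected_null_pairs_per_cohort <-
                length(degT) * length(degG) * config@corr_p_max
            if (nrow(pairTable(pairs)) > 0) {
                f <- file.path(outDir, "pairs.tsv")
                writePairTable(pairs, f)
                sif <- file.path(outDir, "network.sif")
                wrote <- c(wrote, f, writeSifNetwork(pairs, sif))
                network <- buildNetwork(pairs)
            }
        }

        stage <- "secretome"
        annotated <- NULL
        if (!is.null(secretomePath) && !is.null(pairs) &&
            nrow(pairTable(pairs)) > 0) {
            sec <- loadSecretome(secretomePath)
            annotated <- annotatePairs(pairs, sec)
            f <- file.path(outDir, "pairs_annotated.tsv")
            utils::write.table(annotated$pairs, f, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            wrote <- c(wrote, f)
            log$counts$secreted_tubule <- unname(annotated$counts["tubule"])
            log$counts$secreted_glomerulus <-
                unname(annotated$counts["glomerulus"])
            log$secretome <- list(size = sec$size, md5 = sec$md5)
        }

        stage <- "log"
        logPath <- file.path(outDir, "run_log.json")
        jsonlite::write_json(log, logPath, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        wrote <- c(wrote, logPath)
        list(tubule = res$tubule, glomerulus = res$glomerulus, venn = venn,
             pairs = pairs, network = network, secretome = annotated,
             log = log)
    }, silent = TRUE)
    if (inherits(result, "try-error")) {
        unlink(wrote)  # no partial outputs left behind
        stop("pipeline failed at stage '", stage, "': ",
             attr(result, "condition")$message)
    }
    invisible(result)
}

.configAsList <- function(config) {
    out <- lapply(.configFields(), function(nm) slot(config, nm))
    names(out) <- .configFields()
    out
}
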