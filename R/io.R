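#' Read an expression matrix with its sample metadata
#'
#' The matrix file is tab-separated with a header row of sample ids and the
#' first column holding gene (or probe) ids; the metadata file is
#' tab-separated with columns \code{sample_id}, \code{group}
#' (case/control), \code{compartment} (tubule/glomerulus), and optionally
#' \code{patient_id}. Row and column order are preserved from the file.
#'
#' @param path matrix file.
#' @param metadataPath metadata file; every matrix column must be present.
#' @param probeMap optional named vector probe -> gene (see
#'   \code{\link{readProbeGeneMap}}); when supplied, probe rows are
#'   collapsed with \code{\link{collapseProbes}}. Duplicate row ids without
#'   a probe map are an error.
#' @param collapseRule passed to \code{\link{collapseProbes}}.
#' @param datasetId dataset identifier; defaults to the matrix file name.
#' @return an \linkS4class{ExpressionDataset}.
#' @export
readExpressionMatrix <- function(path, metadataPath, probeMap = NULL,
                                 collapseRule = "max_mean_probe",
                                 datasetId = NULL) {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    ids <- tab[[1]]
    samples <- colnames(tab)[-1]
    x <- matrix(NA_real_, nrow(tab), length(samples),
                dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
        v <- suppressWarnings(as.numeric(tab[[j + 1]]))
        bad <- which(is.na(v) & !is.na(tab[[j + 1]]) &
                     toupper(trimws(tab[[j + 1]])) != "NA")
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                         tab[[j + 1]][bad[1]], bad[1], samples[j]))
        x[, j] <- v
    }
    if (anyDuplicated(ids)) {
        if (is.null(probeMap)) {
            dup <- unique(ids[duplicated(ids)])
            stop("duplicate gene id(s) without a probe map: ",
                 paste(utils::head(dup, 5), collapse = ", "))
        }
        rownames(x) <- make.unique(ids)
        names(probeMap) <- names(probeMap)
        # collapseProbes keys on original probe ids; remap uniquified names
        probeMap <- probeMap[ids]
        names(probeMap) <- make.unique(ids)
        probeMap <- probeMap[!is.na(probeMap)]
    } else rownames(x) <- ids
    if (!is.null(probeMap)) x <- collapseProbes(x, probeMap, collapseRule)

    md <- utils::read.delim(metadataPath, header = TRUE,
                            colClasses = "character")
    if (!all(c("sample_id", "group", "compartment") %in% colnames(md)))
        stop("metadata needs columns sample_id, group, compartment")
    missing <- setdiff(samples, md$sample_id)
    if (length(missing))
        stop("sample(s) missing from metadata: ",
             paste(missing, collapse = ", "))
    md <- md[match(samples, md$sample_id), , drop = FALSE]
    comp <- unique(md$compartment)
    if (length(comp) != 1)
        stop("a dataset must come from a single compartment, found: ",
             paste(comp, collapse = ", "))
    ExpressionDataset(
        x, group = md$group, compartment = comp,
        datasetId = datasetId %||% sub("\\.[^.]*$", "", basename(path)),
        patientId = if ("patient_id" %in% colnames(md)) md$patient_id
                    else NULL)
}

#' Write / read the DEG result table
#'
#' Tab-separated, sorted by q_fdr ascending, with the columns gene, f_meta,
#' se, z, p, q_fdr, mean_log2fc, sam_k_significant, repl_p, final_call.
#' Values round-trip losslessly (15 significant digits) through
#' \code{readDegTable}.
#'
#' @param calls a \code{\link{callDegs}} table.
#' @param path output file.
#' @return \code{writeDegTable}: invisible \code{path};
#'   \code{readDegTable}: the table.
#' @export
writeDegTable <- function(calls, path) {
    if (is.null(calls) || !nrow(calls))
        stop("refusing to write an empty DEG table")
    cols <- c("gene", "f_meta", "se", "z", "p", "q_fdr", "mean_log2fc",
              "sam_k_significant", "repl_p", "final_call")
    tab <- calls[order(calls$q_fdr), cols, drop = FALSE]
    num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "gene"
    for (j in which(num)) tab[[j]] <- formatC(tab[[j]], digits = 15,
                                              format = "g")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeDegTable
#' @export
readDegTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE)
    tab$gene <- as.character(tab$gene)
    tab$final_call <- as.logical(tab$final_call)
    tab
}

#' Write the pair network in SIF format (plus node attributes)
#'
#' One line per pair, \code{<tubule_gene> TAB <pos|neg> TAB <glom_gene>},
#' the relation being the consensus correlation sign — the standard simple
#' interaction format consumed by network-visualization tools. A side file
#' labels every gene tubule, glomerulus, or both (genes appearing on both
#' sides across pairs).
#'
#' @param pairs a \linkS4class{CorrelatedPairs} object or its pair table.
#' @param path SIF output file.
#' @param nodeAttrPath node-attribute output file (default: \code{path}
#'   with suffix \code{.nodes.tsv}).
#' @return invisible character vector of the files written.
#' @export
writeSifNetwork <- function(pairs, path,
                            nodeAttrPath = paste0(path, ".nodes.tsv")) {
    tab <- if (is(pairs, "CorrelatedPairs")) pairTable(pairs) else pairs
    if (!nrow(tab)) stop("refusing to write an empty network")
    net <- buildNetwork(tab)
    writeLines(paste(net@edges$tubule_gene, net@edges$sign,
                     net@edges$glom_gene, sep = "\t"), path)
    utils::write.table(net@nodes, nodeAttrPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(path, nodeAttrPath))
}

#' Write the consensus pair table
#'
#' Long-format tab-separated table: one row per pair per cohort with the
#' full correlation triple, preceded by the consensus columns.
#'
#' @param pairs a \linkS4class{CorrelatedPairs}.
#' @param path output file.
#' @return invisible \code{path}.
#' @export
writePairTable <- function(pairs, path) {
    detail <- cohortDetail(pairs)
    cons <- pairTable(pairs)
    if (!nrow(cons)) stop("refusing to write an empty pair table")
    merged <- merge(cons, detail, by = c("tubule_gene", "glom_gene"),
                    sort = TRUE)
    merged <- merged[order(merged$tubule_gene, merged$glom_gene,
                           merged$cohort_id), , drop = FALSE]
    utils::write.table(merged, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write an expression dataset as matrix + metadata files
#'
#' The inverse of \code{\link{readExpressionMatrix}}; used by the simulate
#' entry point so synthetic cohorts land on disk in the same format the
#' pipeline reads.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param path matrix file.
#' @param metadataPath metadata file.
#' @return invisible character vector of the files written.
#' @export
writeExpressionMatrix <- function(dataset, path,
                                  metadataPath = sub("\\.tsv$", "",
                                                     path) |>
                                      paste0(".meta.tsv")) {
    x <- exprs(dataset)
    tab <- data.frame(gene = rownames(x), x, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    md <- data.frame(sample_id = colnames(x),
                     group = sampleGroup(dataset),
                     compartment = compartment(dataset))
    pid <- patientId(dataset)
    if (!is.null(pid)) md$patient_id <- pid
    utils::write.table(md, metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(path, metadataPath))
}
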