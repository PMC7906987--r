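#' Load a secreted-protein gene list
#'
#' One gene id per line; \code{#} comment lines and blank lines are skipped;
#' ids are trimmed and uppercased, duplicates collapsed. The file's md5 hash
#' is recorded for provenance since secretome releases drift over time.
#'
#' @param path file path.
#' @return list of class \code{"SecretomeList"}: \code{genes} (character
#'   set), \code{size}, \code{source} (path), \code{md5},
#'   \code{n_duplicates}, \code{n_blank}.
#' @export
loadSecretome <- function(path) {
    raw <- readLines(path, warn = FALSE)
    nBlank <- sum(!nzchar(trimws(raw)))
    keep <- trimws(raw)
    keep <- keep[nzchar(keep) & !startsWith(keep, "#")]
    keep <- toupper(keep)
    if (!length(keep))
        stop("secretome file contains no gene ids: ", path)
    genes <- unique(keep)
    structure(list(genes = genes, size = length(genes), source = path,
                   md5 = unname(tools::md5sum(path)),
                   n_duplicates = length(keep) - length(genes),
                   n_blank = nBlank),
              class = "SecretomeList")
}

#' @export
print.SecretomeList <- function(x, ...) {
    cat("SecretomeList:", x$size, "genes from", x$source, "\n")
    invisible(x)
}

#' Annotate consensus pairs with secreted-protein status
#'
#' Flags, for each cross-compartment pair, whether the tubule-side and the
#' glomerulus-side gene encode a predicted secreted protein. Pairs whose
#' tubule gene is secreted are ranked first: a secreted tubular gene
#' correlated with a glomerular gene is the ligand-like candidate for
#' tubule-to-glomerulus signaling. Annotation never adds or removes pairs.
#'
#' @param pairs a \linkS4class{CorrelatedPairs} object or its pair table.
#' @param secretome a \code{"SecretomeList"} (see
#'   \code{\link{loadSecretome}}).
#' @return list with \code{pairs} (annotated, re-ranked table gaining
#'   logical columns tubule_secreted / glom_secreted) and \code{counts}
#'   (named vector: number of distinct secreted genes on each side — genes,
#'   not pairs, so a secreted gene in three pairs counts once).
#' @export
annotatePairs <- function(pairs, secretome) {
    tab <- if (is(pairs, "CorrelatedPairs")) pairTable(pairs) else pairs
    sec <- secretome$genes
    tab$tubule_secreted <- toupper(tab$tubule_gene) %in% sec
    tab$glom_secreted <- toupper(tab$glom_gene) %in% sec
    ord <- order(!tab$tubule_secreted, !tab$glom_secreted,
                 tab$tubule_gene, tab$glom_gene)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    counts <- c(tubule = length(unique(tab$tubule_gene[tab$tubule_secreted])),
                glomerulus = length(unique(tab$glom_gene[tab$glom_secreted])))
    list(pairs = tab, counts = counts)
}
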