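#' Dual-method differential-expression meta-analysis for one compartment
#'
#' Runs both evidence streams over a list of same-compartment datasets:
#' \enumerate{
#'   \item Effect sizes: per-dataset Hedges' g per gene, pooled with the
#'     fixed-effect inverse-variance model, two-sided normal p, BH FDR.
#'   \item SAM: per-dataset permutation q-values (and pooled permutation
#'     p-values), combined across datasets by Fisher's method or the exact
#'     binomial replication tail, per \code{config@sam_combine}.
#' }
#' Genes must appear (non-degenerate) in at least
#' \code{config@min_datasets_present} datasets to be pooled; datasets with
#' fewer than two case or two control samples are skipped with a message.
#'
#' @param datasets list of \linkS4class{ExpressionDataset}, one compartment.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list with elements \code{meta} (per-gene pooled results:
#'   gene, f_meta, se, z, p, q_fdr, mean_log2fc, n_datasets_used, Q, I2),
#'   \code{sam} (named list of per-dataset SAM tables), \code{repl}
#'   (cross-dataset combination), \code{calls} (the final DEG calls, see
#'   \code{\link{callDegs}}), and \code{skipped} (dataset ids not usable).
#' @export
metaAnalyze <- function(datasets, config = analysisConfig()) {
    validObject(config)
    usable <- vapply(datasets, usableForMeta, logical(1))
    skipped <- vapply(datasets[!usable], datasetId, character(1))
    if (length(skipped))
        message("skipped dataset(s) without 2+2 replication: ",
                paste(skipped, collapse = ", "))
    datasets <- datasets[usable]
    if (!length(datasets)) stop("no usable datasets for meta-analysis")

    es <- lapply(datasets, function(d)
        .hedgesGMatrix(exprs(d), sampleGroup(d)))
    names(es) <- vapply(datasets, datasetId, character(1))

    genes <- sort(unique(unlist(lapply(es, `[[`, "gene"))))
    G <- matrix(NA_real_, length(genes), length(es),
                dimnames = list(genes, names(es)))
    V <- G; FC <- G
    for (j in seq_along(es)) {
        e <- es[[j]]
        i <- match(e$gene, genes)
        ok <- !e$degenerate
        G[i[ok], j] <- e$g[ok]
        V[i[ok], j] <- e$var_g[ok]
        FC[i, j] <- e$log2fc
    }
    W <- 1 / V
    nUsed <- rowSums(is.finite(W))
    sumW <- rowSums(W, na.rm = TRUE)
    f <- rowSums(W * G, na.rm = TRUE) / sumW
    se <- sqrt(1 / sumW)
    z <- f / se
    Q <- rowSums(W * (G - f)^2, na.rm = TRUE)
    I2 <- ifelse(nUsed > 1 & Q > 0, pmax(0, (Q - (nUsed - 1)) / Q), 0)
    meta <- data.frame(
        gene = genes, f_meta = f, se = se, z = z,
        p = 2 * stats::pnorm(-abs(z)),
        mean_log2fc = rowMeans(FC, na.rm = TRUE),
        n_datasets_used = as.integer(nUsed), Q = Q, I2 = I2,
        row.names = NULL)
    keep <- meta$n_datasets_used >= config@min_datasets_present
    dropped <- meta$gene[!keep]
    if (length(dropped))
        message(length(dropped), " gene(s) present in fewer than ",
                config@min_datasets_present, " datasets were not pooled")
    meta <- meta[keep, , drop = FALSE]
    meta$q_fdr <- bhFdr(meta$p)

    sam <- lapply(datasets, function(d)
        samQValues(exprs(d), sampleGroup(d),
                   nPermutations = config@n_permutations,
                   seed = config@seed, stage = paste0("sam:", datasetId(d))))
    names(sam) <- names(es)
    repl <- .combineSamAcrossDatasets(sam, config@sam_q_max,
                                      config@sam_combine)
    calls <- callDegs(meta, repl, config)
    list(meta = meta, sam = sam, repl = repl, calls = calls,
         skipped = skipped)
}

#' Final DEG calls: intersection of the two meta-analysis methods
#'
#' A gene is a final DEG only when both evidence streams agree: the pooled
#' effect size passes the FDR cutoff AND the cross-dataset SAM combination
#' passes its p cutoff. Genes missing from either stream are never final
#' DEGs and carry a reason.
#'
#' @param meta per-gene pooled effect table (from \code{\link{metaAnalyze}}).
#' @param repl cross-dataset SAM combination table.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame: gene, f_meta, se, z, p, q_fdr, mean_log2fc,
#'   sam_k_significant, repl_p, passes_effect, passes_sam, final_call,
#'   direction (+1/-1), reason ("" when testable by both methods).
#' @export
callDegs <- function(meta, repl, config = analysisConfig()) {
    genes <- sort(union(meta$gene, repl$gene))
    im <- match(genes, meta$gene); ir <- match(genes, repl$gene)
    out <- data.frame(
        gene = genes,
        f_meta = meta$f_meta[im], se = meta$se[im], z = meta$z[im],
        p = meta$p[im], q_fdr = meta$q_fdr[im],
        mean_log2fc = meta$mean_log2fc[im],
        sam_k_significant = repl$k_significant[ir],
        repl_p = repl$repl_p[ir], row.names = NULL)
    out$passes_effect <- !is.na(out$q_fdr) & out$q_fdr <= config@fdr_max
    out$passes_sam <- !is.na(out$repl_p) & out$repl_p <= config@repl_p_max
    out$final_call <- out$passes_effect & out$passes_sam
    out$direction <- sign(out$f_meta)
    out$reason <- ifelse(is.na(im), "missing_effect",
                  ifelse(is.na(ir) | is.na(out$repl_p), "missing_sam", ""))
    out
}

#' Export final DEGs passing the fold-change filter as gene lists
#'
#' Final DEGs with \eqn{|mean\_log2fc| \ge \log_2(fold\_change\_min)} are
#' written one gene per line, split by direction (up- and down-regulated),
#' for hand-off to external enrichment tools.
#'
#' @param calls the table from \code{\link{callDegs}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param outDir directory for the two list files.
#' @param prefix file-name prefix (e.g. the compartment).
#' @return invisible character vector of the files written.
#' @export
exportEnrichmentGenelist <- function(calls, config, outDir, prefix = "degs") {
    thr <- log2(config@fold_change_min)
    keep <- calls$final_call & !is.na(calls$mean_log2fc) &
            abs(calls$mean_log2fc) >= thr
    up <- sort(calls$gene[keep & calls$mean_log2fc > 0])
    down <- sort(calls$gene[keep & calls$mean_log2fc < 0])
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    fup <- file.path(outDir, paste0(prefix, "_up.txt"))
    fdn <- file.path(outDir, paste0(prefix, "_down.txt"))
    writeLines(up, fup); writeLines(down, fdn)
    invisible(c(fup, fdn))
}
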