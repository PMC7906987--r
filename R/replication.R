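#' Exact binomial replication test across datasets
#'
#' Given that a gene was called significant (per-dataset SAM q below the
#' cutoff) in \code{k} of \code{m} datasets, returns the one-sided binomial
#' tail \eqn{P(K \ge k \mid m, rate)}: the probability of at least that many
#' calls if calls were null at the per-dataset cutoff rate.
#'
#' @param k number of datasets calling the gene significant.
#' @param m number of datasets with a defined call (>= 2).
#' @param rate per-dataset null call rate (the SAM q cutoff, default 0.10).
#' @return p-value in (0, 1]; k = 0 gives exactly 1.
#' @examples
#' replicationTest(4, 4, 0.10)  # 1e-4
#' replicationTest(1, 4, 0.10)  # 1 - 0.9^4 = 0.3439
#' @export
replicationTest <- function(k, m, rate = 0.10) {
    if (m < 2) stop("replication needs >= 2 datasets with a defined call")
    if (k < 0 || k > m) stop("k must lie in [0, m]")
    if (k == 0) return(1)
    stats::pbinom(k - 1, m, rate, lower.tail = FALSE)
}

#' Fisher's combined probability test
#'
#' Combines independent per-dataset p-values for one gene via
#' \eqn{X = -2 \sum \ln p_i \sim \chi^2_{2m}} under the null.
#'
#' @param p vector of per-dataset p-values in (0, 1].
#' @return combined p-value.
#' @export
fisherCombinedP <- function(p) {
    p <- p[is.finite(p)]
    if (!length(p)) stop("no p-values to combine")
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# Cross-dataset combination of per-dataset SAM results for all genes.
# samList: named list (dataset id -> data.frame gene/d/q/p_perm).
# Returns data.frame: gene, k_significant, m_datasets, repl_p.
.combineSamAcrossDatasets <- function(samList, sam_q_max, sam_combine) {
    genes <- sort(unique(unlist(lapply(samList, `[[`, "gene"))))
    K <- matrix(NA, length(genes), length(samList),
                dimnames = list(genes, names(samList)))
    Pm <- K
    for (j in seq_along(samList)) {
        s <- samList[[j]]
        K[match(s$gene, genes), j] <- s$q < sam_q_max
        Pm[match(s$gene, genes), j] <- s$p_perm
    }
    m <- rowSums(!is.na(K))
    k <- rowSums(K, na.rm = TRUE)
    repl <- vapply(seq_along(genes), function(i) {
        if (m[i] < 2) return(NA_real_)
        if (sam_combine == "binomial")
            replicationTest(k[i], m[i], sam_q_max)
        else
            fisherCombinedP(Pm[i, !is.na(Pm[i, ])])
    }, numeric(1))
    data.frame(gene = genes, k_significant = as.integer(k),
               m_datasets = as.integer(m), repl_p = repl, row.names = NULL)
}
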