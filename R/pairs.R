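#' Cross-compartment correlated DEG pairs within one paired cohort
#'
#' Aligns the tubule and glomerulus datasets of one cohort by patient id,
#' then screens every (tubular DEG, glomerular DEG) pair for correlation
#' across patients. A pair is retained when \eqn{|coefficient| > r\_min} and
#' \eqn{p < corr\_p\_max} for the methods required by
#' \code{config@corr_consensus}:
#' \describe{
#'   \item{pearson_only (default)}{the cutoffs apply to Pearson's r;
#'     Spearman and Kendall are still computed and reported for every
#'     retained pair. Chosen as default because the three coefficients live
#'     on different scales (for Gaussian data Kendall's tau corresponding to
#'     Pearson r = 0.7 is only about 0.49), so one shared cutoff cannot be
#'     applied to all three coherently.}
#'   \item{all_three}{cutoffs must hold simultaneously for Pearson, Spearman
#'     and Kendall (most conservative).}
#'   \item{any_one}{cutoffs must hold for at least one method.}
#' }
#' The screen is vectorized: Pearson and Spearman are full cross-correlation
#' matrices; under \code{all_three} Kendall (the expensive statistic) is
#' evaluated only for pairs already passing the other two, which cannot
#' change the result of the conjunction.
#'
#' @param tub,glom \linkS4class{ExpressionDataset}s of one cohort, both with
#'   patient ids; >= 3 shared patients required.
#' @param tubDegs,glomDegs character vectors: the candidate (DEG) genes on
#'   each side. Genes absent from the matrices are reported and skipped.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame, one row per retained pair: tubule_gene, glom_gene,
#'   the full correlation triple, n_patients.
#' @export
findPairsOneCohort <- function(tub, glom, tubDegs, glomDegs,
                               config = analysisConfig()) {
    validObject(config)
    pt <- patientId(tub); pg <- patientId(glom)
    if (is.null(pt) || is.null(pg))
        stop("both datasets need patient ids for cross-compartment pairing")
    shared <- intersect(pt, pg)
    if (length(shared) < 3)
        stop("datasets share fewer than 3 patients")
    it <- match(shared, pt); ig <- match(shared, pg)

    missT <- setdiff(tubDegs, rownames(tub))
    missG <- setdiff(glomDegs, rownames(glom))
    if (length(missT) || length(missG))
        message(length(missT) + length(missG),
                " DEG(s) absent from the expression matrices were skipped")
    tubDegs <- intersect(tubDegs, rownames(tub))
    glomDegs <- intersect(glomDegs, rownames(glom))
    empty <- data.frame(tubule_gene = character(), glom_gene = character(),
                        r_pearson = numeric(), p_pearson = numeric(),
                        rho_spearman = numeric(), p_spearman = numeric(),
                        tau_kendall = numeric(), p_kendall = numeric(),
                        n_patients = integer())
    if (!length(tubDegs) || !length(glomDegs)) return(empty)

    Xt <- t(exprs(tub)[tubDegs, it, drop = FALSE])   # patients x genes
    Xg <- t(exprs(glom)[glomDegs, ig, drop = FALSE])
    n <- length(shared)
    consts <- function(M) apply(M, 2, function(v) stats::sd(v) == 0)
    ct <- consts(Xt); cg <- consts(Xg)

    passAt <- function(R) {
        P <- .corPValue(R, n, "pearson")
        ok <- abs(R) > config@r_min & P < config@corr_p_max
        ok[is.na(ok)] <- FALSE
        ok
    }
    Rp <- suppressWarnings(stats::cor(Xt, Xg))
    Rp[ct, ] <- NA; Rp[, cg] <- NA
    okP <- passAt(Rp)
    Rs <- suppressWarnings(stats::cor(Xt, Xg, method = "spearman"))
    Rs[ct, ] <- NA; Rs[, cg] <- NA
    okS <- abs(Rs) > config@r_min &
        .corPValue(Rs, n, "spearman") < config@corr_p_max
    okS[is.na(okS)] <- FALSE

    if (config@corr_consensus == "pearson_only") {
        keep <- okP
    } else if (config@corr_consensus == "all_three") {
        keep <- okP & okS   # kendall refined below on survivors only
    } else {
        Rk <- suppressWarnings(stats::cor(Xt, Xg, method = "kendall"))
        Rk[ct, ] <- NA; Rk[, cg] <- NA
        okK <- abs(Rk) > config@r_min &
            .corPValue(Rk, n, "kendall") < config@corr_p_max
        okK[is.na(okK)] <- FALSE
        keep <- okP | okS | okK
    }
    idx <- which(keep, arr.ind = TRUE)
    if (!nrow(idx)) return(empty)
    out <- do.call(rbind, lapply(seq_len(nrow(idx)), function(r) {
        i <- idx[r, 1]; j <- idx[r, 2]
        tri <- correlationTriple(Xt[, i], Xg[, j])
        cbind(data.frame(tubule_gene = tubDegs[i], glom_gene = glomDegs[j]),
              tri)
    }))
    if (config@corr_consensus == "all_three") {
        okK <- abs(out$tau_kendall) > config@r_min &
               out$p_kendall < config@corr_p_max
        out <- out[!is.na(okK) & okK, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' Consensus pairs present in every paired cohort
#'
#' Intersects the per-cohort pair sets: a consensus pair must be retained
#' (same tubule gene, same glomerulus gene) in ALL cohorts, with a
#' consistent correlation sign (Pearson) across cohorts; sign-conflicted
#' pairs are rejected.
#'
#' @param perCohort named list of per-cohort pair tables
#'   (\code{\link{findPairsOneCohort}} output).
#' @return a \linkS4class{CorrelatedPairs} object.
#' @export
intersectPairs <- function(perCohort) {
    if (!length(perCohort)) stop("need at least one cohort")
    if (is.null(names(perCohort)) || any(!nzchar(names(perCohort))))
        names(perCohort) <- paste0("cohort", seq_along(perCohort))
    keyed <- lapply(perCohort, function(tab)
        paste(tab$tubule_gene, tab$glom_gene, sep = "\r"))
    common <- Reduce(intersect, keyed)
    long <- do.call(rbind, lapply(names(perCohort), function(cid) {
        tab <- perCohort[[cid]]
        tab <- tab[keyed[[cid]] %in% common, , drop = FALSE]
        if (nrow(tab)) cbind(cohort_id = cid, tab) else NULL
    }))
    emptyPairs <- data.frame(tubule_gene = character(),
                             glom_gene = character(),
                             consensus_sign = character(),
                             median_r = numeric(), n_cohorts = integer())
    if (is.null(long) || !nrow(long))
        return(new("CorrelatedPairs", pairs = emptyPairs,
                   perCohort = data.frame()))
    key <- paste(long$tubule_gene, long$glom_gene, sep = "\r")
    pairs <- do.call(rbind, lapply(unique(key), function(k) {
        rows <- long[key == k, , drop = FALSE]
        sg <- sign(rows$r_pearson)
        if (length(unique(sg)) > 1) return(NULL)   # sign conflict: rejected
        data.frame(tubule_gene = rows$tubule_gene[1],
                   glom_gene = rows$glom_gene[1],
                   consensus_sign = if (sg[1] > 0) "pos" else "neg",
                   median_r = stats::median(rows$r_pearson),
                   n_cohorts = nrow(rows))
    }))
    if (is.null(pairs)) pairs <- emptyPairs
    keep <- paste(pairs$tubule_gene, pairs$glom_gene, sep = "\r")
    long <- long[key %in% keep, , drop = FALSE]
    rownames(pairs) <- rownames(long) <- NULL
    new("CorrelatedPairs", pairs = pairs, perCohort = long)
}

#' @rdname CorrelatedPairs
#' @export
setMethod("pairTable", "CorrelatedPairs", function(object) object@pairs)

#' @rdname CorrelatedPairs
#' @export
setMethod("cohortDetail", "CorrelatedPairs",
          function(object) object@perCohort)

setMethod("show", "CorrelatedPairs", function(object) {
    cat("CorrelatedPairs:", nrow(object@pairs), "consensus pair(s)")
    if (nrow(object@pairs))
        cat(" (", sum(object@pairs$consensus_sign == "pos"), "pos /",
            sum(object@pairs$consensus_sign == "neg"), "neg )")
    cat("\n")
})

#' Build the signed bipartite tubule-glomerulus network
#'
#' @param pairs a \linkS4class{CorrelatedPairs} object or its pair table.
#' @return a \linkS4class{PairNetwork}: nodes labelled tubule, glomerulus or
#'   both (gene appears on both sides across pairs); edges carry the
#'   consensus sign and the median Pearson r across cohorts.
#' @export
buildNetwork <- function(pairs) {
    tab <- if (is(pairs, "CorrelatedPairs")) pairTable(pairs) else pairs
    if (!nrow(tab)) stop("no pairs to build a network from")
    tgen <- unique(tab$tubule_gene); ggen <- unique(tab$glom_gene)
    genes <- union(tgen, ggen)
    side <- ifelse(genes %in% tgen & genes %in% ggen, "both",
                   ifelse(genes %in% tgen, "tubule", "glomerulus"))
    nodes <- data.frame(gene = genes, side = side)
    edges <- tab[, c("tubule_gene", "glom_gene", "consensus_sign",
                     "median_r")]
    names(edges)[3] <- "sign"
    new("PairNetwork", nodes = nodes, edges = edges)
}

setMethod("show", "PairNetwork", function(object) {
    cat("PairNetwork:", nrow(object@nodes), "nodes,",
        nrow(object@edges), "edges\n")
})

#' Node degrees of a pair network
#'
#' @param network a \linkS4class{PairNetwork}.
#' @return named integer vector, sorted decreasing — hub genes (one gene
#'   correlated with many partners on the other side) come first.
#' @export
networkDegree <- function(network) {
    sort(table(c(network@edges$tubule_gene, network@edges$glom_gene)),
         decreasing = TRUE)
}
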