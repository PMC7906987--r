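#' SAM relative-difference statistic
#'
#' Tusher's moderated statistic
#' \eqn{d_i = (\bar x_{case} - \bar x_{control}) / (s_i + s_0)} with
#' \eqn{s_i = \sqrt{(1/n_1 + 1/n_2)/(n_1+n_2-2) \cdot
#' (\sum dev_{case}^2 + \sum dev_{control}^2)}}. The fudge factor
#' \eqn{s_0} damps the statistics of low-variance genes.
#'
#' @param x genes x samples numeric matrix (rownames required).
#' @param group per-sample labels in \code{{"case","control"}}, >= 2 each.
#' @param s0 non-negative fudge factor.
#' @return named numeric vector of d, one per gene; genes with
#'   \eqn{s_i + s_0 = 0} are NA (flagged undefined). Attributes \code{"s"}
#'   and \code{"numerator"} carry the per-gene pieces (used for s0 tuning).
#' @examples
#' m <- rbind(g1 = c(4, 5, 6, 1, 2, 3))
#' samStatistic(m, rep(c("case", "control"), each = 3), s0 = 0)  # 3.674
#' @export
samStatistic <- function(x, group, s0) {
    x <- as.matrix(x)
    if (s0 < 0) stop("s0 must be >= 0")
    n1 <- sum(group == "case"); n2 <- sum(group == "control")
    if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
    case <- x[, group == "case", drop = FALSE]
    ctrl <- x[, group == "control", drop = FALSE]
    r <- rowMeans(case) - rowMeans(ctrl)
    ss <- rowSums((case - rowMeans(case))^2) +
          rowSums((ctrl - rowMeans(ctrl))^2)
    s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
    d <- ifelse(s + s0 > 0, r / (s + s0), NA_real_)
    names(d) <- rownames(x)
    structure(d, s = s, numerator = r)
}

#' Choose the SAM fudge factor s0
#'
#' Tusher-style selection: candidate values are the percentiles
#' \{0, 5, ..., 100\} of the per-gene standard errors s; for each candidate
#' the genes are windowed by s-quantile and the coefficient of variation of
#' the windowed median absolute deviations of d is computed; the candidate
#' minimizing that CV wins (ties broken toward the smallest candidate).
#' With fewer than 100 genes the criterion is unstable, so the 5th
#' percentile of s is used as a fallback; the choice and rule are recorded
#' in the result's attributes.
#'
#' @param s per-gene standard errors (denominators of d at s0 = 0).
#' @param numerator per-gene mean differences (numerators of d).
#' @return s0 (numeric scalar) with attributes \code{"rule"}
#'   (\code{"tusher"} or \code{"fallback_p5"}) and \code{"candidates"}.
#' @export
chooseS0 <- function(s, numerator) {
    stopifnot(length(s) == length(numerator))
    if (length(s) < 100L) {
        s0 <- unname(stats::quantile(s, 0.05, type = 7))
        return(structure(s0, rule = "fallback_p5", candidates = NULL))
    }
    cand <- unname(stats::quantile(s, seq(0, 1, by = 0.05), type = 7))
    nwin <- 100L
    win <- cut(rank(s, ties.method = "first"), breaks = nwin, labels = FALSE)
    cv <- vapply(cand, function(s0) {
        d <- numerator / (s + s0)
        d[!is.finite(d)] <- NA  # zero-variance genes at the s0 = 0 candidate
        mads <- tapply(d, win, stats::mad, na.rm = TRUE)
        mads <- mads[is.finite(mads)]
        m <- mean(mads)
        if (!is.finite(m) || m == 0) Inf else stats::sd(mads) / m
    }, numeric(1))
    # ties (to numerical precision) break toward the smallest candidate
    best <- which(cv <= min(cv) + 1e-12)[1]
    structure(cand[best], rule = "tusher", candidates = cand)
}

# Case-index assignments for the permutation null: all of them if few
# enough, else `b` sampled ones. The observed grouping (case set = 1..n1
# after the case-first reordering) and, for balanced designs, its mirror
# are excluded — they reproduce the observed statistic exactly and would
# put a floor under every q. Returns an n x B 0/1 indicator matrix.
.permutationIndicators <- function(n, n1, b) {
    total <- choose(n, n1)
    if (total < 10)
        stop("fewer than ", 10, " distinct label permutations exist (",
             total, "); exact enumeration was attempted but the design is ",
             "too small for a permutation null")
    isObserved <- function(set) all(set <= n1) ||
        (2 * n1 == n && all(set > n1))
    if (total <= b + 2) {
        idx <- utils::combn(n, n1)
        idx <- idx[, !apply(idx, 2, isObserved), drop = FALSE]
        B <- ncol(idx)
    } else {
        B <- b
        idx <- matrix(0L, n1, B)
        for (i in seq_len(B)) {
            repeat {
                s <- sort(sample.int(n, n1))
                if (!isObserved(s)) break
            }
            idx[, i] <- s
        }
    }
    P <- matrix(0, n, B)
    P[cbind(as.vector(idx), rep(seq_len(B), each = n1))] <- 1
    P
}

# d statistics for every permutation in indicator matrix P (n x B),
# computed with matrix products: returns genes x B matrix.
.samPermutedD <- function(x, P, s0) {
    n <- ncol(x); n1 <- sum(P[, 1]); n2 <- n - n1
    T1 <- rowSums(x); T2 <- rowSums(x^2)
    Sc <- x %*% P          # per-perm case sums
    Qc <- x^2 %*% P        # per-perm case sums of squares
    ssc <- Qc - Sc^2 / n1
    ssk <- (T2 - Qc) - (T1 - Sc)^2 / n2
    r <- Sc / n1 - (T1 - Sc) / n2
    s <- sqrt(pmax(0, (1 / n1 + 1 / n2) / (n - 2) * (ssc + ssk)))
    D <- r / (s + s0)
    D[!is.finite(D)] <- 0
    D
}

#' SAM permutation q-values (and pooled permutation p-values)
#'
#' Ranks genes by |d| and estimates, at each observed |d| threshold, the
#' false discovery rate as the mean (over label permutations) count of null
#' |d*| values at or above the threshold, divided by the number of genes
#' called at it, capped at 1. q-values are made monotone non-decreasing in
#' rank by taking the running minimum from the least significant gene
#' upward. The permutation null is pooled across genes (SAM's
#' exchangeability assumption), which also yields a fine-grained per-gene
#' permutation p-value used by the cross-dataset Fisher combination.
#'
#' The null excludes the observed grouping itself (and its mirror in
#' balanced designs), which reproduces the observed statistics exactly and
#' would otherwise put a floor under every q — with it excluded, a gene
#' whose |d| exceeds every genuinely permuted statistic attains q = 0.
#' When the number of remaining distinct assignments is at most
#' \code{nPermutations}, all of them are enumerated exactly; otherwise
#' \code{nPermutations} assignments are drawn from the stage's derived
#' random stream.
#'
#' @inheritParams samStatistic
#' @param nPermutations requested number of permutations.
#' @param seed root seed (the stage stream is derived from it and
#'   \code{stage}).
#' @param s0 fudge factor; \code{NULL} (default) selects it with
#'   \code{\link{chooseS0}}.
#' @param stage label mixed into the derived seed (callers use the dataset
#'   id so each dataset consumes an independent stream).
#' @return data.frame with columns \code{gene}, \code{d}, \code{q},
#'   \code{p_perm}; attributes \code{"s0"} (with its selection rule) and
#'   \code{"n_permutations_used"}.
#' @export
samQValues <- function(x, group, nPermutations = 1000L, seed = 1L,
                       s0 = NULL, stage = "sam") {
    x <- as.matrix(x)
    d <- samStatistic(x, group, s0 = 0)
    if (is.null(s0))
        s0 <- chooseS0(attr(d, "s"), attr(d, "numerator"))
    dobs <- as.numeric(samStatistic(x, group, s0 = s0))
    n <- ncol(x); n1 <- sum(group == "case")
    P <- .withStageSeed(seed, stage,
                        .permutationIndicators(n, n1, nPermutations))
    # permutations must compare case-labelled columns first
    xo <- x[, c(which(group == "case"), which(group == "control")),
            drop = FALSE]
    D <- .samPermutedD(xo, P, s0)
    B <- ncol(P)
    nullAbs <- sort(abs(as.vector(D)))
    N <- length(nullAbs)
    ord <- order(abs(dobs), decreasing = TRUE, na.last = TRUE)
    thr <- abs(dobs)[ord]
    cntGE <- N - findInterval(thr, nullAbs, left.open = TRUE)
    fdr <- pmin(1, (cntGE / B) / seq_along(thr))
    fdr[!is.finite(thr)] <- 1
    q <- rev(cummin(rev(fdr)))
    # tied |d| share one q (the smallest in the tie group)
    tiegrp <- match(thr, thr)
    q <- stats::ave(q, tiegrp, FUN = min)
    pperm <- (1 + cntGE) / (1 + N)
    pperm[!is.finite(thr)] <- 1
    out <- data.frame(gene = rownames(x), d = dobs, q = NA_real_,
                      p_perm = NA_real_, row.names = NULL)
    out$q[ord] <- q
    out$p_perm[ord] <- pperm
    structure(out, s0 = s0, n_permutations_used = B)
}
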