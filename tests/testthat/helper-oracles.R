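# Independent brute-force re-implementations used as oracles. These are
# written directly from the defining formulas, without reference to the
# package internals, and stay deliberately naive (loops, no vectorization).

oracleHedges <- function(case, control) {
    n1 <- length(case); n2 <- length(control)
    m1 <- sum(case) / n1; m2 <- sum(control) / n2
    ss <- sum((case - m1)^2) + sum((control - m2)^2)
    sp <- sqrt(ss / (n1 + n2 - 2))
    J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
    g <- J * (m1 - m2) / sp
    c(g = g, var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
}

oraclePool <- function(g, v) {
    w <- 1 / v
    f <- sum(w * g) / sum(w)
    se <- sqrt(1 / sum(w))
    c(f_meta = f, se = se, z = f / se,
      p = 2 * pnorm(-abs(f / se)))
}

oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    for (i in seq_len(n)) {
        cands <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
        q[o[i]] <- min(1, cands)
    }
    q
}

oracleSam <- function(x, group, s0) {
    n1 <- sum(group == "case"); n2 <- sum(group == "control")
    vapply(seq_len(nrow(x)), function(i) {
        a <- x[i, group == "case"]; b <- x[i, group == "control"]
        r <- mean(a) - mean(b)
        s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) *
                  (sum((a - mean(a))^2) + sum((b - mean(b))^2)))
        r / (s + s0)
    }, numeric(1))
}

oracleBinomTail <- function(k, m, rate) {
    if (k == 0) return(1)
    sum(vapply(k:m, function(j)
        choose(m, j) * rate^j * (1 - rate)^(m - j), numeric(1)))
}

oraclePearson <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracleSpearman <- function(x, y) oraclePearson(rank(x), rank(y))

oracleKendallTauB <- function(x, y) {
    n <- length(x)
    conc <- disc <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
        if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
    ties <- function(v) {
        tt <- table(v)
        sum(tt * (tt - 1) / 2)
    }
    n0 <- n * (n - 1) / 2
    (conc - disc) / sqrt((n0 - ties(x)) * (n0 - ties(y)))
}

# Exhaustive SAM permutation q-values for tiny designs: every assignment of
# n1 case labels other than the observed grouping (and its mirror when
# balanced), FDR = mean null count at threshold / rank, monotonized.
oracleSamQ <- function(x, group, s0) {
    n <- ncol(x); n1 <- sum(group == "case")
    obs <- which(group == "case")
    combos <- combn(n, n1)
    same <- apply(combos, 2, function(idx)
        setequal(idx, obs) || (2 * n1 == n && setequal(idx, setdiff(1:n, obs))))
    combos <- combos[, !same, drop = FALSE]
    D <- apply(combos, 2, function(idx) {
        g <- rep("control", n); g[idx] <- "case"
        oracleSam(x, g, s0)
    })
    d <- oracleSam(x, group, s0)
    B <- ncol(combos)
    nullAbs <- abs(as.vector(D))
    ord <- order(abs(d), decreasing = TRUE)
    fdr <- vapply(seq_along(ord), function(i)
        min(1, sum(nullAbs >= abs(d[ord[i]])) / B / i), numeric(1))
    q <- rev(cummin(rev(fdr)))
    out <- numeric(length(d))
    out[ord] <- q
    out
}

randomGroups <- function(n1, n2) rep(c("case", "control"), c(n1, n2))
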