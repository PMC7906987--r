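groups33 <- rep(c("case", "control"), each = 3)

test_that("SAM d reproduces the hand computation and sign convention", {
    m <- rbind(g1 = c(4, 5, 6, 1, 2, 3), g2 = c(1, 2, 3, 1, 2, 3))
    d <- samStatistic(m, groups33, s0 = 0)
    expect_equal(unname(d["g1"]), 3 / sqrt(2 / 3), tolerance = 1e-12)
    expect_equal(unname(d["g2"]), 0)
    # d sign matches the case-minus-control mean difference
    expect_gt(d["g1"], 0)
    expect_lt(samStatistic(m[, 6:1, drop = FALSE], groups33, 0)["g1"], 0)
})

test_that("SAM d matches the brute-force oracle on random instances", {
    set.seed(11)
    for (i in 1:100) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        x <- matrix(rnorm(8 * (n1 + n2)), 8,
                    dimnames = list(paste0("g", 1:8), NULL))
        s0 <- runif(1, 0, 0.5)
        grp <- randomGroups(n1, n2)
        expect_equal(as.numeric(samStatistic(x, grp, s0)),
                     oracleSam(x, grp, s0), tolerance = 1e-10)
    }
})

test_that("|d| shrinks monotonically toward 0 as s0 grows", {
    set.seed(12)
    x <- matrix(rnorm(40 * 8, 8), 40, 8,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
    grp <- randomGroups(4, 4)
    s0s <- c(0, 0.5, 2, 10, 1e4)
    dmat <- sapply(s0s, function(s0) abs(samStatistic(x, grp, s0)))
    for (j in 2:length(s0s)) expect_true(all(dmat[, j] <= dmat[, j - 1]))
    expect_lt(max(dmat[, length(s0s)]), 1e-2)
})

test_that("s0 selection: degenerate tie-break, fallback rule, qualitative behavior", {
    # all s equal: every candidate gives an identical criterion;
    # the smallest candidate (= the common s value) is returned
    s <- rep(2, 150); num <- rnorm(150)
    expect_equal(as.numeric(chooseS0(s, num)), 2)
    # tiny input falls back to the 5th percentile of s, and says so
    s10 <- runif(10, 1, 2)
    out <- chooseS0(s10, rnorm(10))
    expect_equal(attr(out, "rule"), "fallback_p5")
    expect_equal(as.numeric(out), unname(quantile(s10, 0.05)))
    # variance-dependent numerators: chosen s0 positive, and it minimizes
    # the windowed-MAD CV over the candidate grid (brute-force check)
    set.seed(13)
    s <- sqrt(rchisq(500, 5) / 5) * 0.2 + 0.05
    num <- rnorm(500, sd = s + 0.3)
    s0 <- chooseS0(s, num)
    expect_gt(as.numeric(s0), 0)
    cand <- attr(s0, "candidates")
    win <- cut(rank(s, ties.method = "first"), 100, labels = FALSE)
    crit <- vapply(cand, function(c0) {
        d <- num / (s + c0)
        m <- tapply(d, win, mad)
        sd(m) / mean(m)
    }, numeric(1))
    expect_equal(as.numeric(s0), cand[which.min(crit)])
})

test_that("permutation q-values: dominant gene, exact enumeration, determinism", {
    set.seed(14)
    x <- matrix(rnorm(50 * 6, sd = 0.3), 50, 6,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    x[1, 1:3] <- x[1, 1:3] + 50  # one gene dwarfs every permuted statistic
    res <- samQValues(x, groups33, nPermutations = 1000, seed = 1, s0 = 0.1)
    expect_equal(res$q[res$gene == "g01"], 0)
    # exact enumeration: all 20 assignments minus the observed grouping
    # and its mirror
    expect_equal(attr(res, "n_permutations_used"), choose(6, 3) - 2)
    # exact enumeration matches the independent exhaustive oracle
    expect_equal(res$q, oracleSamQ(x, groups33, 0.1), tolerance = 1e-10)
    # same seed, same result; q monotone over |d| ranking
    res2 <- samQValues(x, groups33, nPermutations = 1000, seed = 1, s0 = 0.1)
    expect_identical(res, res2)
    ord <- order(abs(res$d), decreasing = TRUE)
    expect_true(all(diff(res$q[ord]) >= 0))
    expect_true(all(res$q >= 0 & res$q <= 1))
    expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
})

test_that("label swap preserves q-values and negates d", {
    set.seed(15)
    x <- matrix(rnorm(30 * 8), 30, 8,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
    grp <- randomGroups(4, 4)
    swap <- ifelse(grp == "case", "control", "case")
    a <- samQValues(x, grp, nPermutations = 500, seed = 2, s0 = 0.2)
    b <- samQValues(x, swap, nPermutations = 500, seed = 2, s0 = 0.2)
    expect_equal(a$d, -b$d)
    expect_equal(a$q, b$q)
})

test_that("designs with fewer than 10 label assignments are refused", {
    x <- matrix(rnorm(10 * 4), 10, 4,
                dimnames = list(paste0("g", 1:10), NULL))
    expect_error(samQValues(x, randomGroups(2, 2), seed = 1, s0 = 0.1),
                 "fewer than 10 distinct")
})
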