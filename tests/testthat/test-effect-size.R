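test_that("Hedges' g reproduces hand-computed values", {
    expect_equal(hedgesG(c(1, 2, 3), c(1, 2, 3))$g, 0)
    expect_equal(hedgesG(c(1, 2, 3), c(1, 2, 3))$var_g, 6 / 9)
    h <- hedgesG(c(3, 4, 5), c(1, 2, 3))
    expect_equal(h$g, 1.6)
    expect_equal(h$var_g, 0.88)
    # zero pooled SD flags the gene as degenerate
    d <- hedgesG(c(2, 2), c(2, 2))
    expect_true(d$degenerate)
    expect_true(is.na(d$g))
    expect_error(hedgesG(1, c(1, 2)), "at least 2")
})

test_that("hedgesG, pooling and the matrix path match the brute-force oracle", {
    set.seed(101)
    for (i in 1:100) {
        n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
        case <- rnorm(n1, sd = runif(1, 0.5, 2))
        ctrl <- rnorm(n2, sd = runif(1, 0.5, 2))
        h <- hedgesG(case, ctrl)
        o <- oracleHedges(case, ctrl)
        expect_equal(h$g, unname(o["g"]), tolerance = 1e-10)
        expect_equal(h$var_g, unname(o["var_g"]), tolerance = 1e-10)
    }
    # vectorized per-dataset path agrees exactly with the scalar function
    x <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(sprintf("g%02d", 1:50),
                                                      NULL))
    grp <- randomGroups(4, 4)
    tab <- metaCrosstalk:::.hedgesGMatrix(x, grp)
    for (i in c(1, 17, 50)) {
        h <- hedgesG(x[i, grp == "case"], x[i, grp == "control"])
        expect_equal(tab$g[i], h$g, tolerance = 1e-12)
        expect_equal(tab$var_g[i], h$var_g, tolerance = 1e-12)
    }
})

test_that("fixed-effect pooling: identities, closed forms, oracle", {
    one <- combineEffectSizes(1.6, 0.88)
    expect_equal(one$f_meta, 1.6)
    expect_equal(one$se, sqrt(0.88))
    two <- combineEffectSizes(c(1, 3), c(1, 1))
    expect_equal(two$f_meta, 2)
    expect_equal(two$se, sqrt(0.5))
    expect_equal(two$z, 2 / sqrt(0.5))
    sym <- combineEffectSizes(c(1, -1), c(1, 1))
    expect_equal(sym$f_meta, 0)
    expect_equal(sym$p, 1)
    expect_error(combineEffectSizes(numeric(0), numeric(0)), "no usable")
    set.seed(202)
    for (i in 1:100) {
        k <- sample(1:6, 1)
        g <- rnorm(k); v <- runif(k, 0.1, 2)
        got <- combineEffectSizes(g, v)
        o <- oraclePool(g, v)
        expect_equal(got$f_meta, unname(o["f_meta"]), tolerance = 1e-10)
        expect_equal(got$se, unname(o["se"]), tolerance = 1e-10)
        expect_equal(got$p, unname(o["p"]), tolerance = 1e-10)
    }
})

test_that("pooling agrees with metafor's fixed-effect model", {
    skip_if_not_installed("metafor")
    set.seed(99)
    g <- rnorm(5); v <- runif(5, 0.2, 1)
    fit <- metafor::rma(yi = g, vi = v, method = "FE")
    got <- combineEffectSizes(g, v)
    expect_equal(got$f_meta, as.numeric(fit$beta), tolerance = 1e-8)
    expect_equal(got$se, fit$se, tolerance = 1e-8)
})

test_that("BH adjustment: examples, oracle, permutation invariance, monotonicity", {
    expect_equal(bhFdr(0.05), 0.05)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(0.5, 6)), rep(0.5, 6))
    expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
    expect_error(bhFdr(c(0.1, NA)), "\\[0, 1\\]")
    set.seed(303)
    for (i in 1:50) {
        p <- runif(sample(1:40, 1))
        q <- bhFdr(p)
        expect_equal(q, oracleBH(p), tolerance = 1e-10)
        perm <- sample(seq_along(p))
        expect_equal(bhFdr(p[perm]), q[perm])
        expect_equal(order(q[order(p)]), seq_along(p))  # sorted p => sorted q
    }
})

test_that("swapping case and control labels negates g and preserves p", {
    set.seed(404)
    case <- rnorm(6, 1); ctrl <- rnorm(5)
    a <- hedgesG(case, ctrl); b <- hedgesG(ctrl, case)
    expect_equal(a$g, -b$g)
    expect_equal(a$var_g, b$var_g)
    pa <- combineEffectSizes(c(a$g, 0.5), c(a$var_g, 0.3))
    pb <- combineEffectSizes(c(b$g, -0.5), c(b$var_g, 0.3))
    expect_equal(pa$f_meta, -pb$f_meta)
    expect_equal(pa$p, pb$p)
})
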