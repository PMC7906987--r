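mkPaired <- function(nGenes = 30, nPatients = 12, seed = 51) {
    set.seed(seed)
    pts <- sprintf("P%02d", seq_len(nPatients))
    mk <- function(comp, id) {
        x <- matrix(rnorm(nGenes * nPatients, 8), nGenes, nPatients,
                    dimnames = list(sprintf("%s_g%02d", comp, seq_len(nGenes)),
                                    paste0(id, "_", pts)))
        ExpressionDataset(x, rep(c("case", "control"),
                                 length.out = nPatients),
                          comp, id, patientId = pts)
    }
    list(tub = mk("tubule", "T1"), glom = mk("glomerulus", "G1"))
}

test_that("an identical expression vector across compartments is retained", {
    d <- mkPaired()
    xt <- exprs(d$tub)
    xg <- exprs(d$glom)
    xg[1, ] <- xt[1, ]  # copy tubule gene 1 into glomerulus gene 1
    glom <- ExpressionDataset(xg, sampleGroup(d$glom), "glomerulus", "G1",
                              patientId = patientId(d$glom))
    cfg <- analysisConfig(corr_consensus = "all_three")
    out <- findPairsOneCohort(d$tub, glom, rownames(xt), rownames(xg), cfg)
    hit <- out[out$tubule_gene == "tubule_g01" &
               out$glom_gene == "glomerulus_g01", ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$r_pearson, 1)
    expect_equal(hit$tau_kendall, 1)
})

test_that("independent genes essentially never pass the screen", {
    d <- mkPaired(nGenes = 40, nPatients = 40, seed = 52)
    out <- findPairsOneCohort(d$tub, d$glom, rownames(d$tub),
                              rownames(d$glom), analysisConfig())
    expect_lte(nrow(out), 1)  # 1600 null pairs at p<0.001 & |r|>0.7
})

test_that("patient alignment is enforced and DEGs missing from matrices reported", {
    d <- mkPaired()
    noPid <- ExpressionDataset(exprs(d$glom), sampleGroup(d$glom),
                               "glomerulus", "G2")
    expect_error(findPairsOneCohort(d$tub, noPid, "tubule_g01",
                                    "glomerulus_g01", analysisConfig()),
                 "patient ids")
    expect_message(
        out <- findPairsOneCohort(d$tub, d$glom,
                                  c("tubule_g01", "NOT_THERE"),
                                  "glomerulus_g01", analysisConfig()),
        "absent from the expression matrices")
    expect_s3_class(out, "data.frame")
})

test_that("intersectPairs keeps only pairs present in every cohort", {
    mkTab <- function(...) {
        pr <- list(...)
        do.call(rbind, lapply(pr, function(p)
            data.frame(tubule_gene = p[1], glom_gene = p[2],
                       r_pearson = as.numeric(p[3]), p_pearson = 1e-5,
                       rho_spearman = as.numeric(p[3]), p_spearman = 1e-5,
                       tau_kendall = as.numeric(p[3]), p_kendall = 1e-5,
                       n_patients = 20)))
    }
    sets <- list(c1 = mkTab(c("A", "B", 0.9), c("C", "D", 0.8)),
                 c2 = mkTab(c("A", "B", 0.85)),
                 c3 = mkTab(c("A", "B", 0.95), c("E", "F", 0.9)),
                 c4 = mkTab(c("A", "B", 0.8)))
    cp <- intersectPairs(sets)
    expect_equal(nrow(pairTable(cp)), 1)
    expect_equal(pairTable(cp)$tubule_gene, "A")
    expect_equal(pairTable(cp)$consensus_sign, "pos")
    expect_equal(pairTable(cp)$median_r, median(c(0.9, 0.85, 0.95, 0.8)))
    # a sign conflict in one cohort rejects the pair
    conflict <- sets
    conflict$c2$r_pearson <- -0.85
    expect_equal(nrow(pairTable(intersectPairs(conflict))), 0)
    # single cohort: returned unchanged
    single <- intersectPairs(sets["c1"])
    expect_equal(nrow(pairTable(single)), 2)
    # intersecting a cohort with itself is idempotent
    twice <- intersectPairs(list(a = sets$c1, b = sets$c1))
    expect_setequal(paste(pairTable(twice)$tubule_gene,
                          pairTable(twice)$glom_gene),
                    paste(sets$c1$tubule_gene, sets$c1$glom_gene))
})

test_that("network construction labels sides and exposes hub degree", {
    # one glomerular hub correlated with nine tubular genes
    tab <- data.frame(tubule_gene = paste0("T", 1:9), glom_gene = "HUB",
                      consensus_sign = "pos", median_r = 0.8,
                      n_cohorts = 4)
    net <- buildNetwork(tab)
    expect_equal(unname(networkDegree(net)["HUB"]), 9)
    expect_equal(net@nodes$side[net@nodes$gene == "HUB"], "glomerulus")
    # a single pair yields two nodes and one edge
    one <- buildNetwork(tab[1, ])
    expect_equal(nrow(one@nodes), 2)
    expect_equal(nrow(one@edges), 1)
    # a gene on both sides across pairs is labelled "both"
    both <- rbind(tab[1:2, ],
                  data.frame(tubule_gene = "HUB", glom_gene = "G9",
                             consensus_sign = "neg", median_r = -0.75,
                             n_cohorts = 4))
    netB <- buildNetwork(both)
    expect_equal(netB@nodes$side[netB@nodes$gene == "HUB"], "both")
})

test_that("planted pairs are recovered across cohorts at high latent correlation", {
    gcfg <- generatorConfig(n_genes = 60L, n_planted_degs = 0L,
                            n_planted_pairs = 6L, rho_true = 0.9,
                            n_paired_cohorts = 3L, n_patients = 40L,
                            seed = 53L)
    gen <- generatePairedCompartments(gcfg)
    genes <- rownames(gen$cohorts[[1]]$tubule)
    per <- lapply(gen$cohorts, function(co)
        findPairsOneCohort(co$tubule, co$glomerulus, genes, genes,
                           analysisConfig()))
    got <- pairTable(intersectPairs(per))
    truthKey <- paste(gen$truth@pairTruth$tubule_gene,
                      gen$truth@pairTruth$glom_gene)
    gotKey <- paste(got$tubule_gene, got$glom_gene)
    expect_gte(sum(truthKey %in% gotKey), 5)   # >= 5 of 6 planted
    expect_lte(sum(!gotKey %in% truthKey), 1)  # at most one false pair
    expect_true(all(got$consensus_sign[gotKey %in% truthKey] == "pos"))
})
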