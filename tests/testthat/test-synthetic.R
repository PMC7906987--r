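test_that("generation is deterministic under the root seed", {
    cfg <- generatorConfig(n_genes = 40L, n_datasets = 2L, n_case = 5L,
                           n_control = 5L, n_planted_degs = 5L, seed = 81L)
    a <- generateMetaCohorts(cfg)
    b <- generateMetaCohorts(cfg)
    expect_identical(exprs(a$datasets[[2]]), exprs(b$datasets[[2]]))
    expect_identical(a$truth@degTruth, b$truth@degTruth)
    p1 <- generatePairedCompartments(cfg)
    p2 <- generatePairedCompartments(cfg)
    expect_identical(exprs(p1$cohorts[[1]]$glomerulus),
                     exprs(p2$cohorts[[1]]$glomerulus))
    # different seeds give different data
    c2 <- generateMetaCohorts(generatorConfig(n_genes = 40L,
                                              n_datasets = 2L, n_case = 5L,
                                              n_control = 5L,
                                              n_planted_degs = 5L,
                                              seed = 82L))
    expect_false(identical(exprs(a$datasets[[1]]), exprs(c2$datasets[[1]])))
})

test_that("null configuration plants nothing and produces no structure", {
    cfg <- generatorConfig(n_genes = 50L, n_datasets = 2L, n_case = 5L,
                           n_control = 5L, n_planted_degs = 0L,
                           n_planted_pairs = 0L, seed = 83L)
    gen <- generateMetaCohorts(cfg)
    expect_equal(nrow(gen$truth@degTruth), 0)
    paired <- generatePairedCompartments(cfg)
    expect_equal(nrow(paired$truth@pairTruth), 0)
})

test_that("planted effect sizes are recovered within sampling error", {
    # large groups: per-dataset Hedges' g of planted genes, averaged over
    # genes, datasets and generator replicates, converges on the planted
    # value; 2 SE tolerance on the replicate-averaged estimate
    devs <- sapply(c(84L, 184L, 284L), function(sd0) {
        cfg <- generatorConfig(n_genes = 300L, n_datasets = 2L,
                               n_case = 100L, n_control = 100L,
                               n_planted_degs = 40L,
                               effect_size_true = 1.0, noise_sd = 1.7,
                               seed = sd0)
        gen <- generateMetaCohorts(cfg)
        truth <- gen$truth@degTruth
        gs <- sapply(gen$datasets, function(d) {
            tab <- metaCrosstalk:::.hedgesGMatrix(exprs(d), sampleGroup(d))
            tab$g[match(truth$gene, tab$gene)]
        })
        # half the planted genes are down-regulated
        expect_equal(sum(truth$effect_size < 0), nrow(truth) / 2)
        mean(rowMeans(gs) * sign(truth$effect_size)) - 1.0
    })
    # var(g) ~ (n1+n2)/(n1 n2) + g^2/(2(n1+n2)) = 0.0225 per gene at
    # 100v100; averaged over 40 genes x 2 datasets x 3 replicates
    se <- sqrt(0.0225 / (40 * 2 * 3))
    expect_lt(abs(mean(devs)), 2 * se)
})

test_that("planted pair correlations converge on rho_true (Fisher z)", {
    cfg <- generatorConfig(n_genes = 30L, n_planted_degs = 0L,
                           n_planted_pairs = 5L, n_paired_cohorts = 1L,
                           n_patients = 200L, rho_true = 0.9, seed = 85L)
    gen <- generatePairedCompartments(cfg)
    co <- gen$cohorts[[1]]
    rs <- mapply(function(tg, gg)
        cor(exprs(co$tubule)[tg, ], exprs(co$glomerulus)[gg, ]),
        gen$truth@pairTruth$tubule_gene, gen$truth@pairTruth$glom_gene)
    # Fisher-z 95% band for rho = 0.9 at n = 200 is about [0.87, 0.925]
    expect_true(all(rs > 0.85 & rs < 0.95))
    # negative rho_true plants negative correlations
    cfgN <- generatorConfig(n_genes = 30L, n_planted_degs = 0L,
                            n_planted_pairs = 5L, n_paired_cohorts = 1L,
                            n_patients = 100L, rho_true = -0.85,
                            seed = 86L)
    genN <- generatePairedCompartments(cfgN)
    coN <- genN$cohorts[[1]]
    rsN <- mapply(function(tg, gg)
        cor(exprs(coN$tubule)[tg, ], exprs(coN$glomerulus)[gg, ]),
        genN$truth@pairTruth$tubule_gene, genN$truth@pairTruth$glom_gene)
    expect_true(all(rsN < -0.6))
})

test_that("patient ids are shared across compartments within a cohort", {
    gen <- generatePairedCompartments(generatorConfig(
        n_genes = 20L, n_planted_degs = 0L, n_planted_pairs = 2L,
        n_paired_cohorts = 2L, n_patients = 10L, seed = 87L))
    for (co in gen$cohorts)
        expect_identical(patientId(co$tubule), patientId(co$glomerulus))
    expect_s4_class(gen$collection, "StudyCollection")
    expect_equal(nrow(gen$collection@pairedCohorts), 2)
})

test_that("truth tables round-trip, including the empty case", {
    truth <- new("SyntheticTruth",
                 degTruth = data.frame(gene = c("G1", "G2"),
                                       compartment = "tubule",
                                       effect_size = c(1, -1)),
                 pairTruth = data.frame(tubule_gene = "G1",
                                        glom_gene = "G9",
                                        rho_true = 0.85))
    d <- tempfile()
    writeTruth(truth, d)
    back <- readTruth(d)
    expect_equal(back@degTruth, truth@degTruth)
    expect_equal(back@pairTruth, truth@pairTruth)
    empty <- new("SyntheticTruth",
                 degTruth = data.frame(gene = character(),
                                       compartment = character(),
                                       effect_size = numeric()),
                 pairTruth = data.frame(tubule_gene = character(),
                                        glom_gene = character(),
                                        rho_true = numeric()))
    d2 <- tempfile()
    writeTruth(empty, d2)  # header-only files are valid
    back2 <- readTruth(d2)
    expect_equal(nrow(back2@degTruth), 0)
    expect_equal(nrow(back2@pairTruth), 0)
})
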