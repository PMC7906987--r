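#' Build a GeneratorConfig
#'
#' Study conditions for the synthetic generator. Defaults: 1000 genes; four
#' case/control cohorts of 15 vs 15 with 50 planted DEGs at Hedges-scale
#' effect 1.0 (half down-regulated); four paired two-compartment cohorts of
#' 40 patients with 20 planted cross-compartment pairs at latent correlation
#' 0.85; per-dataset batch shift SD 0.5 and within-sample noise SD 1.0 on
#' the log2 scale.
#'
#' @param n_genes,n_datasets,n_case,n_control,n_planted_degs meta-cohort
#'   dimensions.
#' @param effect_size_true planted standardized effect (in noise-SD units,
#'   so the true Hedges' g of a planted gene is approximately this value
#'   regardless of noise_sd).
#' @param n_paired_cohorts,n_patients,n_planted_pairs,rho_true paired-cohort
#'   dimensions; \code{rho_true} in (-1, 1) is the target population
#'   cross-compartment correlation of a planted pair.
#' @param batch_shift_sd,noise_sd nuisance scales (log2 units).
#' @param seed root seed for all generator randomness.
#' @return a \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(n_genes = 1000L, n_datasets = 4L, n_case = 15L,
                            n_control = 15L, n_planted_degs = 50L,
                            effect_size_true = 1.0, n_paired_cohorts = 4L,
                            n_patients = 40L, n_planted_pairs = 20L,
                            rho_true = 0.85, batch_shift_sd = 0.5,
                            noise_sd = 1.0, seed = 1L) {
    new("GeneratorConfig",
        n_genes = as.integer(n_genes), n_datasets = as.integer(n_datasets),
        n_case = as.integer(n_case), n_control = as.integer(n_control),
        n_planted_degs = as.integer(n_planted_degs),
        effect_size_true = as.numeric(effect_size_true),
        n_paired_cohorts = as.integer(n_paired_cohorts),
        n_patients = as.integer(n_patients),
        n_planted_pairs = as.integer(n_planted_pairs),
        rho_true = as.numeric(rho_true),
        batch_shift_sd = as.numeric(batch_shift_sd),
        noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
}

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig\n")
    for (nm in slotNames(object))
        cat("  ", nm, ": ", as.character(slot(object, nm)), "\n", sep = "")
})

.geneNames <- function(n) sprintf("G%05d", seq_len(n))

# Planted DEG truth: which genes, which signs (half down-regulated).
.plantDegs <- function(config) {
    if (config@n_planted_degs == 0L)
        return(data.frame(gene = character(), effect_size = numeric()))
    genes <- .geneNames(config@n_genes)
    pick <- sample(genes, config@n_planted_degs)
    sgn <- rep(c(1, -1), length.out = length(pick))
    data.frame(gene = pick, effect_size = sgn * config@effect_size_true)
}

#' Generate case/control meta-analysis cohorts with planted DEGs
#'
#' Per dataset: baseline gene means ~ Normal(8, 2) on the log2 scale (drawn
#' once, shared by all datasets), a per-dataset scalar batch shift
#' ~ Normal(0, batch_shift_sd) added to all values, and per-sample noise
#' ~ Normal(0, noise_sd). Planted DEGs get \code{effect_size *
#' noise_sd} added to case samples (signed; half the planted genes are
#' down-regulated), so their true Hedges-scale effect is
#' \code{effect_size_true}. Deterministic under \code{config@seed}.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param compartment compartment label stamped on the datasets.
#' @param stage extra label mixed into the derived random stream, so e.g.
#'   tubule and glomerulus generations are independent.
#' @return list: \code{datasets} (list of \linkS4class{ExpressionDataset}),
#'   \code{truth} (a \linkS4class{SyntheticTruth} with the planted DEG
#'   table).
#' @export
generateMetaCohorts <- function(config, compartment = "tubule",
                                stage = "meta") {
    validObject(config)
    .withStageSeed(config@seed, paste0("generate_meta:", stage), {
        genes <- .geneNames(config@n_genes)
        mu <- stats::rnorm(config@n_genes, 8, 2)
        truth <- .plantDegs(config)
        eff <- stats::setNames(rep(0, config@n_genes), genes)
        eff[truth$gene] <- truth$effect_size * config@noise_sd
        nS <- config@n_case + config@n_control
        group <- rep(c("case", "control"), c(config@n_case, config@n_control))
        datasets <- lapply(seq_len(config@n_datasets), function(d) {
            shift <- stats::rnorm(1, 0, config@batch_shift_sd)
            x <- mu + shift +
                matrix(stats::rnorm(config@n_genes * nS, 0, config@noise_sd),
                       config@n_genes, nS)
            x[, group == "case"] <- x[, group == "case"] + eff
            dimnames(x) <- list(genes, sprintf("D%d_S%02d", d, seq_len(nS)))
            ExpressionDataset(x, group = group, compartment = compartment,
                              datasetId = sprintf("%s_meta_%d",
                                                  compartment, d))
        })
        truth$compartment <- rep(compartment, nrow(truth))
        list(datasets = datasets,
             truth = new("SyntheticTruth",
                         degTruth = truth[, c("gene", "compartment",
                                              "effect_size")],
                         pairTruth = data.frame(tubule_gene = character(),
                                                glom_gene = character(),
                                                rho_true = numeric())))
    })
}

#' Generate paired two-compartment cohorts with planted correlated pairs
#'
#' Each cohort holds a tubule and a glomerulus dataset over the same
#' patients. For a planted pair and patient p, a shared latent factor
#' \eqn{z_p ~ N(0,1)} drives both sides:
#' \eqn{x_{tub} = \sqrt{|\rho|} z + \sqrt{1-|\rho|}\, e_1},
#' \eqn{x_{glom} = sign(\rho)\sqrt{|\rho|} z + \sqrt{1-|\rho|}\, e_2},
#' so the population cross-compartment correlation equals \code{rho_true};
#' non-planted genes are independent noise. Both sides are scaled by
#' \code{noise_sd} and shifted by gene baselines and a per-dataset batch
#' shift. Patients are split into case and control halves; when
#' \code{n_planted_degs > 0} a case mean-shift is planted per compartment.
#' Pair genes are then drawn from the planted DEG genes (so a
#' DEG-restricted correlation screen contains the planted pairs), with DEG
#' signs matched to the sign of \code{rho_true}: the shared disease effect
#' reinforces the latent-factor correlation instead of cancelling it, as
#' expected when a common disease process drives both compartments.
#'
#' @inheritParams generateMetaCohorts
#' @return list: \code{cohorts} (named list; each element has \code{tubule}
#'   and \code{glomerulus} \linkS4class{ExpressionDataset}s),
#'   \code{collection} (a ready \linkS4class{StudyCollection}), and
#'   \code{truth} (planted DEGs for both compartments + planted pair table).
#' @export
generatePairedCompartments <- function(config, stage = "paired") {
    validObject(config)
    .withStageSeed(config@seed, paste0("generate_paired:", stage), {
        genes <- .geneNames(config@n_genes)
        muT <- stats::rnorm(config@n_genes, 8, 2)
        muG <- stats::rnorm(config@n_genes, 8, 2)
        degT <- .plantDegs(config)
        degG <- .plantDegs(config)
        rho <- config@rho_true
        if (nrow(degT) && nrow(degG)) {
            # pair genes come from the planted DEG sets, with DEG signs
            # matched to the sign of rho so the shared disease effect
            # reinforces (not cancels) the latent-factor correlation
            nPairs <- min(config@n_planted_pairs, nrow(degT))
            tubPick <- sample(degT$gene, nPairs)
            sT <- sign(degT$effect_size[match(tubPick, degT$gene)])
            glomPick <- character(nPairs)
            for (s in c(-1, 1)) {
                want <- which(sT * sign(rho) == s)
                poolS <- degG$gene[sign(degG$effect_size) == s]
                take <- min(length(want), length(poolS))
                want <- want[seq_len(take)]
                glomPick[want] <- sample(poolS, length(want))
            }
            keep <- nzchar(glomPick)
            tubPick <- tubPick[keep]; glomPick <- glomPick[keep]
            nPairs <- length(tubPick)
        } else {
            nPairs <- min(config@n_planted_pairs, config@n_genes)
            tubPick <- sample(genes, nPairs)
            glomPick <- sample(genes, nPairs)
        }
        pairTruth <- data.frame(tubule_gene = tubPick,
                                glom_gene = glomPick,
                                rho_true = rep(config@rho_true, nPairs))
        a <- sqrt(abs(rho)); b <- sqrt(1 - abs(rho))
        nP <- config@n_patients
        group <- rep(c("case", "control"), length.out = nP)
        effT <- stats::setNames(rep(0, config@n_genes), genes)
        effG <- effT
        if (nrow(degT)) effT[degT$gene] <- degT$effect_size * config@noise_sd
        if (nrow(degG)) effG[degG$gene] <- degG$effect_size * config@noise_sd
        cohorts <- lapply(seq_len(config@n_paired_cohorts), function(cid) {
            pts <- sprintf("C%d_P%03d", cid, seq_len(nP))
            shiftT <- stats::rnorm(1, 0, config@batch_shift_sd)
            shiftG <- stats::rnorm(1, 0, config@batch_shift_sd)
            Et <- matrix(stats::rnorm(config@n_genes * nP),
                         config@n_genes, nP)
            Eg <- matrix(stats::rnorm(config@n_genes * nP),
                         config@n_genes, nP)
            if (nPairs > 0) {
                Z <- matrix(stats::rnorm(nPairs * nP), nPairs, nP)
                ti <- match(tubPick, genes); gi <- match(glomPick, genes)
                Et[ti, ] <- a * Z + b * Et[ti, , drop = FALSE]
                Eg[gi, ] <- sign(rho) * a * Z + b * Eg[gi, , drop = FALSE]
            }
            xT <- muT + shiftT + config@noise_sd * Et
            xG <- muG + shiftG + config@noise_sd * Eg
            xT[, group == "case"] <- xT[, group == "case"] + effT
            xG[, group == "case"] <- xG[, group == "case"] + effG
            dimnames(xT) <- list(genes, paste0(pts, "_T"))
            dimnames(xG) <- list(genes, paste0(pts, "_G"))
            list(tubule = ExpressionDataset(
                     xT, group = group, compartment = "tubule",
                     datasetId = sprintf("paired_%d_tub", cid),
                     patientId = pts),
                 glomerulus = ExpressionDataset(
                     xG, group = group, compartment = "glomerulus",
                     datasetId = sprintf("paired_%d_glom", cid),
                     patientId = pts))
        })
        names(cohorts) <- sprintf("cohort_%d",
                                  seq_len(config@n_paired_cohorts))
        degT$compartment <- rep("tubule", nrow(degT))
        degG$compartment <- rep("glomerulus", nrow(degG))
        degTruth <- rbind(degT[, c("gene", "compartment", "effect_size")],
                          degG[, c("gene", "compartment", "effect_size")])
        paired <- data.frame(
            cohort_id = names(cohorts),
            tubule_id = vapply(cohorts, function(co)
                datasetId(co$tubule), character(1)),
            glomerulus_id = vapply(cohorts, function(co)
                datasetId(co$glomerulus), character(1)))
        collection <- StudyCollection(
            unlist(lapply(cohorts, function(co)
                list(co$tubule, co$glomerulus)), recursive = FALSE),
            pairedCohorts = paired)
        list(cohorts = cohorts, collection = collection,
             truth = new("SyntheticTruth", degTruth = degTruth,
                         pairTruth = pairTruth))
    })
}

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", nrow(object@degTruth), "planted DEG record(s),",
        nrow(object@pairTruth), "planted pair(s)\n")
})

#' Write / read the planted truth tables
#'
#' Two tab-separated tables (\code{deg_truth.tsv}, \code{pair_truth.tsv});
#' empty truth yields valid header-only files. Round-trip safe.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param outDir output directory (created if needed).
#' @return \code{writeTruth}: invisible paths; \code{readTruth}: a
#'   \linkS4class{SyntheticTruth}.
#' @export
writeTruth <- function(truth, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    fd <- file.path(outDir, "deg_truth.tsv")
    fp <- file.path(outDir, "pair_truth.tsv")
    utils::write.table(truth@degTruth, fd, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth@pairTruth, fp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(fd, fp))
}

#' @rdname writeTruth
#' @param dir directory holding the truth tables.
#' @export
readTruth <- function(dir) {
    deg <- utils::read.delim(file.path(dir, "deg_truth.tsv"),
                             colClasses = c("character", "character",
                                            "numeric"))
    pair <- utils::read.delim(file.path(dir, "pair_truth.tsv"),
                              colClasses = c("character", "character",
                                             "numeric"))
    new("SyntheticTruth", degTruth = deg, pairTruth = pair)
}
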