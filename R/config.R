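#' Build an AnalysisConfig
#'
#' All cutoffs of the pipeline in one validated object. The defaults are the
#' study cutoffs: pooled-effect FDR <= 5%, per-dataset SAM q < 10%,
#' cross-dataset combination p <= 0.05, correlation |r| > 0.7 with p < 0.001,
#' and a linear fold-change filter of 1.5 for the enrichment export.
#'
#' @param fdr_max,sam_q_max,repl_p_max,r_min,corr_p_max,fold_change_min
#'   thresholds; see \linkS4class{AnalysisConfig}.
#' @param n_permutations number of SAM label permutations (>= 100).
#' @param seed root seed; each stochastic stage derives its own substream, so
#'   adding a stage never perturbs another stage's draws.
#' @param corr_consensus \code{"pearson_only"} (default), \code{"all_three"}
#'   or \code{"any_one"}; which correlation methods must clear the cutoffs.
#' @param sam_combine \code{"fisher"} (default) or \code{"binomial"}.
#' @param min_datasets_present minimum datasets a gene must appear in.
#' @return An \linkS4class{AnalysisConfig}.
#' @examples
#' cfg <- analysisConfig(seed = 7)
#' cfg
#' @export
analysisConfig <- function(fdr_max = 0.05, sam_q_max = 0.10,
                           repl_p_max = 0.05, r_min = 0.7,
                           corr_p_max = 0.001, fold_change_min = 1.5,
                           n_permutations = 1000L, seed = 1L,
                           corr_consensus = "pearson_only",
                           sam_combine = "fisher",
                           min_datasets_present = 2L) {
    new("AnalysisConfig",
        fdr_max = as.numeric(fdr_max), sam_q_max = as.numeric(sam_q_max),
        repl_p_max = as.numeric(repl_p_max), r_min = as.numeric(r_min),
        corr_p_max = as.numeric(corr_p_max),
        fold_change_min = as.numeric(fold_change_min),
        n_permutations = as.integer(n_permutations), seed = as.integer(seed),
        corr_consensus = corr_consensus, sam_combine = sam_combine,
        min_datasets_present = as.integer(min_datasets_present))
}

setMethod("show", "AnalysisConfig", function(object) {
    cat("AnalysisConfig\n")
    for (nm in slotNames(object))
        cat("  ", nm, ": ", as.character(slot(object, nm)), "\n", sep = "")
})

.configFields <- function() {
    c("fdr_max", "sam_q_max", "repl_p_max", "r_min", "corr_p_max",
      "fold_change_min", "n_permutations", "seed", "corr_consensus",
      "sam_combine", "min_datasets_present")
}

#' Read / write an AnalysisConfig as a key:value text file
#'
#' One `key: value` pair per line; unknown keys are an error so a typo in a
#' threshold name cannot silently fall back to a default. The written file is
#' echoed verbatim into the run log for provenance.
#'
#' @param path file path.
#' @return \code{readAnalysisConfig}: an \linkS4class{AnalysisConfig};
#'   \code{writeAnalysisConfig}: \code{path}, invisibly.
#' @export
readAnalysisConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
    bad <- lines[vapply(kv, length, integer(1)) != 3L]
    if (length(bad)) stop("malformed config line(s): ",
                          paste(bad, collapse = "; "))
    keys <- vapply(kv, `[`, character(1), 2L)
    vals <- vapply(kv, `[`, character(1), 3L)
    unknown <- setdiff(keys, .configFields())
    if (length(unknown)) stop("unknown config key(s): ",
                              paste(unknown, collapse = ", "))
    args <- as.list(vals)
    names(args) <- keys
    num <- setdiff(.configFields(), c("corr_consensus", "sam_combine"))
    for (k in intersect(names(args), num)) args[[k]] <- as.numeric(args[[k]])
    do.call(analysisConfig, args)
}

#' @rdname readAnalysisConfig
#' @param config an \linkS4class{AnalysisConfig}.
#' @export
writeAnalysisConfig <- function(config, path) {
    lines <- vapply(.configFields(), function(nm)
        paste0(nm, ": ", as.character(slot(config, nm))), character(1))
    writeLines(lines, path)
    invisible(path)
}
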