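#' Two-set Venn partition of DEG lists
#'
#' Splits two gene sets into the genes unique to each and the shared
#' overlap — the comparison used to contrast tubular and glomerular DEG
#' signatures.
#'
#' @param setA,setB character vectors (duplicates are collapsed).
#' @param labels length-2 character vector naming the sets.
#' @return list of class \code{"VennPartition"} with \code{unique_a},
#'   \code{unique_b}, \code{shared}, \code{labels}, and a \code{counts}
#'   vector.
#' @examples
#' vennPartition(c("A", "B", "C"), c("B", "C", "D"))
#' @export
vennPartition <- function(setA, setB, labels = c("A", "B")) {
    a <- unique(as.character(setA)); b <- unique(as.character(setB))
    shared <- intersect(a, b)
    out <- list(unique_a = setdiff(a, b), unique_b = setdiff(b, a),
                shared = shared, labels = labels)
    out$counts <- c(stats::setNames(length(out$unique_a),
                                    paste0("unique_", labels[1])),
                    stats::setNames(length(out$unique_b),
                                    paste0("unique_", labels[2])),
                    shared = length(shared))
    class(out) <- "VennPartition"
    out
}

#' @export
print.VennPartition <- function(x, ...) {
    cat("VennPartition (", x$labels[1], " vs ", x$labels[2], ")\n", sep = "")
    print(x$counts)
    invisible(x)
}

#' Direction-aware Venn partition
#'
#' Variant in which a gene counts as shared only when it is called in both
#' compartments with the same direction of change; genes called in both but
#' with opposite signs are assigned to both unique sets.
#'
#' @param callsA,callsB DEG call tables (\code{\link{callDegs}}) for the two
#'   compartments; only rows with \code{final_call} are used.
#' @inheritParams vennPartition
#' @return a \code{"VennPartition"} (see \code{\link{vennPartition}}).
#' @export
vennPartitionDirectional <- function(callsA, callsB,
                                     labels = c("A", "B")) {
    a <- callsA[callsA$final_call, c("gene", "direction")]
    b <- callsB[callsB$final_call, c("gene", "direction")]
    shared <- merge(a, b, by = "gene")
    shared <- shared$gene[shared$direction.x == shared$direction.y]
    out <- list(unique_a = setdiff(a$gene, shared),
                unique_b = setdiff(b$gene, shared),
                shared = shared, labels = labels)
    out$counts <- c(stats::setNames(length(out$unique_a),
                                    paste0("unique_", labels[1])),
                    stats::setNames(length(out$unique_b),
                                    paste0("unique_", labels[2])),
                    shared = length(shared))
    class(out) <- "VennPartition"
    out
}
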