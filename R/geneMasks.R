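#' Binary gene masks
#'
#' The mask of gene i is the indicator vector of its non-overlapping sample
#' set: bit j is 1 iff x_ij falls inside the core interval of sample j's own
#' class and outside the overlap region, i.e. the gene assigns sample j to
#' its correct class unambiguously. A sample lying outside its own class's
#' core interval (an expression outlier) always gets bit 0, even when it is
#' far from the overlap region. Mask rows therefore encode each gene's
#' training-sample classification power.
#'
#' @param x a \linkS4class{CoreIntervalSet}, or a \linkS4class{POSExperiment}
#'   (intervals are then computed first with the supplied arguments).
#' @param ... for the \code{POSExperiment} method, arguments passed on to
#'   \code{\link{coreIntervals}}.
#' @return A \linkS4class{GeneMaskSet}.
#' @examples
#' sim <- simulateExpression(nInformative = 1, nNoise = 1, seed = 1)
#' geneMasks(sim)
#' @rdname geneMasks
#' @export
setMethod("geneMasks", "CoreIntervalSet", function(x, ...) {
    m <- x@nonoverlap
    storage.mode(m) <- "integer"
    new("GeneMaskSet", masks = m, onesCount = as.integer(rowSums(m)))
})

#' @rdname geneMasks
#' @export
setMethod("geneMasks", "POSExperiment", function(x, ...) {
    geneMasks(coreIntervals(x, ...))
})

#' @rdname accessors
#' @export
setMethod("maskMatrix", "GeneMaskSet", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("onesCount", "GeneMaskSet", function(x) {
    stats::setNames(x@onesCount, rownames(x@masks))
})

setMethod("show", "GeneMaskSet", function(object) {
    cat("GeneMaskSet:", nrow(object@masks), "genes x", ncol(object@masks),
        "samples;", sum(object@onesCount), "one-bits total\n")
})

#' Aggregate mask of a gene set
#'
#' Elementwise logical OR of the masks of the given genes: bit j is 1 iff at
#' least one gene in the set classifies sample j unambiguously. The empty set
#' yields the all-zero vector (the greedy search's loop initialisation).
#' Samples with bit 0 in the aggregate over all genes are unclassifiable by
#' every gene.
#'
#' @param masks a \linkS4class{GeneMaskSet} or a binary matrix with genes in
#'   rows.
#' @param genes gene indices or ids forming the set; NULL (default) uses all
#'   genes.
#' @return Integer 0/1 vector with one entry per sample.
#' @examples
#' m <- rbind(g1 = c(1, 1, 0, 0), g2 = c(0, 0, 1, 1))
#' aggregateMask(m)
#' @export
aggregateMask <- function(masks, genes = NULL) {
    m <- if (is(masks, "GeneMaskSet")) maskMatrix(masks) else as.matrix(masks)
    if (is.null(genes)) genes <- seq_len(nrow(m))
    if (is.character(genes)) genes <- match(genes, rownames(m))
    if (length(genes) == 0L)
        return(stats::setNames(integer(ncol(m)), colnames(m)))
    as.integer(colSums(m[genes, , drop = FALSE]) > 0L) |>
        stats::setNames(colnames(m))
}

#' Write a 0/1 mask matrix as TSV (debug aid)
#'
#' @param masks a \linkS4class{GeneMaskSet}.
#' @param path output path.
#' @export
writeMasks <- function(masks, path) {
    m <- maskMatrix(masks)
    utils::write.table(data.frame(gene_id = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}
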