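#' Round-robin ranking of the remaining genes
#'
#' Partitions the genes not chosen into the minimum subset by their relative
#' dominant class, sorts each group by ascending POS (ties by gene index,
#' which keeps runs reproducible), and interleaves the two groups starting
#' from the class-1 group. When one group runs out, the rest of the other is
#' appended. Alternating between the two RDC groups balances the selected
#' genes across the classes each gene distinguishes best, which counters the
#' bias a plain POS sort would show under unbalanced class sizes.
#'
#' @param scores a \linkS4class{GeneScoreTable}.
#' @param exclude gene indices or ids to leave out (normally the minimum
#'   subset).
#' @return Integer vector of gene indices in ranking order.
#' @examples
#' sim <- simulateExpression(nInformative = 2, nNoise = 6, seed = 1)
#' sc <- posScores(sim, seed = 1)
#' roundRobinRank(sc)
#' @export
roundRobinRank <- function(scores, exclude = integer(0)) {
    if (is.character(exclude)) exclude <- match(exclude, scores@geneIds)
    keep <- setdiff(seq_along(scores@pos), exclude)
    g1 <- keep[scores@rdc[keep] == 1L]
    g2 <- keep[scores@rdc[keep] == 2L]
    g1 <- g1[order(scores@pos[g1], g1)]
    g2 <- g2[order(scores@pos[g2], g2)]
    n1 <- length(g1); n2 <- length(g2); n <- min(n1, n2)
    head <- integer(0)
    if (n > 0L) {
        head <- integer(2L * n)
        head[seq(1L, 2L * n, by = 2L)] <- g1[seq_len(n)]
        head[seq(2L, 2L * n, by = 2L)] <- g2[seq_len(n)]
    }
    c(head, if (n1 > n) g1[(n + 1L):n1] else integer(0),
            if (n2 > n) g2[(n + 1L):n2] else integer(0))
}

#' Run the full POS gene selection
#'
#' End-to-end pipeline: core intervals, gene masks, POS scores and RDC
#' assignments, greedy minimum covering subset, then the final ranked list:
#' the minimum subset first (in selection order, regardless of POS, because
#' those genes jointly classify the maximum number of training samples),
#' extended by the top nu = r - |G*| genes of the round-robin ranking. When
#' |G*| >= r the whole minimum subset is returned with a warning (length
#' |G*| > r); set \code{strictR = TRUE} to truncate to exactly r at the cost
#' of the coverage guarantee.
#'
#' @param x a \linkS4class{POSExperiment}.
#' @param r requested total number of genes (1 <= r <= number of genes).
#' @param seed integer seed used for RDC tie randomisation.
#' @param quartileType quantile rule for the core intervals (default 7).
#' @param sampleDenominator overlapped-sample factor denominator, see
#'   \code{\link{posScores}}.
#' @param overlapOnNonoutlier see \code{\link{coreIntervals}}.
#' @param strictR truncate the result to exactly r genes (default FALSE).
#' @param ... unused.
#' @return A \linkS4class{SelectionResult}.
#' @examples
#' sim <- simulateExpression(nInformative = 3, nNoise = 20, seed = 1)
#' res <- selectGenes(sim, r = 5, seed = 1)
#' finalGenes(res)
#' @rdname selectGenes
#' @export
setMethod("selectGenes", "POSExperiment",
    function(x, r, seed = 1L, quartileType = 7L,
             sampleDenominator = c("all", "nonoutlier"),
             overlapOnNonoutlier = FALSE, strictR = FALSE, ...) {
    r <- as.integer(r)
    if (is.na(r) || r < 1L) .valStop("r must be a positive integer")
    if (r > nrow(x))
        .valStop("r = ", r, " exceeds the number of genes (", nrow(x), ")")
    sampleDenominator <- match.arg(sampleDenominator)
    ci <- coreIntervals(x, quartileType = quartileType,
                        overlapOnNonoutlier = overlapOnNonoutlier)
    masks <- geneMasks(ci)
    scores <- posScores(x, intervals = ci, masks = masks, seed = seed,
                        sampleDenominator = sampleDenominator)
    ms <- minimumSubset(masks, scores)
    ranked <- roundRobinRank(scores, exclude = ms@genes)
    nu <- r - length(ms@genes)
    if (nu < 0L && !strictR)
        warning("minimum covering subset has ", length(ms@genes),
                " genes, exceeding r = ", r,
                "; returning the whole subset (use strictR = TRUE to truncate)",
                call. = FALSE)
    idx <- c(ms@genes, utils::head(ranked, max(0L, nu)))
    if (strictR) idx <- utils::head(idx, r)
    ids <- scores@geneIds
    tab <- S4Vectors::DataFrame(
        geneId = ids[idx],
        rank = seq_along(idx),
        pos = scores@pos[idx],
        rdc = scores@rdc[idx],
        inMinimumSubset = seq_along(idx) <= min(length(ms@genes),
                                                length(idx)),
        maskOnes = as.integer(rowSums(maskMatrix(masks)))[idx],
        source = ifelse(seq_along(idx) <= min(length(ms@genes), length(idx)),
                        "min_subset", "ranked"))
    new("SelectionResult", finalGenes = ids[idx], table = tab,
        minSubset = ms, scores = scores, r = r, seed = as.integer(seed),
        parameters = list(quartileType = as.integer(quartileType),
                          sampleDenominator = sampleDenominator,
                          overlapOnNonoutlier = overlapOnNonoutlier,
                          strictR = strictR,
                          labelMap = metadata(x)$labelMap,
                          nMinSubset = length(ms@genes)))
})

#' @rdname accessors
#' @export
setMethod("finalGenes", "SelectionResult", function(x) x@finalGenes)

#' @rdname accessors
#' @export
setMethod("selectionTable", "SelectionResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("posScore", "SelectionResult", function(x)
    stats::setNames(x@table$pos, x@table$geneId))

#' @rdname accessors
#' @export
setMethod("relativeDominantClass", "SelectionResult", function(x)
    stats::setNames(x@table$rdc, x@table$geneId))

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult: r =", object@r, "->", length(object@finalGenes),
        "genes (", length(object@minSubset@genes), "in minimum subset )\n")
    print(utils::head(as.data.frame(object@table), 8L))
    if (length(object@finalGenes) > 8L)
        cat("...", length(object@finalGenes) - 8L, "more\n")
})

#' Write a selection result as a TSV table
#'
#' Tab-separated columns gene_id, rank, pos_score, rdc, in_minimum_subset,
#' mask_ones; rows in final ranking order. Note the table has
#' max(r, |G*|) rows: when the minimum covering subset exceeds the requested
#' r it is written in full.
#'
#' @param result a \linkS4class{SelectionResult}.
#' @param path output path.
#' @export
writeSelection <- function(result, path) {
    tab <- result@table
    if (nrow(tab) == 0L) .valStop("empty selection: nothing to write")
    out <- data.frame(gene_id = tab$geneId, rank = tab$rank,
                      pos_score = tab$pos, rdc = tab$rdc,
                      in_minimum_subset = tab$inMinimumSubset,
                      mask_ones = tab$maskOnes)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(NULL)
}
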