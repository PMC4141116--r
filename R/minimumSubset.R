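#' Greedy minimum-covering gene subset
#'
#' Searches for the smallest gene set whose aggregate mask equals the
#' aggregate mask of all genes, i.e. that unambiguously classifies every
#' sample any gene can classify. Iteratively: (1) find the genes whose
#' current (updated) mask has the most 1 bits; (2) among those, pick the one
#' with the lowest POS score, breaking remaining ties by lowest gene index;
#' (3) add it to the subset; (4) clear, in every gene's mask, the bits of the
#' samples now covered. The loop stops when no 1 bits remain; every
#' iteration covers at least one new sample, so it terminates. 1-bit counts
#' are recomputed on the updated masks each iteration, which makes the
#' selection order a non-increasing sequence of counts.
#'
#' The greedy search carries the classical ln(N) + 1 approximation guarantee
#' of set cover; it is not guaranteed globally minimal.
#'
#' @param masks a \linkS4class{GeneMaskSet} or binary matrix, genes in rows.
#' @param scores a \linkS4class{GeneScoreTable} or numeric vector of POS
#'   scores over the same genes.
#' @param ... unused.
#' @return A \linkS4class{MinSubsetResult}.
#' @examples
#' m <- rbind(g1 = c(1, 1, 0, 0), g2 = c(0, 0, 1, 1), g3 = c(1, 1, 1, 0))
#' minimumSubset(m, c(g1 = 0.2, g2 = 0.3, g3 = 0.25))
#' @rdname minimumSubset
#' @export
setMethod("minimumSubset", c("ANY", "ANY"), function(masks, scores, ...) {
    m <- if (is(masks, "GeneMaskSet")) maskMatrix(masks) else {
        mm <- as.matrix(masks); storage.mode(mm) <- "integer"; mm
    }
    pos <- if (is(scores, "GeneScoreTable")) posScore(scores)
           else as.numeric(scores)
    if (length(pos) != nrow(m))
        .valStop("scores cover ", length(pos), " genes but masks have ",
                 nrow(m), " rows")
    cur <- m > 0L
    covered <- rep(FALSE, ncol(m))
    sel <- integer(0); selOnes <- integer(0)
    repeat {
        ones <- rowSums(cur)
        best <- max(ones)
        if (best == 0L) break
        cand <- which(ones == best)
        g <- cand[order(pos[cand], cand)][1L]
        sel <- c(sel, g)
        selOnes <- c(selOnes, as.integer(best))
        covered <- covered | cur[g, ]
        cur[, covered] <- FALSE
    }
    ids <- rownames(m)
    new("MinSubsetResult", genes = sel,
        geneIds = if (is.null(ids)) as.character(sel) else ids[sel],
        covered = stats::setNames(covered, colnames(m)),
        onesAtSelection = selOnes, iterations = length(sel))
})

setMethod("show", "MinSubsetResult", function(object) {
    cat("MinSubsetResult:", length(object@genes), "genes covering",
        sum(object@covered), "of", length(object@covered), "samples\n")
    if (length(object@genes))
        cat("selection order:", paste(utils::head(object@geneIds, 8L),
            collapse = ", "),
            if (length(object@genes) > 8L) "..." else "", "\n")
})

#' @rdname accessors
#' @export
setMethod("minSubset", "SelectionResult", function(x) x@minSubset)
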