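# Shared fixture builders. Everything is generated in code; no stored data.

# A fresh scratch directory that survives until the R session ends.
scratchDir <- function() {
    d <- tempfile("fixture")
    dir.create(d)
    d
}

# POSExperiment without the label-mapping message and with the small-class
# floor relaxed, for tiny hand-built fixtures.
quietPE <- function(exprs, labels, ...) {
    suppressMessages(POSExperiment(exprs, labels, minClassSize = 2L,
                                   verbose = FALSE, ...))
}

# One POSExperiment from per-gene value vectors: genes is a list of numeric
# vectors, all of length n1 + n2.
peFromGenes <- function(genes, n1, n2) {
    X <- do.call(rbind, genes)
    rownames(X) <- names(genes)
    if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_along(genes))
    colnames(X) <- paste0("s", seq_len(ncol(X)))
    quietPE(X, rep(c("1", "2"), c(n1, n2)))
}

# Random 0/1 mask matrix.
randomMasks <- function(P, N, p = 0.3) {
    matrix(as.integer(runif(P * N) < p), P, N,
           dimnames = list(paste0("g", seq_len(P)), paste0("s", seq_len(N))))
}

# Exact minimum set-cover size by exhaustive subset enumeration (N <= 16).
# Independent oracle for the greedy search: returns the size of the smallest
# gene subset whose aggregate mask equals the aggregate of all genes.
bruteMinCoverSize <- function(m) {
    P <- nrow(m)
    bits <- vapply(seq_len(P), function(i)
        sum(2L^(which(m[i, ] > 0L) - 1L)), numeric(1))
    target <- Reduce(bitwOr, as.integer(bits), 0L)
    if (target == 0L) return(0L)
    for (s in seq_len(P)) {
        for (comb in utils::combn(P, s, simplify = FALSE)) {
            if (Reduce(bitwOr, as.integer(bits[comb]), 0L) == target)
                return(s)
        }
    }
    P
}

# Hand-built single-gene geometry in the shape .geneGeometry returns, for
# unit-testing the score formula in isolation.
madeGeometry <- function(overlapLength, totalLength, overlapSet, nonoutlier,
                         hasOverlap = TRUE) {
    list(hasOverlap = hasOverlap, overlapLength = overlapLength,
         totalLength = totalLength, overlapSet = overlapSet,
         nonoutlier = nonoutlier)
}
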