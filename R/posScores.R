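#' Proportional overlapping scores and relative dominant classes
#'
#' The POS score of gene i multiplies three factors, each in [0, 1]:
#' \enumerate{
#'   \item the overlap-length factor, length of the overlap region over
#'     length of the total core interval;
#'   \item the overlapped-sample factor, |V_i| over the gene's sample
#'     universe (all N samples by default, the non-outlier count |S_i| with
#'     \code{sampleDenominator = "nonoutlier"});
#'   \item the class-proportion factor 4 theta_1 theta_2, where theta_c is
#'     the share of class-c samples among the overlapping samples. The
#'     multiplier 4 scales the factor to 1 at the balanced worst case
#'     theta_1 = theta_2 = 0.5, so POS lies in [0, 1].
#' }
#' Lower POS means a more discriminative gene. Genes with disjoint class
#' intervals, or with no sample inside the overlap region, score 0. A fully
#' degenerate gene (identical expression everywhere, total interval of zero
#' length) scores 1, the fully indistinguishable worst case.
#'
#' The relative dominant class (RDC) of a gene is the class with the larger
#' proportion, relative to its class size, of mask-covered samples. Exact
#' ties are distributed on both classes at random under \code{seed}: tied
#' genes, taken in ascending POS order, are assigned to the two classes
#' alternately starting from a seeded random class, so a single tied gene
#' lands in a random class, the tie pool stays balanced across classes, and
#' reruns with the same seed are bit-identical. Measuring relative to class
#' size keeps the assignment meaningful under unbalanced designs.
#'
#' @param x a \linkS4class{POSExperiment}.
#' @param intervals optional precomputed \linkS4class{CoreIntervalSet}.
#' @param masks optional precomputed \linkS4class{GeneMaskSet}.
#' @param seed integer seed for RDC tie randomisation.
#' @param sampleDenominator \code{"all"} (N, default) or \code{"nonoutlier"}
#'   (|S_i|) in the overlapped-sample factor.
#' @param quartileType,overlapOnNonoutlier used when \code{intervals} is not
#'   supplied; see \code{\link{coreIntervals}}.
#' @param ... unused.
#' @return A \linkS4class{GeneScoreTable}.
#' @examples
#' sim <- simulateExpression(nInformative = 2, nNoise = 3, seed = 1)
#' sc <- posScores(sim, seed = 1)
#' round(posScore(sc), 3)
#' @rdname posScores
#' @export
setMethod("posScores", "POSExperiment",
    function(x, intervals = NULL, masks = NULL, seed = 1L,
             sampleDenominator = c("all", "nonoutlier"), quartileType = 7L,
             overlapOnNonoutlier = FALSE, ...) {
    sampleDenominator <- match.arg(sampleDenominator)
    if (is.null(intervals))
        intervals <- coreIntervals(x, quartileType = quartileType,
                                   overlapOnNonoutlier = overlapOnNonoutlier)
    if (is.null(masks)) masks <- geneMasks(intervals)
    cls <- classLabels(x)
    N <- length(cls)
    ov <- intervals@overlapSet
    v1 <- rowSums(ov[, cls == 1L, drop = FALSE])
    v2 <- rowSums(ov[, cls == 2L, drop = FALSE])
    nV <- v1 + v2
    theta1 <- ifelse(nV > 0L, v1 / nV, NA_real_)
    denom <- switch(sampleDenominator,
                    all = N, nonoutlier = rowSums(intervals@nonoutlier))
    hasOverlap <- !is.na(intervals@overlapLow)
    degenerate <- intervals@totalLength <= 0
    if (any(degenerate))
        message(sum(degenerate), " gene(s) with zero-length total interval ",
                "assigned the worst score 1")
    lenFactor <- ifelse(degenerate, NA_real_,
                        intervals@overlapLength / intervals@totalLength)
    pos <- ifelse(degenerate, 1,
           ifelse(!hasOverlap | nV == 0L, 0,
                  lenFactor * (nV / denom) * 4 * theta1 * (1 - theta1)))
    m <- maskMatrix(masks)
    rdc <- .rdcAssign(m, cls, pos, seed)
    theta <- cbind(theta1 = theta1, theta2 = 1 - theta1)
    rownames(theta) <- rownames(m)
    vc <- cbind(v1 = v1, v2 = v2)
    rownames(vc) <- rownames(m)
    new("GeneScoreTable", geneIds = rownames(m), pos = as.numeric(pos),
        theta = theta, vCounts = vc, rdc = as.integer(rdc),
        seed = as.integer(seed), sampleDenominator = sampleDenominator)
})

#' @rdname accessors
#' @export
setMethod("posScore", "GeneScoreTable", function(x)
    stats::setNames(x@pos, x@geneIds))

#' @rdname accessors
#' @export
setMethod("relativeDominantClass", "GeneScoreTable", function(x)
    stats::setNames(x@rdc, x@geneIds))

setMethod("show", "GeneScoreTable", function(object) {
    cat("GeneScoreTable:", length(object@pos), "genes\n")
    cat(sprintf("POS range [%.4g, %.4g]; RDC split %d / %d; seed %d\n",
                min(object@pos), max(object@pos), sum(object@rdc == 1L),
                sum(object@rdc == 2L), object@seed))
})

#' Score table as a data.frame / write it to TSV
#'
#' @param x a \linkS4class{GeneScoreTable}.
#' @param path output path for \code{writeScores}.
#' @return \code{scoresAsFrame}: a data.frame with columns gene_id, pos,
#'   theta1, theta2, rdc.
#' @export
scoresAsFrame <- function(x) {
    data.frame(gene_id = x@geneIds, pos = x@pos,
               theta1 = x@theta[, 1L], theta2 = x@theta[, 2L],
               rdc = x@rdc, row.names = NULL)
}

#' @rdname scoresAsFrame
#' @export
writeScores <- function(x, path) {
    utils::write.table(scoresAsFrame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(NULL)
}

# Relative dominant class per gene: argmax over c of the class-size-relative
# proportion of mask-covered samples. Exact ties are distributed on both
# classes: tied genes sorted by ascending POS (then index) are assigned
# alternately, starting from a seeded random class, so a lone tie lands in a
# random class and the tie pool stays balanced.
.rdcAssign <- function(m, cls, pos, seed) {
    p1 <- rowSums(m[, cls == 1L, drop = FALSE]) / sum(cls == 1L)
    p2 <- rowSums(m[, cls == 2L, drop = FALSE]) / sum(cls == 2L)
    rdc <- ifelse(p1 > p2, 1L, ifelse(p2 > p1, 2L, NA_integer_))
    ties <- which(is.na(rdc))
    if (length(ties)) {
        ord <- ties[order(pos[ties], ties)]
        start <- .withSeed(seed, sample(c(1L, 2L), 1L))
        rdc[ord] <- rep_len(c(start, 3L - start), length(ord))
    }
    as.integer(rdc)
}

#' POS score of a single gene from raw class values
#'
#' Convenience entry point that scores one gene given its expression values
#' in each class, without building any container. Used heavily by the
#' enumeration checks; handy for interactive exploration.
#'
#' @param class1,class2 numeric expression values (at least 2 each).
#' @param quartileType quantile rule (default 7).
#' @param sampleDenominator see \code{\link{posScores}}.
#' @return A list with elements \code{pos}, \code{theta} (length 2),
#'   \code{v} (per-class overlapping sample counts), \code{overlapLength} and
#'   \code{totalLength}.
#' @examples
#' posScoreValues(c(1, 2, 3), c(10, 11, 12))$pos   # disjoint: 0
#' posScoreValues(1:6, 1:6)$pos                    # identical classes: 1
#' @export
posScoreValues <- function(class1, class2, quartileType = 7L,
                           sampleDenominator = c("all", "nonoutlier")) {
    cls <- rep(c(1L, 2L), c(length(class1), length(class2)))
    geom <- .geneGeometry(c(class1, class2), cls, quartileType)
    res <- .posFromGeometry(geom, cls, match.arg(sampleDenominator))
    res$overlapLength <- geom$overlapLength
    res$totalLength <- geom$totalLength
    res
}
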