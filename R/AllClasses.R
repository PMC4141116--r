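#' @import methods
#' @importFrom stats quantile
NULL

#' POSExperiment: two-class expression data container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a genes x
#' samples expression matrix (assay \code{"exprs"}) together with a binary
#' class label per sample. Class labels are stored in \code{colData} both as
#' the original strings (\code{label}) and as integer codes in \{1, 2\}
#' (\code{class}), assigned by first occurrence. All selection machinery in
#' this package consumes a \code{POSExperiment}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{POSExperiment}}, \code{\link{readPOSExperiment}}
#' @export
setClass("POSExperiment", contains = "SummarizedExperiment")

setValidity("POSExperiment", function(object) {
    msg <- character(0)
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        X <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(X))
            msg <- c(msg, "assay 'exprs' must be numeric")
        else if (anyNA(X))
            msg <- c(msg, "assay 'exprs' must not contain missing values")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("label", "class") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'label' and 'class' columns")
    } else {
        cls <- cd$class
        if (!all(cls %in% c(1L, 2L)))
            msg <- c(msg, "sample classes must be coded 1 or 2")
        else if (any(tabulate(cls, 2L) < 2L))
            msg <- c(msg, "each class needs at least two samples")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
})

#' CoreIntervalSet: per-gene, per-class robust expression intervals
#'
#' Holds, for every gene, the two class core intervals (quartile-based,
#' outlier-fenced) plus all derived overlap geometry: the total core interval,
#' the overlap region (intersection of the two class intervals), and the
#' per-sample membership sets (non-outlier, overlapping, non-overlapping).
#'
#' Interval matrices are P x 2 (columns = class 1, class 2); membership
#' matrices are P x N logical.
#'
#' @slot lower,upper P x 2 matrices of core-interval bounds a_(i,c), b_(i,c).
#' @slot q1,q3,iqr P x 2 matrices of empirical quartiles and the IQR.
#' @slot totalLow,totalHigh bounds of the total core interval per gene.
#' @slot overlapLow,overlapHigh bounds of the overlap region (NA when the
#'   class intervals are disjoint).
#' @slot overlapLength,totalLength interval lengths per gene (overlap length
#'   is 0 when there is no overlap).
#' @slot nonoutlier,overlapSet,nonoverlap P x N logical membership matrices
#'   for the non-outlier set S_i, the overlapping set V_i and the
#'   non-overlapping set S_i \\ V_i.
#' @slot quartileType the \code{stats::quantile} type used.
#' @slot overlapOnNonoutlier whether V_i was restricted to non-outlier samples.
#' @export
setClass("CoreIntervalSet", representation(
    lower = "matrix", upper = "matrix",
    q1 = "matrix", q3 = "matrix", iqr = "matrix",
    totalLow = "numeric", totalHigh = "numeric",
    overlapLow = "numeric", overlapHigh = "numeric",
    overlapLength = "numeric", totalLength = "numeric",
    nonoutlier = "matrix", overlapSet = "matrix", nonoverlap = "matrix",
    quartileType = "integer", overlapOnNonoutlier = "logical"))

setValidity("CoreIntervalSet", function(object) {
    msg <- character(0)
    if (any(object@lower > object@upper))
        msg <- c(msg, "interval lower bounds must not exceed upper bounds")
    if (any(object@iqr < 0))
        msg <- c(msg, "IQR must be non-negative")
    if (any(object@totalLength < object@overlapLength))
        msg <- c(msg, "total length must be >= overlap length")
    if (any(object@overlapLength < 0))
        msg <- c(msg, "overlap length must be non-negative")
    if (any(object@nonoverlap & !object@nonoutlier))
        msg <- c(msg, "non-overlap set must be a subset of the non-outlier set")
    if (any(object@nonoverlap & object@overlapSet))
        msg <- c(msg, "non-overlap and overlap sets must be disjoint")
    if (length(msg)) msg else TRUE
})

#' GeneMaskSet: binary gene masks
#'
#' A P x N binary matrix M with m_ij = 1 iff gene i unambiguously assigns
#' sample j to its correct class: x_ij lies inside the core interval of its
#' own class only (sample j belongs to the non-overlapping set of gene i).
#'
#' @slot masks integer 0/1 matrix, genes in rows.
#' @slot onesCount per-gene number of 1 bits, |S_i \\ V_i|.
#' @export
setClass("GeneMaskSet", representation(
    masks = "matrix", onesCount = "integer"))

setValidity("GeneMaskSet", function(object) {
    if (!all(object@masks %in% c(0L, 1L)))
        return("masks must be binary")
    if (!identical(object@onesCount, as.integer(rowSums(object@masks))))
        return("onesCount must equal the per-gene row sums of the masks")
    TRUE
})

#' GeneScoreTable: POS scores and relative dominant classes
#'
#' Per-gene proportional overlapping score (in [0, 1], lower = more
#' discriminative), the class-proportion factors theta_1, theta_2 among
#' overlapping samples, per-class overlapping sample counts, and the relative
#' dominant class (RDC) assignment. Ties in the RDC proportions are broken at
#' random using the recorded seed, so a rerun with the same seed is
#' bit-identical.
#'
#' @slot geneIds gene identifiers.
#' @slot pos POS score per gene.
#' @slot theta P x 2 matrix of class proportions among overlapping samples
#'   (NA when a gene has no overlapping samples).
#' @slot vCounts P x 2 matrix of per-class overlapping sample counts |V_(i,c)|.
#' @slot rdc relative dominant class per gene, 1 or 2.
#' @slot seed seed used for tie randomisation.
#' @slot sampleDenominator denominator of the overlapped-sample factor
#'   ("all" = N, "nonoutlier" = |S_i|).
#' @export
setClass("GeneScoreTable", representation(
    geneIds = "character", pos = "numeric", theta = "matrix",
    vCounts = "matrix", rdc = "integer", seed = "integer",
    sampleDenominator = "character"))

setValidity("GeneScoreTable", function(object) {
    msg <- character(0)
    if (any(object@pos < 0 | object@pos > 1))
        msg <- c(msg, "POS scores must lie in [0, 1]")
    if (!all(object@rdc %in% c(1L, 2L)))
        msg <- c(msg, "RDC must be 1 or 2")
    ok <- !is.na(object@theta[, 1L])
    if (any(abs(rowSums(object@theta[ok, , drop = FALSE]) - 1) > 1e-12))
        msg <- c(msg, "theta_1 + theta_2 must equal 1 where defined")
    if (length(msg)) msg else TRUE
})

#' MinSubsetResult: greedy minimum-covering gene subset
#'
#' Output of the greedy search for the smallest gene set whose aggregate mask
#' (bitwise OR) equals the aggregate mask of all genes. Genes are stored in
#' selection order, which is also descending order of 1 bits counted on the
#' updated masks at each selection step.
#'
#' @slot genes gene indices in selection order.
#' @slot geneIds corresponding gene identifiers.
#' @slot covered the achieved aggregate mask (logical, one entry per sample).
#' @slot onesAtSelection 1-bit count of each selected gene at its step.
#' @slot iterations number of greedy iterations performed.
#' @export
setClass("MinSubsetResult", representation(
    genes = "integer", geneIds = "character", covered = "logical",
    onesAtSelection = "integer", iterations = "integer"))

#' SelectionResult: final ranked gene selection
#'
#' The minimum covering subset first (in selection order, regardless of POS),
#' followed by the round-robin interleave of the two RDC groups, each sorted
#' by ascending POS, up to the requested total of r genes. When the minimum
#' subset alone exceeds r the whole subset is returned (unless truncation was
#' requested), so the length is max(r, |G*|).
#'
#' @slot finalGenes ordered gene ids of the final selection.
#' @slot table per-gene annotation table (\code{S4Vectors::DataFrame}) with
#'   columns geneId, rank, pos, rdc, inMinimumSubset, maskOnes, source.
#' @slot minSubset the \linkS4class{MinSubsetResult}.
#' @slot scores the full \linkS4class{GeneScoreTable}.
#' @slot r the requested number of genes.
#' @slot seed tie-randomisation seed.
#' @slot parameters run parameters (quartile type, denominators, flags,
#'   label mapping) echoed for reproducibility.
#' @export
setClass("SelectionResult", representation(
    finalGenes = "character", table = "DataFrame",
    minSubset = "MinSubsetResult", scores = "GeneScoreTable",
    r = "integer", seed = "integer", parameters = "list"))

#' StabilityAssessment: selection stability across subsamples
#'
#' Fixed-size gene selections collected from lambda training subsamples plus
#' their stability index, a number in [1/lambda, 1]: 1 when all selections are
#' identical, 1/lambda when they are pairwise disjoint.
#'
#' @slot selections list of lambda gene-id vectors, all of size k.
#' @slot k selection size.
#' @slot lambda number of subsamples.
#' @slot score the stability index.
#' @slot method "frequency" (selection-frequency form) or "jaccard"
#'   (pairwise-Jaccard form).
#' @export
setClass("StabilityAssessment", representation(
    selections = "list", k = "integer", lambda = "integer",
    score = "numeric", method = "character"))
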