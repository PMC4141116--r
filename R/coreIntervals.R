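#' Per-gene, per-class robust core expression intervals
#'
#' For every gene, the core interval of class c is built from the empirical
#' quartiles of the class-c expressions: [max(Q1 - 1.5 IQR, min), min(Q3 +
#' 1.5 IQR, max)], i.e. Tukey fences clipped to the observed class range.
#' Clipping keeps interval lengths on the scale of the data; an interval
#' extending beyond every observation could never change a membership set but
#' would distort the overlap-length factor of the POS score. From the two
#' class intervals the method derives, per gene:
#' \itemize{
#'   \item the total core interval (union span of the two class intervals),
#'   \item the overlap region (their intersection, possibly empty),
#'   \item the non-outlier sample set S_i (samples inside their own class's
#'     interval),
#'   \item the overlapping sample set V_i (samples inside the overlap
#'     region; membership is tested on the closed interval), and
#'   \item the non-overlapping set S_i \\ V_i, which becomes the gene mask.
#' }
#' Because the overlap region is the intersection of the two class intervals,
#' every sample in it automatically lies inside its own class interval, so
#' V_i is a subset of S_i whichever way \code{overlapOnNonoutlier} is set;
#' the flag is kept for explicitness.
#'
#' @param x a \linkS4class{POSExperiment}.
#' @param quartileType quantile interpolation rule, passed to
#'   \code{stats::quantile} (default 7, linear interpolation of order
#'   statistics). Recorded in the result because POS values depend on it.
#' @param overlapOnNonoutlier if TRUE, restrict V_i to non-outlier samples
#'   (equivalent to the default by construction; see above).
#' @param ... unused.
#' @return A \linkS4class{CoreIntervalSet}.
#' @examples
#' sim <- simulateExpression(nInformative = 2, nNoise = 2, seed = 1)
#' ci <- coreIntervals(sim)
#' ci
#' @rdname coreIntervals
#' @export
setMethod("coreIntervals", "POSExperiment",
    function(x, quartileType = 7L, overlapOnNonoutlier = FALSE, ...) {
    X <- expressionMatrix(x)
    cls <- classLabels(x)
    P <- nrow(X); N <- ncol(X)
    stats1 <- t(vapply(seq_len(P), function(i)
        .classInterval(X[i, cls == 1L], quartileType), numeric(5L)))
    stats2 <- t(vapply(seq_len(P), function(i)
        .classInterval(X[i, cls == 2L], quartileType), numeric(5L)))
    lower <- cbind(stats1[, "low"], stats2[, "low"])
    upper <- cbind(stats1[, "high"], stats2[, "high"])
    dimnames(lower) <- dimnames(upper) <- list(rownames(X), c("1", "2"))
    ovLow <- pmax(lower[, 1L], lower[, 2L])
    ovHigh <- pmin(upper[, 1L], upper[, 2L])
    hasOverlap <- ovLow <= ovHigh
    # P-vectors recycle down the columns of a P x N matrix, i.e. per gene
    nonoutlier <- X >= lower[, cls] & X <= upper[, cls]
    overlapSet <- hasOverlap & X >= ovLow & X <= ovHigh
    if (overlapOnNonoutlier) overlapSet <- overlapSet & nonoutlier
    obj <- new("CoreIntervalSet",
        lower = lower, upper = upper,
        q1 = cbind(stats1[, "q1"], stats2[, "q1"]),
        q3 = cbind(stats1[, "q3"], stats2[, "q3"]),
        iqr = cbind(stats1[, "iqr"], stats2[, "iqr"]),
        totalLow = pmin(lower[, 1L], lower[, 2L]),
        totalHigh = pmax(upper[, 1L], upper[, 2L]),
        overlapLow = ifelse(hasOverlap, ovLow, NA_real_),
        overlapHigh = ifelse(hasOverlap, ovHigh, NA_real_),
        overlapLength = ifelse(hasOverlap, ovHigh - ovLow, 0),
        totalLength = pmax(upper[, 1L], upper[, 2L]) -
            pmin(lower[, 1L], lower[, 2L]),
        nonoutlier = nonoutlier, overlapSet = overlapSet,
        nonoverlap = nonoutlier & !overlapSet,
        quartileType = as.integer(quartileType),
        overlapOnNonoutlier = overlapOnNonoutlier)
    validObject(obj)
    obj
})

setMethod("show", "CoreIntervalSet", function(object) {
    P <- nrow(object@lower)
    cat("CoreIntervalSet:", P, "genes x", ncol(object@nonoutlier),
        "samples (quartile type", paste0(object@quartileType, ")\n"))
    cat(sprintf("overlapping class intervals: %d/%d genes\n",
                sum(!is.na(object@overlapLow)), P))
})
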