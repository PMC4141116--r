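#' Simulate two-class expression data with known ground truth
#'
#' Generates a genes x samples matrix emulating the structures the selection
#' method reasons about, with per-gene ground-truth labels in
#' \code{rowData(x)$truth}:
#' \itemize{
#'   \item \strong{informative} genes: class means separated by
#'     \code{classShift} within-class spread units, large enough by default
#'     for the two class core intervals to be disjoint;
#'   \item \strong{partial} genes: class shift calibrated so that an expected
#'     fraction \code{overlapFraction} of the samples falls inside the
#'     overlap region of the two core intervals;
#'   \item \strong{scale} genes: equal class means but the class-2 spread
#'     inflated by \code{scaleRatio} — analysable through interval overlap
#'     yet invisible to a rank-sum location test;
#'   \item \strong{noise} genes: identically distributed classes.
#' }
#' Outliers are injected per gene: with probability \code{outlierRate} a gene
#' receives a single outlier — one randomly chosen sample shifted
#' \code{outlierMagnitude} spread units up or down. The base distribution is
#' standard normal per class; \code{heavyTails = TRUE} switches to a scaled
#' t(3) to stress the interval fences. Output is bit-identical for a fixed
#' seed.
#'
#' The partial-gene calibration works from the expected upper core-interval
#' bound of a standard normal class of size n, approximately
#' min(Q3 + 1.5 IQR, E max) = min(2.70, qnorm((n - 0.375) / (n + 0.25))),
#' and solves the single-gene overlap-fraction equation for the class shift.
#'
#' @param nPerClass integer pair, samples per class (default c(18, 18)).
#' @param nInformative,nPartial,nScale,nNoise gene counts per type.
#' @param classShift mean separation of informative genes in within-class
#'   standard deviation units (default 6).
#' @param overlapFraction target fraction of samples inside the overlap
#'   region for partial genes (default 0.5).
#' @param scaleRatio class-2 spread multiplier for scale genes (default 5).
#' @param outlierRate per-gene probability of a single injected outlier
#'   (default 0).
#' @param outlierMagnitude outlier offset in spread units (default 6).
#' @param heavyTails use a scaled t(3) base distribution (default FALSE).
#' @param seed integer seed.
#' @return A \linkS4class{POSExperiment} with gene types in
#'   \code{rowData(x)$truth} and the generator settings in
#'   \code{metadata(x)$simulation}.
#' @examples
#' sim <- simulateExpression(nInformative = 5, nNoise = 45, seed = 7)
#' table(SummarizedExperiment::rowData(sim)$truth)
#' @importFrom stats rnorm rt runif qnorm pnorm
#' @export
simulateExpression <- function(nPerClass = c(18L, 18L), nInformative = 5L,
                               nPartial = 0L, nScale = 0L, nNoise = 45L,
                               classShift = 6, overlapFraction = 0.5,
                               scaleRatio = 5, outlierRate = 0,
                               outlierMagnitude = 6, heavyTails = FALSE,
                               seed = 1L) {
    stopifnot(length(nPerClass) == 2L, all(nPerClass >= 2L),
              nInformative >= 0L, nPartial >= 0L, nScale >= 0L, nNoise >= 0L,
              outlierRate >= 0, outlierRate <= 1,
              overlapFraction >= 0, overlapFraction <= 1)
    n1 <- nPerClass[1L]; n2 <- nPerClass[2L]; N <- n1 + n2
    cls <- rep(c(1L, 2L), c(n1, n2))
    types <- rep(c("informative", "partial", "scale", "noise"),
                 c(nInformative, nPartial, nScale, nNoise))
    P <- length(types)
    if (P < 1L) .valStop("at least one gene must be requested")
    rbase <- if (heavyTails) function(n) rt(n, df = 3) / sqrt(3) else rnorm
    .withSeed(seed, {
        X <- matrix(rbase(P * N), nrow = P)
        partialShift <- .partialShift(overlapFraction, min(n1, n2))
        is2 <- cls == 2L
        X[types == "informative", is2] <-
            X[types == "informative", is2] + classShift
        X[types == "partial", is2] <- X[types == "partial", is2] + partialShift
        X[types == "scale", is2] <- X[types == "scale", is2] * scaleRatio
        if (outlierRate > 0) {
            for (g in which(runif(P) < outlierRate)) {
                j <- sample.int(N, 1L)
                X[g, j] <- X[g, j] + sample(c(-1, 1), 1L) * outlierMagnitude
            }
        }
        rownames(X) <- sprintf("g%03d_%s", seq_len(P), types)
        colnames(X) <- sprintf("s%02d_c%d", seq_len(N), cls)
        pe <- POSExperiment(X, as.character(cls), minClassSize = 2L,
                            verbose = FALSE)
        SummarizedExperiment::rowData(pe)$truth <-
            factor(types, levels = c("informative", "partial", "scale",
                                     "noise"))
        metadata(pe)$simulation <- list(
            nPerClass = c(n1, n2), nInformative = nInformative,
            nPartial = nPartial, nScale = nScale, nNoise = nNoise,
            classShift = classShift, overlapFraction = overlapFraction,
            scaleRatio = scaleRatio, outlierRate = outlierRate,
            outlierMagnitude = outlierMagnitude, heavyTails = heavyTails,
            seed = seed, partialShift = partialShift)
        pe
    })
}

# Class shift delta giving an expected in-overlap sample fraction f for two
# standard normal classes of size n: the class core interval is roughly
# [mu - a, mu + a] with a = min(2.70, Blom estimate of E max), the overlap
# region [delta - a, a], and the per-class in-overlap fraction
# Phi(a) - Phi(delta - a).
.partialShift <- function(f, n) {
    a <- min(2.70, qnorm((n - 0.375) / (n + 0.25)))
    target <- max(min(pnorm(a) - f, 1 - 1e-9), 1e-9)
    a + qnorm(target)
}
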