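#' Exhaustive POS sweep over small two-class configurations
#'
#' Enumerates every pair of expression-value multisets drawn from a small
#' integer grid (one multiset per class, class sizes from \code{sizes}) and
#' scores each configuration with \code{\link{posScoreValues}}. Order within
#' a class does not affect any interval or score, so multisets cover the
#' configuration space exhaustively. Used to verify the score's [0, 1]
#' bounds and its boundary cases by brute force; with the defaults the sweep
#' covers 6400 configurations of up to 12 samples.
#'
#' @param grid integer expression values to draw from (default 0:2).
#' @param sizes class sizes to enumerate (default 2:6).
#' @param quartileType,sampleDenominator see \code{\link{posScoreValues}}.
#' @return data.frame with one row per configuration: pos, n1, n2, nOverlap
#'   (|V|), overlapLength, totalLength, and identicalEqual (TRUE when both
#'   classes hold the same multiset and have equal size).
#' @examples
#' sweep <- posScoreSweep(grid = 0:1, sizes = 2:3)
#' range(sweep$pos)
#' @export
posScoreSweep <- function(grid = 0:2, sizes = 2:6, quartileType = 7L,
                          sampleDenominator = "all") {
    msets <- lapply(sizes, function(n) {
        tup <- as.matrix(expand.grid(rep(list(as.numeric(grid)), n)))
        unique(t(apply(tup, 1L, sort)))
    })
    total <- sum(outer(vapply(msets, nrow, 0L), vapply(msets, nrow, 0L)))
    pos <- nOv <- ovLen <- totLen <- numeric(total)
    n1 <- n2 <- integer(total)
    idEq <- logical(total)
    k <- 0L
    for (a in seq_along(sizes)) for (b in seq_along(sizes)) {
        A <- msets[[a]]; B <- msets[[b]]
        for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
            k <- k + 1L
            r <- posScoreValues(A[i, ], B[j, ], quartileType,
                                sampleDenominator)
            pos[k] <- r$pos; nOv[k] <- sum(r$v)
            ovLen[k] <- r$overlapLength; totLen[k] <- r$totalLength
            n1[k] <- sizes[a]; n2[k] <- sizes[b]
            idEq[k] <- sizes[a] == sizes[b] && all(A[i, ] == B[j, ])
        }
    }
    data.frame(pos = pos, n1 = n1, n2 = n2, nOverlap = nOv,
               overlapLength = ovLen, totalLength = totLen,
               identicalEqual = idEq)
}
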