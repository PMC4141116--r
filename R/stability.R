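#' Selection-stability index over subsamples
#'
#' Measures agreement of fixed-size feature selections collected from lambda
#' subsamples of a dataset. The default frequency form is
#' sum_f count_f^2 / (lambda^2 k), where count_f is the number of subsamples
#' selecting feature f. It equals 1 iff all lambda selections are identical
#' and 1/lambda iff they are pairwise disjoint. The alternative
#' \code{method = "jaccard"} averages pairwise Jaccard agreement,
#' (lambda + sum_\{i != j\} |A_i intersect A_j| / |A_i union A_j|) / lambda^2,
#' which attains the same two boundary values.
#'
#' @param selections list of lambda (>= 2) gene-id vectors, all of the same
#'   size k >= 1 (duplicates within a selection are not allowed).
#' @param method \code{"frequency"} (default) or \code{"jaccard"}.
#' @return The stability score, a number in [1/lambda, 1].
#' @examples
#' stabilityScore(rep(list(c("a", "b", "c")), 4))          # 1
#' stabilityScore(list(c("a", "b"), c("c", "d")))          # 1/2
#' stabilityScore(list(c("a", "b"), c("a", "c")))          # 0.75
#' @export
stabilityScore <- function(selections, method = c("frequency", "jaccard")) {
    method <- match.arg(method)
    lambda <- length(selections)
    if (lambda < 2L) .valStop("need at least 2 selections, got ", lambda)
    k <- unique(lengths(selections))
    if (length(k) != 1L)
        .valStop("all selections must have the same size; sizes seen: ",
                 paste(sort(k), collapse = ", "))
    if (k < 1L) .valStop("selections must be nonempty")
    if (any(vapply(selections, anyDuplicated, 0L) > 0L))
        .valStop("selections must not contain duplicated features")
    if (method == "frequency") {
        counts <- table(unlist(selections))
        return(sum(as.numeric(counts)^2) / (lambda^2 * k))
    }
    tot <- 0
    for (i in seq_len(lambda - 1L)) for (j in (i + 1L):lambda) {
        int <- length(intersect(selections[[i]], selections[[j]]))
        tot <- tot + int / (2L * k - int)
    }
    (lambda + 2 * tot) / lambda^2
}

#' Selection stability under repeated cross-validation subsampling
#'
#' Mirrors the repeated stratified cross-validation protocol used to judge
#' selector stability: for each repeat, samples are split into stratified
#' folds (the split is reseeded per repeat); the full POS selection is run on
#' each training portion (all folds but one) and its top k genes are
#' collected. The lambda = folds x repeats selections are then scored with
#' \code{\link{stabilityScore}}.
#'
#' @param x a \linkS4class{POSExperiment}.
#' @param k number of genes to keep from each subsample's selection.
#' @param folds number of cross-validation folds (>= 2; every class must
#'   have at least \code{folds} samples).
#' @param repeats number of repetitions of the fold split.
#' @param seed master seed; per-repeat and per-fold sub-seeds are derived
#'   from it.
#' @param method stability formula, see \code{\link{stabilityScore}}.
#' @param ... passed to \code{\link{selectGenes}}.
#' @return A \linkS4class{StabilityAssessment}.
#' @examples
#' sim <- simulateExpression(nPerClass = c(12, 12), nInformative = 2,
#'                           nNoise = 10, seed = 1)
#' subsampleStability(sim, k = 2, folds = 3, repeats = 2, seed = 1)
#' @export
subsampleStability <- function(x, k, folds = 10L, repeats = 50L, seed = 1L,
                               method = c("frequency", "jaccard"), ...) {
    method <- match.arg(method)
    folds <- as.integer(folds); repeats <- as.integer(repeats)
    if (folds < 2L) .valStop("folds must be >= 2")
    cls <- classLabels(x)
    if (any(tabulate(cls, 2L) < folds))
        .valStop("every class needs at least `folds` samples (folds = ",
                 folds, ", class sizes ", tabulate(cls, 2L)[1L], "/",
                 tabulate(cls, 2L)[2L], ")")
    seeds <- .subSeeds(seed, repeats * (folds + 1L))
    selections <- vector("list", folds * repeats)
    s <- 0L
    for (rep in seq_len(repeats)) {
        foldId <- .stratifiedFolds(cls, folds, seeds[(rep - 1L) *
                                                     (folds + 1L) + 1L])
        for (f in seq_len(folds)) {
            s <- s + 1L
            runSeed <- seeds[(rep - 1L) * (folds + 1L) + 1L + f]
            res <- selectGenes(x[, foldId != f], r = k, seed = runSeed,
                               strictR = TRUE, ...)
            selections[[s]] <- finalGenes(res)
        }
    }
    new("StabilityAssessment", selections = selections, k = as.integer(k),
        lambda = length(selections),
        score = stabilityScore(selections, method), method = method)
}

# Stratified fold labels: within each class, fold ids 1..folds are dealt out
# as evenly as possible in a random order.
.stratifiedFolds <- function(cls, folds, seed) {
    .withSeed(seed, {
        foldId <- integer(length(cls))
        for (c in 1:2) {
            idx <- which(cls == c)
            foldId[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
        foldId
    })
}

#' @rdname accessors
#' @export
setMethod("stabilityValue", "StabilityAssessment", function(x) x@score)

setMethod("show", "StabilityAssessment", function(object) {
    cat(sprintf(
        "StabilityAssessment: k = %d, lambda = %d, %s score = %.4f\n",
        object@k, object@lambda, object@method, object@score))
})

#' Write a stability report as TSV
#'
#' One row with columns k, lambda, score.
#'
#' @param assessment a \linkS4class{StabilityAssessment}.
#' @param path output path.
#' @export
writeStability <- function(assessment, path) {
    utils::write.table(
        data.frame(k = assessment@k, lambda = assessment@lambda,
                   score = assessment@score),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}
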