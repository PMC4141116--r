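#' Wilcoxon rank-sum baseline gene ranking
#'
#' Ranks genes by the two-sample Wilcoxon rank-sum test p-value (ascending;
#' ties broken by gene index). A standard univariate location-shift filter,
#' included as the comparison baseline for the overlap-based selection.
#'
#' @param x a \linkS4class{POSExperiment}.
#' @param exact passed to \code{stats::wilcox.test} (default FALSE: normal
#'   approximation, fast and adequate for ranking).
#' @return data.frame with columns gene_id, statistic, p, ordered by
#'   increasing p.
#' @examples
#' sim <- simulateExpression(nInformative = 2, nNoise = 5, seed = 1)
#' head(wilcoxonRank(sim), 3)
#' @importFrom stats wilcox.test
#' @export
wilcoxonRank <- function(x, exact = FALSE) {
    X <- expressionMatrix(x)
    cls <- classLabels(x)
    res <- vapply(seq_len(nrow(X)), function(i) {
        w <- suppressWarnings(wilcox.test(X[i, cls == 1L], X[i, cls == 2L],
                                          exact = exact))
        c(w$statistic, w$p.value)
    }, numeric(2L))
    ord <- order(res[2L, ], seq_len(nrow(X)))
    data.frame(gene_id = rownames(X)[ord], statistic = res[1L, ord],
               p = res[2L, ord], row.names = NULL)
}

#' Cross-validated error-rate benchmark of selectors
#'
#' Repeated stratified cross-validation comparing the POS selection against
#' the Wilcoxon rank-sum baseline over a range of selected-set sizes. Gene
#' selection runs on the training folds only; the classifier is then trained
#' on the selected genes and its error measured on the held-out fold, so no
#' test information leaks into the selection. Classifiers are evaluation
#' plumbing invoked with their conventional defaults: random forest with 500
#' trees; kNN with k = sqrt(n) rounded to the nearest odd number; SVM with
#' package defaults.
#'
#' @param x a \linkS4class{POSExperiment}.
#' @param sizes selected-set sizes to evaluate (default 1:10).
#' @param folds,repeats cross-validation layout (default 5 x 5).
#' @param classifier \code{"knn"} (default), \code{"rf"} or \code{"svm"};
#'   requires the class, randomForest or e1071 package respectively.
#' @param methods selectors to compare, subset of c("pos", "wilcoxon").
#' @param seed master seed for fold splits and selection tie-breaking.
#' @param ... passed to \code{\link{selectGenes}}.
#' @return data.frame with columns method, size, error (mean test error over
#'   all folds and repeats); per-fold errors in \code{attr(, "folds")}.
#' @examples
#' \donttest{
#' sim <- simulateExpression(nPerClass = c(15, 15), nInformative = 3,
#'                           nNoise = 30, seed = 1)
#' benchmarkSelection(sim, sizes = c(1, 3), folds = 3, repeats = 1, seed = 1)
#' }
#' @export
benchmarkSelection <- function(x, sizes = 1:10, folds = 5L, repeats = 5L,
                               classifier = c("knn", "rf", "svm"),
                               methods = c("pos", "wilcoxon"), seed = 1L,
                               ...) {
    classifier <- match.arg(classifier)
    methods <- match.arg(methods, several.ok = TRUE)
    pkg <- switch(classifier, knn = "class", rf = "randomForest",
                  svm = "e1071")
    if (!requireNamespace(pkg, quietly = TRUE))
        .valStop("classifier '", classifier, "' needs the '", pkg,
                 "' package; install it or pick another classifier")
    cls <- classLabels(x)
    if (any(tabulate(cls, 2L) < folds))
        .valStop("every class needs at least `folds` samples (folds = ",
                 folds, ")")
    sizes <- sort(unique(as.integer(sizes)))
    if (max(sizes) > nrow(x))
        .valStop("largest size ", max(sizes), " exceeds gene count ", nrow(x))
    X <- expressionMatrix(x)
    seeds <- .subSeeds(seed, repeats * (folds + 1L))
    rows <- list()
    for (rep in seq_len(repeats)) {
        foldId <- .stratifiedFolds(cls, folds,
                                   seeds[(rep - 1L) * (folds + 1L) + 1L])
        for (f in seq_len(folds)) {
            runSeed <- seeds[(rep - 1L) * (folds + 1L) + 1L + f]
            train <- foldId != f
            ranked <- list()
            if ("pos" %in% methods)
                ranked$pos <- finalGenes(selectGenes(
                    x[, train], r = max(sizes), seed = runSeed,
                    strictR = TRUE, ...))
            if ("wilcoxon" %in% methods)
                ranked$wilcoxon <- wilcoxonRank(x[, train])$gene_id
            for (m in names(ranked)) for (s in sizes) {
                feats <- utils::head(ranked[[m]], s)
                err <- .cvError(X, cls, feats, train, classifier, runSeed)
                rows[[length(rows) + 1L]] <- data.frame(
                    repeatId = rep, fold = f, method = m, size = s,
                    error = err)
            }
        }
    }
    perFold <- do.call(rbind, rows)
    out <- stats::aggregate(error ~ method + size, perFold, mean)
    out <- out[order(out$method, out$size), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "folds") <- perFold
    attr(out, "classifier") <- classifier
    out
}

.cvError <- function(X, cls, feats, train, classifier, seed) {
    tr <- t(X[feats, train, drop = FALSE])
    te <- t(X[feats, !train, drop = FALSE])
    ytr <- factor(cls[train], levels = 1:2)
    yte <- cls[!train]
    pred <- .withSeed(seed, switch(classifier,
        knn = {
            k <- max(1L, 2L * as.integer(round((sqrt(nrow(tr)) - 1) / 2)) + 1L)
            as.integer(as.character(class::knn(tr, te, ytr, k = k)))
        },
        rf = as.integer(as.character(stats::predict(
            randomForest::randomForest(tr, ytr, ntree = 500), te))),
        svm = as.integer(as.character(stats::predict(
            e1071::svm(tr, ytr), te)))))
    mean(pred != yte)
}

#' Log error-rate improvement of POS over the baseline
#'
#' Per set size, log(error_baseline / error_pos) from a
#' \code{\link{benchmarkSelection}} result; positive values indicate an
#' improvement of the POS selection over the baseline. A small floor guards
#' zero error rates.
#'
#' @param bench result of \code{\link{benchmarkSelection}} containing both
#'   methods.
#' @param floor lower bound applied to error rates before the ratio
#'   (default 1e-4).
#' @return data.frame with columns size, logRatio.
#' @export
errorLogRatio <- function(bench, floor = 1e-4) {
    wide <- stats::reshape(bench[, c("method", "size", "error")],
                           direction = "wide", idvar = "size",
                           timevar = "method")
    data.frame(size = wide$size,
               logRatio = log(pmax(wide$error.wilcoxon, floor) /
                              pmax(wide$error.pos, floor)))
}
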