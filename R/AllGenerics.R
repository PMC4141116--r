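#' @rdname coreIntervals
#' @export
setGeneric("coreIntervals", function(x, ...) standardGeneric("coreIntervals"))

#' @rdname geneMasks
#' @export
setGeneric("geneMasks", function(x, ...) standardGeneric("geneMasks"))

#' @rdname posScores
#' @export
setGeneric("posScores", function(x, ...) standardGeneric("posScores"))

#' @rdname minimumSubset
#' @export
setGeneric("minimumSubset",
    function(masks, scores, ...) standardGeneric("minimumSubset"))

#' @rdname selectGenes
#' @export
setGeneric("selectGenes", function(x, r, ...) standardGeneric("selectGenes"))

#' Accessors
#'
#' Small accessor generics for the package's result classes: the expression
#' matrix and integer class labels of a \linkS4class{POSExperiment}; the mask
#' matrix and per-gene 1-bit counts of a \linkS4class{GeneMaskSet}; POS scores
#' and relative dominant classes of a \linkS4class{GeneScoreTable} or
#' \linkS4class{SelectionResult}; the ordered final gene list, annotation
#' table and minimum subset of a \linkS4class{SelectionResult}; the score of
#' a \linkS4class{StabilityAssessment}.
#'
#' @param x an object of the documented classes.
#' @return The corresponding component; see the class documentation.
#' @name accessors
#' @examples
#' sim <- simulateExpression(nInformative = 2, nNoise = 3, seed = 1)
#' classLabels(sim)[1:4]
#' dim(expressionMatrix(sim))
NULL

#' @rdname accessors
#' @export
setGeneric("expressionMatrix",
    function(x) standardGeneric("expressionMatrix"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("onesCount", function(x) standardGeneric("onesCount"))

#' @rdname accessors
#' @export
setGeneric("posScore", function(x) standardGeneric("posScore"))

#' @rdname accessors
#' @export
setGeneric("relativeDominantClass",
    function(x) standardGeneric("relativeDominantClass"))

#' @rdname accessors
#' @export
setGeneric("finalGenes", function(x) standardGeneric("finalGenes"))

#' @rdname accessors
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @rdname accessors
#' @export
setGeneric("minSubset", function(x) standardGeneric("minSubset"))

#' @rdname accessors
#' @export
setGeneric("stabilityValue", function(x) standardGeneric("stabilityValue"))
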