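#' Construct a POSExperiment
#'
#' Bundles a genes x samples expression matrix with per-sample binary class
#' labels. Arbitrary label strings are mapped to integer classes \{1, 2\} by
#' first occurrence (the first label seen becomes class 1); the mapping is
#' stored in \code{metadata(x)$labelMap} and reported via a message, because
#' downstream relative-dominant-class and round-robin outputs depend on it.
#'
#' @param exprs numeric matrix, genes in rows, samples in columns; no missing
#'   values.
#' @param labels vector of length \code{ncol(exprs)} with exactly two
#'   distinct values.
#' @param geneIds,sampleIds optional identifiers; default to the dimnames or
#'   to generated ids.
#' @param minClassSize minimum samples required per class (default 4, so that
#'   per-class quartiles are estimated from at least a handful of values; the
#'   hard floor for a core interval is 2).
#' @param verbose emit the label-mapping message (default TRUE).
#' @return A \linkS4class{POSExperiment}.
#' @examples
#' X <- matrix(rnorm(40), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
#' pe <- POSExperiment(X, rep(c("tumour", "normal"), each = 4))
#' classLabels(pe)
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @export
POSExperiment <- function(exprs, labels, geneIds = rownames(exprs),
                          sampleIds = colnames(exprs), minClassSize = 4L,
                          verbose = TRUE) {
    exprs <- as.matrix(exprs)
    storage.mode(exprs) <- "double"
    if (is.null(geneIds)) geneIds <- paste0("gene", seq_len(nrow(exprs)))
    if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(ncol(exprs)))
    if (length(labels) != ncol(exprs))
        .valStop("label/sample mismatch: ", length(labels), " labels for ",
                 ncol(exprs), " samples")
    if (anyNA(exprs))
        .valStop("expression matrix contains missing values; use ",
                 "readPOSExperiment(missing = 'drop_gene') or clean the input")
    enc <- .encodeLabels(labels)
    counts <- tabulate(enc$class, 2L)
    if (any(counts < minClassSize))
        .valStop("each class needs at least ", minClassSize,
                 " samples; got ", counts[1L], " and ", counts[2L])
    if (anyDuplicated(geneIds)) .valStop("gene ids must be unique")
    if (anyDuplicated(sampleIds)) .valStop("sample ids must be unique")
    dimnames(exprs) <- list(geneIds, sampleIds)
    se <- SummarizedExperiment(
        assays = list(exprs = exprs),
        colData = DataFrame(label = as.character(labels),
                            class = enc$class, row.names = sampleIds))
    metadata(se)$labelMap <- stats::setNames(1:2, enc$levels)
    if (verbose)
        message("label mapping: '", enc$levels[1L], "' -> class 1, '",
                enc$levels[2L], "' -> class 2")
    new("POSExperiment", se)
}

#' @rdname accessors
#' @export
setMethod("expressionMatrix", "POSExperiment", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("classLabels", "POSExperiment", function(x)
    SummarizedExperiment::colData(x)$class)

setMethod("show", "POSExperiment", function(object) {
    cls <- tabulate(classLabels(object), 2L)
    cat("POSExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    map <- metadata(object)$labelMap
    cat("classes: ", cls[1L], " x '", names(map)[1L], "' (1), ",
        cls[2L], " x '", names(map)[2L], "' (2)\n", sep = "")
})

.detectSep <- function(path) {
    line <- readLines(path, n = 1L)
    if (grepl("\t", line)) "\t" else ","
}

#' Read a two-class expression dataset from delimited text
#'
#' Loads an expression matrix (TSV or CSV, delimiter auto-detected) and a
#' matching label file into a \linkS4class{POSExperiment}. The matrix file is
#' expected to carry sample ids in the header and gene ids in the first
#' column; \code{orientation = "samples_in_rows"} transposes after reading.
#' The label file may hold one label per line, a single delimited line, or a
#' two-column (sample id, label) table with or without a header; two-column
#' labels are matched to the matrix sample ids.
#'
#' Non-numeric cells are a hard error reported with their gene/sample
#' coordinates. Missing cells follow \code{missing}: \code{"error"} rejects
#' the file, \code{"drop_gene"} drops affected genes with a warning carrying
#' the count.
#'
#' @param matrixPath path to the expression matrix file.
#' @param labelsPath path to the class label file.
#' @param orientation \code{"genes_in_rows"} (default) or
#'   \code{"samples_in_rows"}.
#' @param sep field delimiter; auto-detected among tab and comma when NULL.
#' @param missing missing-cell policy, \code{"error"} or \code{"drop_gene"}.
#' @param minClassSize,verbose passed to \code{\link{POSExperiment}}.
#' @return A \linkS4class{POSExperiment}.
#' @seealso \code{\link{writePOSExperiment}} for the inverse.
#' @export
readPOSExperiment <- function(matrixPath, labelsPath,
                              orientation = c("genes_in_rows",
                                              "samples_in_rows"),
                              sep = NULL, missing = c("error", "drop_gene"),
                              minClassSize = 4L, verbose = TRUE) {
    orientation <- match.arg(orientation)
    missing <- match.arg(missing)
    if (!file.exists(matrixPath)) .valStop("matrix file not found: ", matrixPath)
    if (!file.exists(labelsPath)) .valStop("label file not found: ", labelsPath)
    if (is.null(sep)) sep <- .detectSep(matrixPath)
    raw <- utils::read.table(matrixPath, header = TRUE, sep = sep,
                             row.names = 1L, check.names = FALSE,
                             colClasses = "character",
                             na.strings = c("NA", ""), comment.char = "",
                             quote = "\"")
    X <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(rownames(raw), colnames(raw)))
    bad <- NULL
    for (j in seq_len(ncol(raw))) {
        col <- raw[[j]]
        num <- suppressWarnings(as.numeric(col))
        nonnum <- which(is.na(num) & !is.na(col))
        if (length(nonnum) && is.null(bad)) bad <- c(nonnum[1L], j)
        X[, j] <- num
    }
    if (!is.null(bad))
        .valStop("non-numeric value '", raw[[bad[2L]]][bad[1L]],
                 "' at gene '", rownames(raw)[bad[1L]], "' (row ", bad[1L],
                 "), sample '", colnames(raw)[bad[2L]], "' (column ",
                 bad[2L], ")")
    if (orientation == "samples_in_rows") X <- t(X)
    if (anyNA(X)) {
        if (missing == "error") {
            idx <- which(is.na(X), arr.ind = TRUE)[1L, ]
            .valStop("missing value at gene '", rownames(X)[idx[1L]],
                     "', sample '", colnames(X)[idx[2L]],
                     "'; rerun with missing = 'drop_gene' to drop such genes")
        }
        drop <- rowSums(is.na(X)) > 0L
        warning(sum(drop), " gene(s) with missing values dropped",
                call. = FALSE)
        X <- X[!drop, , drop = FALSE]
    }
    labels <- .readLabels(labelsPath, colnames(X))
    if (length(labels) != ncol(X))
        .valStop("dimension mismatch: ", length(labels), " labels but ",
                 ncol(X), " samples in the matrix")
    POSExperiment(X, labels, minClassSize = minClassSize, verbose = verbose)
}

.readLabels <- function(path, sampleIds) {
    sep <- .detectSep(path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 1L && length(sampleIds) > 1L)
        return(trimws(strsplit(lines, sep, fixed = TRUE)[[1L]]))
    tokens <- strsplit(lines, sep, fixed = TRUE)
    ncols <- lengths(tokens)
    if (all(ncols >= 2L)) {
        ids <- trimws(vapply(tokens, `[`, "", 1L))
        vals <- trimws(vapply(tokens, `[`, "", 2L))
        if (!ids[1L] %in% sampleIds) { # header row
            ids <- ids[-1L]; vals <- vals[-1L]
        }
        if (all(sampleIds %in% ids))
            return(vals[match(sampleIds, ids)])
        return(vals)
    }
    vals <- trimws(vapply(tokens, `[`, "", 1L))
    if (length(vals) == length(sampleIds) + 1L) vals <- vals[-1L]
    vals
}

#' Write a POSExperiment to delimited text
#'
#' Writes the expression matrix (gene ids in the first column, sample ids in
#' the header) and a two-column (sample_id, label) table, the format
#' \code{\link{readPOSExperiment}} reads back. Values round-trip at full
#' printed precision.
#'
#' @param x a \linkS4class{POSExperiment}.
#' @param matrixPath,labelsPath output paths.
#' @param sep field delimiter (default tab).
#' @export
writePOSExperiment <- function(x, matrixPath, labelsPath, sep = "\t") {
    X <- expressionMatrix(x)
    # %.17g guarantees binary-exact numeric round trips through text
    fmt <- matrix(sprintf("%.17g", X), nrow = nrow(X),
                  dimnames = dimnames(X))
    df <- data.frame(gene_id = rownames(X), fmt, check.names = FALSE)
    utils::write.table(df, matrixPath, sep = sep, quote = FALSE,
                       row.names = FALSE)
    lab <- data.frame(sample_id = colnames(X),
                      label = SummarizedExperiment::colData(x)$label)
    utils::write.table(lab, labelsPath, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(NULL)
}
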