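# Low-level vectorised primitives shared by the S4 layer, the exhaustive
# enumeration helpers and the CLI. These work on plain numeric vectors /
# matrices so that tiny configurations can be scored without building a
# SummarizedExperiment.

# Validation failures are signalled with a dedicated condition class so the
# command-line front end can map them onto exit code 1.
.valStop <- function(...) {
    stop(structure(class = c("posValidationError", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Derive a stream of sub-seeds from one master seed (kept below 2^31).
.subSeeds <- function(seed, n) {
    .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Core interval of one class of one gene: empirical quartiles under the given
# quantile type, Tukey fences Q1 - 1.5 IQR / Q3 + 1.5 IQR, clipped to the
# observed class minimum / maximum so the interval never extends beyond data.
.classInterval <- function(values, quartileType = 7L) {
    values <- values[is.finite(values)]
    if (length(values) < 2L)
        .valStop("core interval undefined: need at least 2 finite values, got ",
                 length(values))
    q <- quantile(values, c(0.25, 0.75), type = quartileType, names = FALSE)
    iqr <- q[2L] - q[1L]
    c(low  = max(q[1L] - 1.5 * iqr, min(values)),
      high = min(q[2L] + 1.5 * iqr, max(values)),
      q1 = q[1L], q3 = q[2L], iqr = iqr)
}

# Full overlap geometry for a single gene given its expressions and integer
# class labels (1/2). Returns the pieces named as in CoreIntervalSet.
.geneGeometry <- function(values, cls, quartileType = 7L,
                          overlapOnNonoutlier = FALSE) {
    i1 <- .classInterval(values[cls == 1L], quartileType)
    i2 <- .classInterval(values[cls == 2L], quartileType)
    lower <- c(i1[["low"]], i2[["low"]])
    upper <- c(i1[["high"]], i2[["high"]])
    ovLow <- max(lower); ovHigh <- min(upper)
    hasOverlap <- ovLow <= ovHigh
    nonoutlier <- values >= lower[cls] & values <= upper[cls]
    overlapSet <- if (hasOverlap) values >= ovLow & values <= ovHigh
                  else rep(FALSE, length(values))
    if (overlapOnNonoutlier) overlapSet <- overlapSet & nonoutlier
    list(interval1 = i1, interval2 = i2,
         totalLow = min(lower), totalHigh = max(upper),
         overlapLow = if (hasOverlap) ovLow else NA_real_,
         overlapHigh = if (hasOverlap) ovHigh else NA_real_,
         hasOverlap = hasOverlap,
         overlapLength = if (hasOverlap) ovHigh - ovLow else 0,
         totalLength = max(upper) - min(lower),
         nonoutlier = nonoutlier, overlapSet = overlapSet,
         nonoverlap = nonoutlier & !overlapSet)
}

# POS score from a single-gene geometry. Degenerate gene (all expressions at
# one point across both classes) scores 1, the fully indistinguishable worst
# case. A gene whose intervals are disjoint, or whose overlap region contains
# no sample, scores 0.
.posFromGeometry <- function(geom, cls, sampleDenominator = c("all",
                             "nonoutlier")) {
    sampleDenominator <- match.arg(sampleDenominator)
    v1 <- sum(geom$overlapSet & cls == 1L)
    v2 <- sum(geom$overlapSet & cls == 2L)
    nV <- v1 + v2
    if (geom$totalLength <= 0)
        return(list(pos = 1, theta = c(NA_real_, NA_real_), v = c(v1, v2)))
    if (!geom$hasOverlap || nV == 0L)
        return(list(pos = 0, theta = c(NA_real_, NA_real_), v = c(v1, v2)))
    theta <- c(v1, v2) / nV
    denom <- switch(sampleDenominator,
                    all = length(cls), nonoutlier = sum(geom$nonoutlier))
    pos <- (geom$overlapLength / geom$totalLength) * (nV / denom) *
        4 * theta[1L] * theta[2L]
    list(pos = pos, theta = theta, v = c(v1, v2))
}

# Parse an integer-coded class vector out of arbitrary labels by first
# occurrence; exactly two distinct labels are required.
.encodeLabels <- function(labels) {
    labels <- as.character(labels)
    lev <- unique(labels)
    if (length(lev) != 2L)
        .valStop("binary classes required: found ", length(lev),
                 " distinct labels (", paste(utils::head(lev, 5L),
                 collapse = ", "), if (length(lev) > 5L) ", ..." else "", ")")
    list(class = match(labels, lev), levels = lev)
}
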