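writeFixture <- function(X, labels, dir = scratchDir()) {
    mp <- file.path(dir, "matrix.tsv")
    lp <- file.path(dir, "labels.tsv")
    df <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
    write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(labels, lp)
    list(matrix = mp, labels = lp)
}

fix34 <- function() {
    X <- matrix(as.numeric(1:12), nrow = 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    writeFixture(X, c("A", "A", "B", "B"))
}

test_that("a delimited matrix and label file load into a validated dataset", {
    p <- fix34()
    pe <- suppressMessages(readPOSExperiment(p$matrix, p$labels,
                                             minClassSize = 2L))
    expect_s4_class(pe, "POSExperiment")
    expect_equal(dim(pe), c(3L, 4L))
    expect_equal(classLabels(pe), c(1L, 1L, 2L, 2L))
    expect_equal(unname(expressionMatrix(pe)[2, 3]), 8)
})

test_that("label strings map to classes 1/2 by first occurrence", {
    p <- fix34()
    writeLines(c("tumour", "tumour", "normal", "normal"), p$labels)
    expect_message(
        pe <- readPOSExperiment(p$matrix, p$labels, minClassSize = 2L,
                                verbose = TRUE),
        "tumour' -> class 1")
    expect_equal(metadata(pe)$labelMap, c(tumour = 1L, normal = 2L))
    # reversed file order flips the mapping deterministically
    writeLines(c("normal", "normal", "tumour", "tumour"), p$labels)
    pe2 <- suppressMessages(readPOSExperiment(p$matrix, p$labels,
                                              minClassSize = 2L))
    expect_equal(names(metadata(pe2)$labelMap)[1], "normal")
})

test_that("more than two classes is rejected as out of scope", {
    p <- fix34()
    writeLines(c("A", "B", "C", "A"), p$labels)
    expect_error(readPOSExperiment(p$matrix, p$labels, minClassSize = 2L),
                 "binary classes required")
})

test_that("label/column count mismatch names both counts", {
    p <- fix34()
    writeLines(c("A", "A", "B"), p$labels)
    expect_error(
        suppressMessages(readPOSExperiment(p$matrix, p$labels,
                                           minClassSize = 2L)),
        "3 labels but 4 samples")
})

test_that("a non-numeric cell is a hard error with its coordinates", {
    p <- fix34()
    lines <- readLines(p$matrix)
    lines[3] <- sub("\t5\t", "\toops\t", lines[3])
    writeLines(lines, p$matrix)
    expect_error(readPOSExperiment(p$matrix, p$labels, minClassSize = 2L),
                 "non-numeric value 'oops'.*g2.*s2")
})

test_that("missing cells follow the configured policy", {
    p <- fix34()
    lines <- readLines(p$matrix)
    lines[3] <- sub("\t5\t", "\tNA\t", lines[3])
    writeLines(lines, p$matrix)
    expect_error(readPOSExperiment(p$matrix, p$labels, minClassSize = 2L),
                 "missing value")
    expect_warning(
        pe <- suppressMessages(readPOSExperiment(p$matrix, p$labels,
                                                 missing = "drop_gene",
                                                 minClassSize = 2L)),
        "1 gene\\(s\\) with missing values dropped")
    expect_equal(nrow(pe), 2L)
    expect_false("g2" %in% rownames(pe))
})

test_that("comma-delimited input is auto-detected", {
    dir <- withr::local_tempdir()
    mp <- file.path(dir, "m.csv"); lp <- file.path(dir, "l.csv")
    writeLines(c("gene_id,s1,s2,s3,s4", "g1,1.5,2,3,4", "g2,5,6,7,8"), mp)
    writeLines("A,A,B,B", lp)
    pe <- suppressMessages(readPOSExperiment(mp, lp, minClassSize = 2L))
    expect_equal(unname(expressionMatrix(pe)[1, 1]), 1.5)
    expect_equal(classLabels(pe), c(1L, 1L, 2L, 2L))
})

test_that("write then read round-trips values and labels exactly", {
    sim <- simulateExpression(nPerClass = c(5, 5), nInformative = 2,
                              nNoise = 3, seed = 3)
    dir <- withr::local_tempdir()
    mp <- file.path(dir, "m.tsv"); lp <- file.path(dir, "l.tsv")
    writePOSExperiment(sim, mp, lp)
    back <- suppressMessages(readPOSExperiment(mp, lp, minClassSize = 2L))
    expect_identical(expressionMatrix(back), expressionMatrix(sim))
    expect_identical(classLabels(back), classLabels(sim))
    expect_identical(rownames(back), rownames(sim))
})

test_that("sample-id-keyed label tables are matched to matrix columns", {
    sim <- simulateExpression(nPerClass = c(4, 4), nInformative = 1,
                              nNoise = 1, seed = 1)
    dir <- withr::local_tempdir()
    mp <- file.path(dir, "m.tsv"); lp <- file.path(dir, "l.tsv")
    writePOSExperiment(sim, mp, lp)
    # shuffle label file rows; reader must realign by sample id
    lab <- read.table(lp, header = TRUE, sep = "\t")
    write.table(lab[rev(seq_len(nrow(lab))), ], lp, sep = "\t",
                quote = FALSE, row.names = FALSE)
    back <- suppressMessages(readPOSExperiment(mp, lp, minClassSize = 2L))
    expect_identical(classLabels(back), classLabels(sim))
})

test_that("selection tables are written with ranks and all columns", {
    sim <- simulateExpression(nInformative = 3, nNoise = 17, seed = 2)
    res <- selectGenes(sim, r = 5, seed = 1)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSelection(res, path)
    tab <- read.table(path, header = TRUE, sep = "\t")
    expect_equal(nrow(tab), 5L)
    expect_equal(tab$rank, 1:5)
    expect_named(tab, c("gene_id", "rank", "pos_score", "rdc",
                        "in_minimum_subset", "mask_ones"))
    expect_error(writeSelection(
        new("SelectionResult", table = S4Vectors::DataFrame()), path),
        "empty selection")
})

test_that("the dataset invariants are enforced at construction", {
    X <- matrix(rnorm(20), 5, 4)
    expect_error(POSExperiment(X, c("A", "A", "B", "B")),
                 "at least 4 samples")   # default class-size floor
    expect_error(quietPE(X, c("A", "A", "A", "A")), "binary classes")
    X[2, 2] <- NA
    expect_error(quietPE(X, c("A", "A", "B", "B")), "missing values")
    X[2, 2] <- 0
    rownames(X) <- c("g1", "g1", "g2", "g3", "g4")
    expect_error(quietPE(X, c("A", "A", "B", "B")), "gene ids must be unique")
})
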